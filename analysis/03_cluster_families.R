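#!/usr/bin/env Rscript
# Family assignment: genes with qualifying best hits into reference families,
# the remainder Markov-clustered de novo on the -log10(E) similarity graph.

suppressPackageStartupMessages(library(molluscfam))

fx <- "results/fixtures"
hits <- read_blast_tab(file.path(fx, "allvsall.tsv"))
ref <- read.delim(file.path(fx, "reference_families.tsv"))
retained <- readLines("results/retained_ids.txt")

asn <- assign_families(hits, ref, all_genes = retained)
asn <- asn[asn$gene_id %in% retained, ]
write.table(asn, "results/families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("assigned %d genes: %d reference, %d de novo, %d orphan candidates\n",
            nrow(asn), sum(asn$source == "reference"),
            sum(asn$source == "de_novo"), sum(asn$source == "none")))

acc <- partition_accounting(nrow(asn), sum(asn$source == "reference"),
                            sum(asn$source == "de_novo"))
cat(sprintf("partition: %d unassigned after reference, %d orphans\n",
            acc$n_unassigned_after_reference, acc$n_orphan))
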