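#!/usr/bin/env Rscript
# Hypergeometric GO enrichment of the genes in families private to the two
# bivalve-like genomes (shared by species 1 and 2 but absent from species 3)
# against all retained genes, flagged at raw p < 0.01 with BH q-values
# reported alongside.

suppressPackageStartupMessages(library(molluscfam))

asn <- read.delim("results/families.tsv")
fams <- read.delim("results/family_records.tsv")
go <- read_go_table("results/fixtures/go.tsv")

bivalve_private <- fams$family[fams$source == "de_novo" &
                               fams$species_combo == "cgi+pfu"]
foreground <- asn$gene_id[asn$family_id %in% bivalve_private]
background <- asn$gene_id

res <- enrich_go_terms(foreground, background, go, alpha = 0.01)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("tested %d terms over N = %d background, n = %d foreground\n",
            nrow(res), attr(res, "N"), attr(res, "n")))
cat(sprintf("%d terms enriched at p < 0.01:\n", sum(res$enriched)))
print(head(res[res$enriched, ], 10))
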