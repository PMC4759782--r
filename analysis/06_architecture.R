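#!/usr/bin/env Rscript
# Genome architecture on the simulated scaffolds: tandem arrays of family
# members (the shell-matrix-protein / C1qDC reading), an ordered cluster
# layout report for a labeled gene set (the Hox-cluster reading), and
# assembly summary statistics.

suppressPackageStartupMessages(library(molluscfam))

fx <- "results/fixtures"
species <- c("pfu", "cgi", "lgi")
coords <- do.call(rbind, lapply(species, function(sp)
  read_gff3_genes(file.path(fx, sprintf("%s.genes.gff3", sp)))))
asn <- read.delim("results/families.tsv")
genes <- merge(coords, asn[, c("gene_id", "family_id")],
               by.x = "id", by.y = "gene_id")
genes$family <- ifelse(genes$family_id == NO_FAMILY, NA, genes$family_id)

arrays <- detect_tandem_arrays(genes, max_intervening = 1)
flat <- arrays
flat$members <- vapply(arrays$members, paste, collapse = ",", FUN.VALUE = "")
write.table(flat, "results/tandem_arrays.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d tandem arrays detected (%d genes involved)\n",
            nrow(arrays), sum(arrays$n_members)))

# layout report for the largest detected array's family, Hox-cluster style
if (nrow(arrays)) {
  fam <- arrays$family[which.max(arrays$n_members)]
  labels <- setNames(sprintf("%s.%d", fam,
                             seq_len(sum(genes$family %in% fam))),
                     genes$id[genes$family %in% fam])
  print(cluster_layout_report(genes, labels))
}

# assembly statistics of the per-species protein-coding gene space stand-in:
# simulated scaffolds summarized from the GFF3 extents
lens <- tapply(genes$end, genes$scaffold, max)
asm <- assembly_summary(assembly_set(as.numeric(lens)))
jsonlite::write_json(asm, "results/assembly_stats.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("scaffold stand-ins: n = %d, N50 = %d bases, average %.1f kb\n",
            asm$n_sequences, asm$n50, asm$average_length_kb))
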