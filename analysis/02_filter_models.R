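#!/usr/bin/env Rscript
# Gene-model retention cascade on the simulated genomes: drop models under
# 50 aa, drop transposable-element-like models, then drop clusterless models
# without transcript evidence. The ledger reproduces, on synthetic data, the
# style of accounting genome papers print for their model sets.

suppressPackageStartupMessages(library(molluscfam))

fx <- "results/fixtures"
species <- c("pfu", "cgi", "lgi")
coords <- do.call(rbind, lapply(species, function(sp)
  read_gff3_genes(file.path(fx, sprintf("%s.genes.gff3", sp)))))
plen <- unlist(lapply(species, function(sp)
  read_protein_lengths(file.path(fx, sprintf("%s.proteins.fasta", sp)))))
models <- gene_models(id = coords$id, species = coords$species,
                      scaffold = coords$scaffold, start = coords$start,
                      end = coords$end, strand = coords$strand,
                      protein_length = unname(plen[coords$id]),
                      has_start_codon = coords$has_start_codon,
                      has_stop_codon = coords$has_stop_codon)

te <- read.delim(file.path(fx, "te_hits.tsv"))$model_id
ev <- read.delim(file.path(fx, "evidence.tsv"))$model_id
truth <- jsonlite::read_json(file.path(fx, "truth.json"))
clusterless <- names(Filter(function(x) x == "orphan", truth$gene_category))

# GO-annotated genes stand in for the protein-database hit set
db <- unique(read_go_table(file.path(fx, "go.tsv"))$gene_id)

res <- run_cascade(models, te_hits = te, clusterless_ids = clusterless,
                   evidence_ids = ev, db_hit_ids = db)
print(res$ledger)
led <- res$ledger
write.csv(data.frame(stage = names(unclass(led)),
                     value = unlist(unclass(led), use.names = FALSE)),
          "results/filter_ledger.csv", row.names = FALSE)
writeLines(res$retained$id, "results/retained_ids.txt")
cat(sprintf("retained %d of %d models\n", led$n_retained, led$n_initial))
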