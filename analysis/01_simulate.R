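#!/usr/bin/env Rscript
# Generate the synthetic three-genome benchmark used by the rest of the
# analysis: three mollusc-like proteomes with planted reference-shared,
# mollusc-shared and lineage-specific families, orphans, faulty models,
# tandem arrays, enriched GO terms and gene trees. Ground truth is written
# alongside the data, so every later step can be audited.

suppressPackageStartupMessages(library(molluscfam))

cfg <- truth_config(seed = 20260920L)
truth <- generate_truth(cfg)
print(truth)

out <- "results/fixtures"
manifest <- write_fixture_bundle(truth, out)
cat(sprintf("wrote %d files to %s (see MANIFEST.tsv)\n", nrow(manifest), out))
cat(sprintf("planted: %d genes, %d families, %d tandem arrays, %d gene trees\n",
            nrow(truth$genes), nrow(truth$families), length(truth$tandem),
            length(truth$trees)))
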