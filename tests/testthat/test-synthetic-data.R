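# The generator is itself first-class code: its planted structure must be
# deterministic, countable, and recoverable.

test_that("truth generation is deterministic and honours planted counts", {
  cfg <- truth_config(seed = 5)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$families, t2$families)
  expect_identical(generate_similarity_table(t1), generate_similarity_table(t2))

  tab <- table(t1$families$category)
  expect_equal(unname(tab[["reference"]]), cfg$n_reference_families)
  expect_equal(unname(tab[["shared"]]), cfg$n_shared_families)
  expect_equal(unname(tab[["lineage_specific"]]), 3 * cfg$n_lineage_specific)
  expect_equal(sum(t1$genes$category == "orphan"), 3 * cfg$n_orphans)
  expect_equal(sum(t1$genes$category == "short"), cfg$short_model_count)
  expect_equal(sum(t1$genes$category == "te"), cfg$te_model_count)
  expect_true(all(t1$genes$protein_length[t1$genes$category == "short"] < 50))

  # every gene id appears exactly once in the gene-to-family map
  expect_false(anyDuplicated(t1$genes$id) > 0)

  # shared families: not reference, >= 2 species
  sh <- t1$families[t1$families$category == "shared", ]
  expect_equal(nrow(sh), cfg$n_shared_families)
  n_sp <- lengths(strsplit(sh$species_combo, "+", fixed = TRUE))
  expect_true(all(n_sp >= 2))
})

test_that("zero-count configurations yield empty categories", {
  cfg <- truth_config(seed = 2, n_orphans = 0, short_model_count = 0,
                      te_model_count = 0)
  tr <- generate_truth(cfg)
  expect_equal(sum(tr$genes$family == NO_FAMILY), 0)
})

test_that("inconsistent configurations are rejected with the field named", {
  expect_error(truth_config(expansion_copies = c(1, 4)), "expansion_copies")
  expect_error(truth_config(edge_dropout_prob = 1.2), "edge_dropout_prob")
  expect_error(truth_config(within_family_weight_range = c(5, 2)),
               "within_family_weight_range")
  expect_error(truth_config(tandem_arrays = list(list(family = "x",
    scaffold = "pfu_s01", copies = 1, max_intervening = 0))), "copies")
})

test_that("noiseless similarity graph components are exactly the planted families", {
  tr <- generate_truth(noiseless_config(seed = 4))
  sim <- generate_similarity_table(tr)
  g <- normalize_similarity_graph(sim)
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                      vertices = g$nodes)
  mem <- igraph::components(ig)$membership
  comp_key <- partition_key(split(names(mem), mem))
  fams <- tr$genes[tr$genes$family != NO_FAMILY, ]
  planted_key <- partition_key(split(fams$id, fams$family))
  expect_identical(comp_key, planted_key)

  # orphans appear in no emitted pair
  orph <- tr$genes$id[tr$genes$category == "orphan"]
  expect_false(any(orph %in% c(sim$qseqid, sim$sseqid)))
})

test_that("within-family dropout thins ordered pairs within binomial bounds", {
  cfg <- truth_config(seed = 9, n_reference_families = 0,
                      n_shared_families = 0, n_lineage_specific = 1,
                      expansion_copies = c(10, 10), n_orphans = 0,
                      short_model_count = 0, te_model_count = 0,
                      edge_dropout_prob = 0.1, between_family_edge_prob = 0,
                      n_scaffolds = 10, tandem_arrays = list())
  tr <- generate_truth(cfg)
  sim <- generate_similarity_table(tr)
  # 3 species x one 10-member family: 90 ordered pairs each, kept w.p. 0.9
  for (sp in cfg$species) {
    cnt <- sum(startsWith(sim$qseqid, sp))
    expect_gte(cnt, qbinom(0.005, 90, 0.9))
    expect_lte(cnt, qbinom(0.995, 90, 0.9))
  }
})

test_that("GO simulation honours degenerate and stochastic probabilities", {
  genes <- sprintf("pfu_g%04d", 1:300)
  fg <- genes[1:100]
  et <- data.frame(term = "GO:0000001", fg_prob = 1)
  go <- simulate_go_annotations(genes, fg, 3, background_prob = 0, et)
  carried <- go$gene_id[go$term == "GO:0000001"]
  expect_setequal(carried, fg)
  expect_equal(nrow(go[go$term != "GO:0000001", ]), 0)

  # fg prob 0.5 over 200 foreground genes: count within binomial 99% bounds
  set.seed(42)
  genes2 <- sprintf("g%04d", 1:2000)
  fg2 <- genes2[1:200]
  et2 <- data.frame(term = "GO:0000002", fg_prob = 0.5)
  go2 <- simulate_go_annotations(genes2, fg2, 5, background_prob = 0, et2)
  k <- sum(go2$term == "GO:0000002")
  expect_gte(k, qbinom(0.005, 200, 0.5))
  expect_lte(k, qbinom(0.995, 200, 0.5))
})

test_that("planted tandem arrays occupy near-consecutive ranks on their scaffold", {
  cfg <- noiseless_config(seed = 6, tandem_arrays = list(
    list(family = "LSP_pfu_001", scaffold = "pfu_s02", copies = 3,
         max_intervening = 0)))
  tr <- generate_truth(cfg)
  ann <- generate_annotations(tr)
  members <- tr$tandem[[1]]$members
  co <- ann$coords[ann$coords$scaffold == "pfu_s02", ]
  co <- co[order(co$start), ]
  ranks <- match(members, co$id)
  expect_equal(sort(diff(sort(ranks))), c(1, 1))  # strictly consecutive
})

test_that("gene trees round-trip supports and realize planted structures", {
  tr <- generate_truth(noiseless_config(seed = 8))
  tws <- generate_gene_trees(tr)
  expect_gt(length(tws), 0)
  fam <- names(tws)[vapply(tr$trees[names(tws)], function(p)
    !is.null(p$pairs), logical(1))][1]
  t <- ape::read.tree(text = tws[[fam]])
  plan <- tr$trees[[fam]]
  res <- find_supported_ortholog_pairs(t, "pfu", "cgi")
  expect_true(plan$pairs$leaf_a %in% res$pairs$leaf_a)
  got <- res$pairs[res$pairs$leaf_a == plan$pairs$leaf_a, ]
  expect_equal(got$support, plan$pairs$support)  # support round-trips
  # all supports parse as integers 0..100
  sup <- suppressWarnings(as.numeric(t$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("fixture bundles round-trip and carry valid checksums", {
  tr <- generate_truth(noiseless_config(seed = 12, n_reference_families = 5,
                                        n_shared_families = 4,
                                        n_lineage_specific = 2, n_orphans = 3,
                                        short_model_count = 2,
                                        te_model_count = 2))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(tr, dir)
  expect_true(file.exists(file.path(dir, "MANIFEST.tsv")))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) f <- file.path(dir, "trees", manifest$file[i])
    expect_identical(unname(tools::md5sum(f)), manifest$md5[i])
  }
  # round-trip: FASTA and GFF3 agree with the planted gene counts
  for (sp in tr$config$species) {
    lens <- read_protein_lengths(file.path(dir, sprintf("%s.proteins.fasta", sp)))
    expect_equal(length(lens), sum(tr$genes$species == sp))
    gff <- read_gff3_genes(file.path(dir, sprintf("%s.genes.gff3", sp)))
    expect_setequal(gff$id, tr$genes$id[tr$genes$species == sp])
    expect_equal(unname(lens[gff$id]),
                 (gff$end - gff$start + 1 - 3) / 3)  # length-correct dummies
  }
  hits <- read_blast_tab(file.path(dir, "allvsall.tsv"))
  expect_named(hits, c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore"))
})

test_that("an empty truth set still writes a valid bundle", {
  cfg <- truth_config(seed = 1, n_reference_families = 0,
                      n_shared_families = 0, n_lineage_specific = 0,
                      n_orphans = 0, short_model_count = 0, te_model_count = 0,
                      tandem_arrays = list())
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr$genes), 0)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(tr, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_gt(nrow(manifest), 0)
})
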