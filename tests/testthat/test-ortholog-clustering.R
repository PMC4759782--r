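test_that("similarity weights follow the -log10(E) convention", {
  hits <- data.frame(
    qseqid = c("a", "a", "b", "c", "a"),
    sseqid = c("b", "b", "a", "a", "a"),
    evalue = c(1e-5, 1e-15, 0, 1e-4, 1e-50),
    bitscore = 1)
  g <- normalize_similarity_graph(hits)
  # a-b: directed weights 5 and 15 averaged with the reciprocal cap-300 hit:
  # mean(5, 15, 300) = 106.6667; a-c discarded (above cutoff); self-hit dropped
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, mean(c(5, 15, 300)))

  one <- data.frame(qseqid = "a", sseqid = "b", evalue = 1e-5, bitscore = 1)
  expect_equal(normalize_similarity_graph(one)$edges$weight, 5)
  zero <- data.frame(qseqid = "a", sseqid = "b", evalue = 0, bitscore = 1)
  expect_equal(normalize_similarity_graph(zero)$edges$weight, 300)
  # one-directional hits are kept at their own weight
  expect_equal(normalize_similarity_graph(one)$edges$weight, 5)
  neg <- data.frame(qseqid = "a", sseqid = "b", evalue = -1, bitscore = 1)
  expect_error(normalize_similarity_graph(neg), "negative e-value")
})

test_that("MCL separates disconnected cliques and isolates singletons", {
  clique <- function(nodes, w = 10) {
    p <- t(combn(nodes, 2))
    data.frame(a = p[, 1], b = p[, 2], weight = w)
  }
  g <- similarity_graph(rbind(clique(c("a1", "a2", "a3", "a4")),
                              clique(c("b1", "b2", "b3", "b4"))))
  cl <- mcl_cluster(g)
  expect_equal(partition_key(cl), "a1,a2,a3,a4;b1,b2,b3,b4")

  iso <- similarity_graph(data.frame(a = character(), b = character(),
                                     weight = numeric()),
                          nodes = c("x", "y", "z"))
  expect_equal(partition_key(mcl_cluster(iso)), "x;y;z")
  expect_error(mcl_cluster(g, inflation = 1), "inflation")
})

test_that("MCL matches the dense step-by-step oracle on random graphs", {
  for (s in 1:40) {
    g <- random_simgraph(sample(5:20, 1), edge_prob = runif(1, 0.15, 0.6),
                         seed = 1000 + s)
    got <- mcl_cluster(g)
    want <- oracle_mcl(g)
    expect_identical(partition_key(got), partition_key(want))
  }
})

test_that("relabeling genes permutes but does not change the partition", {
  g <- random_simgraph(14, seed = 77)
  cl <- mcl_cluster(g)
  perm <- setNames(sprintf("z%02d", sample(14)), g$nodes)
  g2 <- similarity_graph(data.frame(a = unname(perm[g$edges$a]),
                                    b = unname(perm[g$edges$b]),
                                    weight = g$edges$weight),
                         nodes = unname(perm))
  cl2 <- mcl_cluster(g2)
  relabeled <- lapply(cl, function(x) sort(unname(perm[x])))
  expect_identical(partition_key(relabeled), partition_key(cl2))
})

test_that("reference assignment uses qualifying best hits only", {
  ref <- data.frame(member_id = c("r1", "r2", "r3"),
                    family = c("F1", "F1", "F2"))
  hits <- data.frame(qseqid = c("g1", "g1", "g2"),
                     sseqid = c("r1", "r2", "r3"),
                     evalue = c(1e-20, 1e-30, 1e-4),
                     bitscore = c(100, 120, 50))
  a <- assign_reference_families(hits, ref)
  # two hits into the same family assign it once; sub-cutoff hit leaves g2 out
  expect_equal(a$family_id[a$gene_id == "g1"], "F1")
  expect_false("g2" %in% a$gene_id)
  # listed members keep their own family
  expect_equal(a$family_id[a$gene_id == "r3"], "F2")

  bad <- data.frame(member_id = "r9", family = NA)
  expect_error(assign_reference_families(hits, bad), "no family")
  expect_error(assign_reference_families(hits, ref[0, ]), "empty")
})

test_that("de novo clustering completes the assignment partition", {
  ref <- data.frame(member_id = "r1", family = "F1")
  hits <- data.frame(
    qseqid = c("pfu_a", "cgi_b", "pfu_c"),
    sseqid = c("cgi_b", "pfu_a", "r1"),
    evalue = 1e-30, bitscore = 100)
  g <- normalize_similarity_graph(hits)
  ra <- assign_reference_families(hits, ref)
  asn <- cluster_unassigned(g, ra, all_genes = c("pfu_a", "cgi_b", "pfu_c",
                                                 "r1", "lgi_lone"))
  expect_setequal(asn$gene_id, c("pfu_a", "cgi_b", "pfu_c", "r1", "lgi_lone"))
  # a strongly linked unassigned pair becomes one de novo family of 2
  expect_equal(asn$source[asn$gene_id == "pfu_a"], "de_novo")
  expect_equal(asn$family_id[asn$gene_id == "pfu_a"],
               asn$family_id[asn$gene_id == "cgi_b"])
  # an isolated unassigned gene is an orphan candidate
  expect_equal(asn$source[asn$gene_id == "lgi_lone"], "none")
  expect_equal(asn$family_id[asn$gene_id == "lgi_lone"], NO_FAMILY)
  # disjoint and exhaustive sources
  expect_equal(sum(table(asn$source)), 5)
})

test_that("noiseless fixtures are recovered exactly end to end", {
  tr <- generate_truth(noiseless_config(seed = 14))
  sim <- generate_similarity_table(tr)
  asn <- assign_families(sim, tr$reference_members, all_genes = tr$genes$id)
  m <- merge(tr$genes, asn, by.x = "id", by.y = "gene_id")
  expect_true(all(m$source[m$category == "reference"] == "reference"))
  expect_true(all(m$source[m$category %in% c("shared", "lineage_specific")]
                  == "de_novo"))
  expect_true(all(m$source[m$category %in% c("orphan", "short", "te")]
                  == "none"))
  dn <- m[m$category %in% c("shared", "lineage_specific"), ]
  expect_equal(mclust::adjustedRandIndex(dn$family, dn$family_id), 1)
})

test_that("clustering accuracy degrades monotonically with edge dropout", {
  ari_at <- function(dropout, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- truth_config(seed = s, edge_dropout_prob = dropout,
                          between_family_edge_prob = 0,
                          n_reference_families = 10, n_shared_families = 10,
                          n_lineage_specific = 6, n_orphans = 5,
                          short_model_count = 0, te_model_count = 0)
      tr <- generate_truth(cfg)
      sim <- generate_similarity_table(tr)
      asn <- assign_families(sim, tr$reference_members, all_genes = tr$genes$id)
      m <- merge(tr$genes, asn, by.x = "id", by.y = "gene_id")
      dn <- m[m$category %in% c("shared", "lineage_specific") &
                m$source != "reference", ]
      pred <- ifelse(dn$family_id == NO_FAMILY, paste0("u_", dn$id),
                     dn$family_id)
      mclust::adjustedRandIndex(dn$family, pred)
    }, numeric(1)))
  }
  seeds <- 1:6
  a0 <- ari_at(0, seeds)
  a2 <- ari_at(0.2, seeds)
  a5 <- ari_at(0.5, seeds)
  expect_gte(a0, a2 - 1e-9)
  expect_gte(a2, a5 - 1e-9)
  expect_equal(a0, 1)
})
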