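tre <- function(txt) ape::read.tree(text = txt)

test_that("domain counting applies per-domain length thresholds gene-wise", {
  hits <- data.frame(
    gene_id = c("pfu_a", "pfu_a", "pfu_b", "cgi_a", "cgi_a"),
    species = c("pfu", "pfu", "pfu", "cgi", "cgi"),
    domain = c("HSP70", "HSP70", "HSP70", "C1q", "C1q"),
    length = c(150, 220, 300, 120, 110))
  tab <- domain_count_table(hits, c(HSP70 = 200, C1q = 100))
  # the 150 aa HSP70 hit is excluded but its gene still counts via the 220 hit;
  # a gene with two qualifying hits counts once
  expect_equal(tab$n_genes[tab$species == "pfu" & tab$domain == "HSP70"], 2L)
  expect_equal(tab$n_genes[tab$species == "cgi" & tab$domain == "C1q"], 1L)

  only_short <- data.frame(gene_id = "pfu_c", species = "pfu",
                           domain = "HSP70", length = 150)
  expect_equal(nrow(domain_count_table(only_short, c(HSP70 = 200))), 0)
  expect_error(domain_count_table(hits, c(HSP70 = 0)), "min_length")
})

test_that("fixture domain counts equal the planted table", {
  tr <- generate_truth(noiseless_config(seed = 19))
  ann <- generate_annotations(tr)
  thr <- setNames(rep(ann$domain_min_length,
                      length(unique(ann$domains$domain))),
                  unique(ann$domains$domain))
  tab <- domain_count_table(ann$domains, thr)
  want <- ann$domain_counts[order(ann$domain_counts$domain,
                                  ann$domain_counts$species), ]
  got <- tab[order(tab$domain, tab$species), ]
  expect_equal(got$n_genes, want$count)
  expect_equal(got$species, want$species)
  expect_equal(got$domain, want$domain)
})

test_that("lineage-specific expansions are the maximal one-species sides", {
  t1 <- tre("((pfu_1,pfu_2)90,(cgi_1,lgi_1)50);")
  calls <- find_lineage_specific_expansions(t1)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$species, "pfu")
  expect_setequal(calls[[1]]$leaves, c("pfu_1", "pfu_2"))

  t2 <- tre("((pfu_1,cgi_1)90,(pfu_2,cgi_2)88);")
  expect_length(find_lineage_specific_expansions(t2), 0)

  # nested monospecific clades collapse into one maximal call
  t3 <- tre("(((pfu_1,pfu_2)99,pfu_3)98,(cgi_1,cgi_2)97,lgi_1);")
  calls3 <- find_lineage_specific_expansions(t3)
  expect_length(calls3, 2)
  sizes <- sort(vapply(calls3, function(c) length(c$leaves), integer(1)))
  expect_equal(sizes, c(2L, 3L))
  # calls partition a subset of leaves: no leaf in two calls
  all_leaves <- unlist(lapply(calls3, `[[`, "leaves"))
  expect_false(anyDuplicated(all_leaves) > 0)

  expect_error(find_lineage_specific_expansions(tre("(nounderscore,pfu_1,pfu_2);")),
               "nounderscore")
})

test_that("tree calls match brute-force side enumeration on random trees", {
  for (s in 1:40) {
    tree <- random_support_tree(sample(8:20, 1), seed = 300 + s)
    got <- find_lineage_specific_expansions(tree)
    want <- oracle_expansions(tree)
    expect_identical(sort(vapply(got, function(c) paste(c$leaves, collapse = ","), "")),
                     sort(vapply(want, paste, collapse = ",", FUN.VALUE = "")))
    no_dup <- unlist(lapply(got, `[[`, "leaves"))
    expect_false(anyDuplicated(no_dup) > 0)
  }
})

test_that("ortholog pairs require a high-support cross-species cherry", {
  t85 <- tre("((pfu_1,cgi_1)85,(pfu_2,lgi_1)99);")
  res <- find_supported_ortholog_pairs(t85, "pfu", "cgi")
  expect_equal(res$pairs$leaf_a, "pfu_1")
  expect_equal(res$pairs$support, 85)

  t75 <- tre("((pfu_1,cgi_1)75,(pfu_2,lgi_1)99);")
  expect_equal(nrow(find_supported_ortholog_pairs(t75, "pfu", "cgi")$pairs), 0)

  tna <- tre("((pfu_1,cgi_1),(pfu_2,lgi_1)99);")
  resna <- find_supported_ortholog_pairs(tna, "pfu", "cgi")
  expect_equal(nrow(resna$pairs), 0)
  expect_equal(resna$warnings$leaf_a, "pfu_1")  # skipped, reported

  expect_error(find_supported_ortholog_pairs(t85, "pfu", "dme"),
               "both species")
})

test_that("fractional supports are rescaled at the reader", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((pfu_1,cgi_1)0.95,(pfu_2,lgi_1)0.5);", f)
  expect_message(trees <- read_gene_trees(f), "rescaling")
  res <- find_supported_ortholog_pairs(trees[[1]], "pfu", "cgi")
  expect_equal(res$pairs$support, 95)
})

test_that("ancestral groups are the minimal many-species sides, disjoint", {
  one <- tre("(((pfu_1,cgi_1)90,(lgi_1,hro_1)85)95,dme_1,dme_2);")
  r1 <- find_ancestral_groups(one, c("pfu", "cgi", "lgi", "hro"), 4)
  expect_equal(r1$count, 1L)
  expect_setequal(r1$groups[[1]]$leaves,
                  c("pfu_1", "cgi_1", "lgi_1", "hro_1"))

  r0 <- find_ancestral_groups(one, c("pfu", "cgi", "lgi"), 4)
  expect_equal(r0$count, 0L)

  two <- tre(paste0("(((pfu_1,cgi_1)90,(lgi_1,hro_1)85)95,",
                    "((pfu_2,cgi_2)91,(lgi_2,hro_2)86)96);"))
  r2 <- find_ancestral_groups(two, c("pfu", "cgi", "lgi", "hro"), 4,
                              min_support = 80)
  expect_equal(r2$count, 2L)
  expect_equal(r2$n_high_support, 2L)
  leaves <- unlist(lapply(r2$groups, `[[`, "leaves"))
  expect_false(anyDuplicated(leaves) > 0)
})

test_that("all calls are invariant under rerooting (bipartition semantics)", {
  for (s in 1:15) {
    tree <- random_support_tree(sample(8:16, 1), seed = 500 + s)
    key_exp <- function(t) sort(vapply(find_lineage_specific_expansions(t),
                                       function(c) paste(c$leaves, collapse = ","), ""))
    key_pair <- function(t) {
      p <- find_supported_ortholog_pairs(t, "pfu", "cgi")$pairs
      sort(paste(p$leaf_a, p$leaf_b))
    }
    sp <- sub("_.*", "", tree$tip.label)
    if (!all(c("pfu", "cgi") %in% sp)) next
    out <- sample(tree$tip.label, 1)
    rerooted <- ape::root(tree, outgroup = out, edgelabel = TRUE)
    expect_identical(key_exp(tree), key_exp(rerooted))
    expect_identical(key_pair(tree), key_pair(rerooted))
  }
})

test_that("planted tree structures are recovered exactly on noiseless fixtures", {
  tr <- generate_truth(noiseless_config(seed = 23))
  tws <- generate_gene_trees(tr)
  n_pairs <- 0L
  for (fam in names(tws)) {
    t <- tre(tws[[fam]])
    plan <- tr$trees[[fam]]
    got <- sort(vapply(find_lineage_specific_expansions(t),
                       function(c) paste(c$leaves, collapse = ","), ""))
    want <- sort(vapply(lapply(unname(plan$expansions), sort),
                        paste, collapse = ",", FUN.VALUE = ""))
    expect_identical(got, want)
    sp <- sub("_.*", "", t$tip.label)
    if (all(c("pfu", "cgi") %in% sp)) {
      p <- find_supported_ortholog_pairs(t, "pfu", "cgi")$pairs
      gp <- sort(paste(p$leaf_a, p$leaf_b))
      wp <- if (is.null(plan$pairs)) character(0) else
        sort(paste(plan$pairs$leaf_a, plan$pairs$leaf_b))
      expect_identical(gp, wp)
      n_pairs <- n_pairs + length(wp)
    }
  }
  expect_gt(n_pairs, 0)   # precision and recall both 1 over a nonempty set
})
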