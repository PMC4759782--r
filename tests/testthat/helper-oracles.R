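# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package: dense
# base-R matrices, direct enumeration, and O(n^2) scans.

# --- dense step-by-step Markov clustering on the whole matrix ---------------
oracle_mcl <- function(graph, inflation = 1.5, max_iter = 100, tol = 1e-6,
                       prune = 1e-5) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(list())
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    A[e$a[r], e$b[r]] <- e$weight[r]
    A[e$b[r], e$a[r]] <- e$weight[r]
  }
  for (j in seq_len(n)) A[j, j] <- max(A[, j], .Machine$double.eps)
  normalize <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) { M[cbind(which(zero), which(zero))] <- 1; cs[zero] <- 1 }
    sweep(M, 2, cs, "/")
  }
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- normalize(M2)
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  # clusters = connected components of the attractor support (BFS)
  supp <- (M != 0) | (t(M) != 0)
  seen <- rep(FALSE, n)
  clusters <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE; comp <- c(comp, v)
      queue <- c(queue, which(supp[v, ] & !seen))
    }
    clusters[[length(clusters) + 1L]] <- sort(nodes[comp])
  }
  clusters[order(vapply(clusters, `[`, "", 1))]
}

# canonical string form of a partition, for comparisons
partition_key <- function(clusters) {
  paste(sort(vapply(clusters, function(x) paste(sort(x), collapse = ","),
                    "")), collapse = ";")
}

random_simgraph <- function(n, edge_prob = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < edge_prob
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      weight = runif(sum(keep), 1, 50),
                      stringsAsFactors = FALSE)
  similarity_graph(edges, nodes = nodes)
}

# --- exhaustive hypergeometric upper tail -----------------------------------
oracle_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- N50 straight from the definition ---------------------------------------
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
}

# --- O(n^2) pairwise tandem linkage -----------------------------------------
oracle_tandem <- function(genes, max_intervening = 1L) {
  out <- list()
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (is.null(g$end)) g$end <- g$start
    g <- g[order(g$start, g$end, g$id), , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    fam <- g[!is.na(g$family) & g$family != NO_FAMILY, , drop = FALSE]
    for (f in unique(fam$family)) {
      sub <- fam[fam$family == f, , drop = FALSE]
      if (nrow(sub) < 2) next
      adj <- matrix(FALSE, nrow(sub), nrow(sub))
      for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub)))
        if (i != j && abs(sub$rank[i] - sub$rank[j]) - 1 <= max_intervening)
          adj[i, j] <- TRUE
      seen <- rep(FALSE, nrow(sub))
      for (s in seq_len(nrow(sub))) {
        if (seen[s]) next
        queue <- s; comp <- integer(0)
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          if (seen[v]) next
          seen[v] <- TRUE; comp <- c(comp, v)
          queue <- c(queue, which(adj[v, ] & !seen))
        }
        if (length(comp) >= 2)
          out[[length(out) + 1L]] <- list(
            scaffold = sc, family = f,
            members = sub$id[sort(comp)][order(sub$rank[sort(comp)])])
      }
    }
  }
  out
}

tandem_key <- function(members_list)
  sort(vapply(members_list, function(m) paste(m, collapse = ","), ""))

# --- brute-force bipartition sides by manual tree traversal -----------------
oracle_tree_sides <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", n + tree$Nnode)
  rec <- function(v) {
    if (v <= n) return(tips[v])
    s <- sort(unique(unlist(lapply(kids[[as.character(v)]], rec))))
    sets[[v]] <<- s
    s
  }
  rec(n + 1L)
  sup <- if (is.null(tree$node.label)) rep(NA_real_, tree$Nnode) else
    suppressWarnings(as.numeric(tree$node.label))
  sides <- list()
  if (tree$Nnode < 2) return(sides)
  for (v in (n + 2L):(n + tree$Nnode)) {
    s <- sets[[v]]
    for (side in list(s, setdiff(tips, s))) {
      if (length(side) < 2 || length(side) > n - 1) next
      key <- paste(sort(side), collapse = ",")
      old <- sides[[key]]
      sv <- sup[v - n]
      if (is.null(old) || (is.na(old$support) && !is.na(sv)) ||
          (!is.na(old$support) && !is.na(sv) && sv > old$support))
        sides[[key]] <- list(leaves = sort(side), support = sv)
    }
  }
  unname(sides)
}

oracle_expansions <- function(tree, min_size = 2) {
  sp <- setNames(sub("_.*$", "", tree$tip.label), tree$tip.label)
  if (length(unique(sp)) == 1)
    return(if (length(sp) >= min_size)
      list(sort(tree$tip.label)) else list())
  sides <- oracle_tree_sides(tree)
  cand <- Filter(function(s) length(s$leaves) >= min_size &&
                   length(unique(sp[s$leaves])) == 1, sides)
  leaves <- lapply(cand, `[[`, "leaves")
  keep <- vapply(seq_along(leaves), function(i)
    !any(vapply(seq_along(leaves), function(j)
      i != j && length(leaves[[i]]) < length(leaves[[j]]) &&
        all(leaves[[i]] %in% leaves[[j]]), logical(1))), logical(1))
  lapply(cand[keep], `[[`, "leaves")
}

random_support_tree <- function(n_leaves, species = c("pfu", "cgi", "lgi"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- sprintf("%s_t%02d", sample(species, n_leaves, replace = TRUE),
                  seq_len(n_leaves))
  tree <- ape::unroot(ape::rtree(n_leaves, tip.label = tips))
  tree$node.label <- as.character(sample(0:100, tree$Nnode, replace = TRUE))
  tree
}

# noiseless generator configuration shared by recovery tests
noiseless_config <- function(seed = 11, ...) {
  truth_config(seed = seed, edge_dropout_prob = 0,
               between_family_edge_prob = 0, ...)
}
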