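# Gene-tree interpretation: per-species domain-count tables and the
# figure-reading rules for unrooted bootstrap trees — lineage-specific
# expansion clades, high-support cross-species ortholog pairs, and ancestral
# copy groups spanning several species.
#
# The trees consumed here are unrooted in spirit (maximum-likelihood trees
# with bootstrap supports on internal nodes), so "clades" are defined as
# bipartition sides: for every internal edge both sides of the split are
# candidates, which makes all calls invariant under rerooting.

#' Species of each leaf
#'
#' @param tree a `phylo` object.
#' @param species_map optional named character vector (leaf -> species)
#'   overriding prefix parsing.
#' @return named character vector of species codes, one per leaf. Leaves
#'   without an underscore-delimited prefix and absent from the map raise an
#'   error naming the leaf.
#' @export
leaf_species <- function(tree, species_map = NULL) {
  tips <- tree$tip.label
  sp <- if (!is.null(species_map)) unname(species_map[tips]) else rep(NA_character_, length(tips))
  need <- is.na(sp)
  parsed <- sub("_.*$", "", tips[need])
  bad <- parsed == tips[need]
  if (any(bad))
    abort("cannot parse a species prefix from leaf '%s'", tips[need][bad][1])
  sp[need] <- parsed
  setNames(sp, tips)
}

# numeric supports from internal node labels (NA when absent/blank)
node_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}

# All bipartition sides of the tree with the support of their defining edge.
# Returns a list of entries: leaves (character), support (numeric, NA if
# absent). Trivial sides (single leaf or all leaves) are included only when
# `trivial = TRUE`. When the same side arises both as a node's own clade and
# as the complement of another node (a degree-2 root), the support recorded
# at the side's own subtending node takes precedence.
tree_sides <- function(tree, trivial = FALSE) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  sup <- node_supports(tree)
  sides <- list()
  add <- function(leaves, support, own_node) {
    if (!trivial && (length(leaves) < 2 || length(leaves) > n - 1)) return()
    key <- paste(sort(leaves), collapse = "\r")
    prev <- sides[[key]]
    if (is.null(prev) || (own_node && !prev$own_node))
      sides[[key]] <<- list(leaves = sort(leaves), support = support,
                            own_node = own_node)
  }
  for (i in seq_along(pp)) {
    if (i == 1) next  # root: trivial full split
    cl <- tips[pp[[i]]]
    add(cl, sup[i], own_node = TRUE)
    add(setdiff(tips, cl), sup[i], own_node = FALSE)
  }
  unname(lapply(sides, function(s) s[c("leaves", "support")]))
}

#' Per-species domain gene counts with length filters
#'
#' A gene counts once for a domain if it has at least one hit of that domain
#' whose matched length passes the domain's threshold (domains without a
#' listed threshold default to 1 aa).
#'
#' @param hits data frame with columns gene_id, species, domain, length.
#' @param min_length named integer vector of per-domain minimum matched
#'   lengths (e.g. `c(HSP70 = 200, C1q = 100)`).
#' @return data frame with columns species, domain, n_genes.
#' @export
domain_count_table <- function(hits, min_length = integer(0)) {
  stopifnot(all(c("gene_id", "species", "domain", "length") %in% names(hits)))
  if (length(min_length) && any(min_length < 1))
    abort("'min_length' thresholds must be >= 1")
  thr <- ifelse(hits$domain %in% names(min_length),
                min_length[hits$domain], 1L)
  h <- hits[hits$length >= thr, , drop = FALSE]
  h <- unique(h[, c("gene_id", "species", "domain")])
  if (nrow(h) == 0)
    return(data.frame(species = character(), domain = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(species = h$species, domain = h$domain),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  out <- data.frame(species = tab$species, domain = tab$domain,
                    n_genes = as.integer(tab$Freq), stringsAsFactors = FALSE)
  out <- out[order(out$domain, out$species), ]
  rownames(out) <- NULL
  out
}

#' Lineage-specific expansion clades of a gene tree
#'
#' Returns the maximal bipartition sides whose leaves all belong to one
#' species, with at least `min_size` leaves — the tree-reading for "the
#' clade comprises only one species, suggesting lineage-specific gene
#' expansion". Calls are pairwise disjoint. A tree whose leaves are all one
#' species yields a single call covering every leaf.
#'
#' @param tree a `phylo` object with species-prefixed leaf names.
#' @param min_size minimum clade size (default 2).
#' @param species_map optional leaf -> species override.
#' @return list of calls, each a list with `species` and `leaves`.
#' @export
find_lineage_specific_expansions <- function(tree, min_size = 2L,
                                             species_map = NULL) {
  sp <- leaf_species(tree, species_map)
  tips <- tree$tip.label
  if (length(unique(sp)) == 1) {
    if (length(tips) >= min_size)
      return(list(list(species = unname(sp[1]), leaves = sort(tips))))
    return(list())
  }
  sides <- tree_sides(tree)
  mono <- Filter(function(s) {
    length(s$leaves) >= min_size && length(unique(sp[s$leaves])) == 1
  }, sides)
  if (!length(mono)) return(list())
  # maximal under inclusion
  keep <- rep(TRUE, length(mono))
  for (i in seq_along(mono)) for (j in seq_along(mono)) {
    if (i != j && keep[i] &&
        length(mono[[i]]$leaves) < length(mono[[j]]$leaves) &&
        all(mono[[i]]$leaves %in% mono[[j]]$leaves))
      keep[i] <- FALSE
  }
  calls <- lapply(mono[keep], function(s)
    list(species = unname(sp[s$leaves[1]]), leaves = s$leaves))
  calls[order(vapply(calls, function(c) c$leaves[1], ""))]
}

#' High-support cross-species ortholog pairs (cherries)
#'
#' Two-leaf bipartition sides with one leaf from each requested species and
#' a defining-edge bootstrap support of at least `min_support`. Cherries
#' without a recorded support are skipped and listed in the `warnings`
#' element.
#'
#' @param tree a `phylo` object.
#' @param species_a,species_b the two species codes.
#' @param min_support minimum bootstrap support (default 80).
#' @param species_map optional leaf -> species override.
#' @return list with `pairs` (data frame: leaf_a, leaf_b, support) and
#'   `warnings` (data frame of skipped cherries lacking support).
#' @export
find_supported_ortholog_pairs <- function(tree, species_a, species_b,
                                          min_support = 80, species_map = NULL) {
  sp <- leaf_species(tree, species_map)
  if (!species_a %in% sp || !species_b %in% sp)
    abort("both species must be present among the leaves")
  sides <- tree_sides(tree)
  pairs <- list()
  warns <- list()
  for (s in sides) {
    if (length(s$leaves) != 2) next
    got <- sort(unname(sp[s$leaves]))
    if (!identical(got, sort(c(species_a, species_b)))) next
    la <- s$leaves[sp[s$leaves] == species_a]
    lb <- s$leaves[sp[s$leaves] == species_b]
    if (is.na(s$support)) {
      warns[[length(warns) + 1L]] <- data.frame(
        leaf_a = la, leaf_b = lb, reason = "no support value",
        stringsAsFactors = FALSE)
    } else if (s$support >= min_support) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        leaf_a = la, leaf_b = lb, support = s$support, stringsAsFactors = FALSE)
    }
  }
  empty_p <- data.frame(leaf_a = character(), leaf_b = character(),
                        support = numeric(), stringsAsFactors = FALSE)
  empty_w <- data.frame(leaf_a = character(), leaf_b = character(),
                        reason = character(), stringsAsFactors = FALSE)
  p <- if (length(pairs)) do.call(rbind, pairs) else empty_p
  p <- p[order(p$leaf_a), , drop = FALSE]
  rownames(p) <- NULL
  list(pairs = p,
       warnings = if (length(warns)) do.call(rbind, warns) else empty_w)
}

#' Ancestral copy groups: smallest clades uniting many species
#'
#' Finds the bipartition sides containing genes of at least `min_species`
#' distinct focal species and keeps the minimal such sides (none containing
#' another qualifying side). On a tree these are pairwise disjoint, and
#' their number estimates how many gene copies the focal species' common
#' ancestor carried: each ancestral copy founds one multi-species group.
#'
#' @param tree a `phylo` object.
#' @param focal_species character vector of species codes to count.
#' @param min_species minimum distinct focal species per group (default 4).
#' @param min_support if not `NULL`, also report how many groups have
#'   defining-edge support at or above this value.
#' @param species_map optional leaf -> species override.
#' @return list with `groups` (each: leaves, n_focal_species, support),
#'   `count`, and `n_high_support` (NA unless `min_support` given).
#' @export
find_ancestral_groups <- function(tree, focal_species, min_species = 4L,
                                  min_support = NULL, species_map = NULL) {
  if (!length(focal_species)) abort("'focal_species' must be nonempty")
  sp <- leaf_species(tree, species_map)
  sides <- tree_sides(tree, trivial = FALSE)
  qual <- Filter(function(s)
    length(unique(intersect(sp[s$leaves], focal_species))) >= min_species,
    sides)
  if (!length(qual))
    return(list(groups = list(), count = 0L, n_high_support = NA_integer_))
  # minimal under inclusion
  keep <- rep(TRUE, length(qual))
  for (i in seq_along(qual)) for (j in seq_along(qual)) {
    if (i != j && keep[i] &&
        length(qual[[j]]$leaves) < length(qual[[i]]$leaves) &&
        all(qual[[j]]$leaves %in% qual[[i]]$leaves))
      keep[i] <- FALSE
  }
  groups <- qual[keep]
  # guard against rare crossing sides: greedily keep disjoint groups,
  # smallest first
  groups <- groups[order(vapply(groups, function(g) length(g$leaves), 1L),
                         vapply(groups, function(g) g$leaves[1], ""))]
  taken <- character(0)
  sel <- list()
  for (g in groups) {
    if (!length(intersect(g$leaves, taken))) {
      sel[[length(sel) + 1L]] <- list(
        leaves = g$leaves,
        n_focal_species = length(unique(intersect(sp[g$leaves], focal_species))),
        support = g$support)
      taken <- c(taken, g$leaves)
    }
  }
  n_high <- if (is.null(min_support)) NA_integer_ else
    sum(vapply(sel, function(g) !is.na(g$support) && g$support >= min_support,
               logical(1)))
  list(groups = sel, count = length(sel), n_high_support = n_high)
}
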