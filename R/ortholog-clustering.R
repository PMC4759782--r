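# Similarity-graph construction, reference ortholog-family assignment, and
# de novo Markov clustering (MCL) of the residual graph.
#
# The scheme follows the canonical ortholog-clustering recipe: all-vs-all
# protein hits are thresholded at E <= 1e-5, transformed to -log10(E)
# weights (zero E-values capped), reciprocal hits averaged into one
# undirected edge, and the resulting column-stochastic matrix iterated
# through expansion (matrix self-multiplication) and inflation (elementwise
# powering with column renormalization) until it reaches an attractor whose
# connected support defines the clusters.

#' Construct a weighted similarity graph
#'
#' @param edges data frame with columns `a`, `b`, `weight` (one row per
#'   unordered pair, finite nonnegative weights).
#' @param nodes optional character vector of node ids (isolated nodes are
#'   allowed); defaults to the ids present in `edges`.
#' @param species optional named character vector mapping node id to species;
#'   defaults to the prefix before the first underscore.
#' @return object of class `mf_simgraph`.
#' @export
similarity_graph <- function(edges, nodes = NULL, species = NULL) {
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    abort("edge weights must be finite and nonnegative")
  if (any(edges$a == edges$b)) abort("self-edges are not allowed")
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  if (is.null(species)) species <- setNames(sub("_.*$", "", nodes), nodes)
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  if (anyDuplicated(key)) abort("at most one edge per unordered pair")
  out <- list(edges = edges[, c("a", "b", "weight")], nodes = nodes,
              species = species)
  class(out) <- "mf_simgraph"
  out
}

#' @export
print.mf_simgraph <- function(x, ...) {
  cat(sprintf("mf_simgraph: %d nodes, %d edges, %d species\n",
              length(x$nodes), nrow(x$edges), length(unique(x$species))))
  invisible(x)
}

#' Build a normalized similarity graph from BLAST-style hits
#'
#' Hits above the E-value cutoff are discarded; the weight of a hit is
#' `-log10(evalue)` with `evalue == 0` (and anything above the cap) mapped to
#' `weight_cap`; all directed hits for an unordered pair are averaged into a
#' single undirected edge; self-hits are dropped.
#'
#' @param hits data frame with columns qseqid, sseqid, evalue (e.g. from
#'   [read_blast_tab()]).
#' @param evalue_cutoff maximum E-value retained (default 1e-5).
#' @param weight_cap weight assigned to zero E-values (default 300).
#' @param species optional named node-to-species map.
#' @param rescale_between_species if TRUE, cross-species edge weights are
#'   divided by the mean weight of their species pair (a correction for
#'   between-proteome similarity bias); off by default.
#' @return an `mf_simgraph`.
#' @export
normalize_similarity_graph <- function(hits, evalue_cutoff = 1e-5,
                                       weight_cap = 300, species = NULL,
                                       rescale_between_species = FALSE) {
  stopifnot(all(c("qseqid", "sseqid", "evalue") %in% names(hits)))
  if (evalue_cutoff <= 0) abort("'evalue_cutoff' must be positive")
  if (any(hits$evalue < 0)) abort("negative e-value in hit table")
  h <- hits[hits$evalue <= evalue_cutoff & hits$qseqid != hits$sseqid, ,
            drop = FALSE]
  if (nrow(h) == 0)
    return(similarity_graph(data.frame(a = character(), b = character(),
                                       weight = numeric()), species = species))
  w <- -log10(h$evalue)
  w[!is.finite(w) | w > weight_cap] <- weight_cap
  a <- pmin(h$qseqid, h$sseqid)
  b <- pmax(h$qseqid, h$sseqid)
  agg <- tapply(w, paste(a, b, sep = "\r"), mean)
  ab <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(ab, `[`, "", 1), b = vapply(ab, `[`, "", 2),
                      weight = as.numeric(agg), stringsAsFactors = FALSE)
  g <- similarity_graph(edges, species = species)
  if (rescale_between_species) {
    spa <- g$species[g$edges$a]
    spb <- g$species[g$edges$b]
    cross <- spa != spb
    pair <- paste(pmin(spa, spb), pmax(spa, spb))
    mw <- tapply(g$edges$weight[cross], pair[cross], mean)
    g$edges$weight[cross] <- g$edges$weight[cross] / mw[pair[cross]]
  }
  g
}

#' Assign genes to reference ortholog families by best hit
#'
#' A gene that is itself listed in the reference membership table keeps its
#' listed family. Any other gene with at least one qualifying hit
#' (E <= cutoff) to a listed member is assigned to the family of its best
#' hit (maximal bitscore; ties broken by lower e-value, then by the
#' lexicographically smaller subject id). Genes without qualifying hits stay
#' unassigned.
#'
#' @param hits BLAST-style data frame (qseqid, sseqid, evalue, bitscore).
#' @param reference_members data frame with columns member_id, family.
#' @param evalue_cutoff maximum qualifying E-value (default 1e-5).
#' @return data frame with columns gene_id, family_id, source ("reference").
#' @export
assign_reference_families <- function(hits, reference_members,
                                      evalue_cutoff = 1e-5) {
  stopifnot(all(c("member_id", "family") %in% names(reference_members)))
  if (nrow(reference_members) == 0) abort("reference membership table is empty")
  if (any(is.na(reference_members$family) | reference_members$family == ""))
    abort("reference member '%s' has no family",
          reference_members$member_id[which(is.na(reference_members$family) |
                                            reference_members$family == "")[1]])
  fam_of <- setNames(reference_members$family, reference_members$member_id)
  h <- hits[hits$evalue <= evalue_cutoff &
            hits$sseqid %in% reference_members$member_id &
            hits$qseqid != hits$sseqid, , drop = FALSE]
  best <- map_synonyms(h)
  assigned <- data.frame(gene_id = names(best),
                         family_id = unname(fam_of[best]),
                         stringsAsFactors = FALSE)
  direct <- data.frame(gene_id = reference_members$member_id,
                       family_id = reference_members$family,
                       stringsAsFactors = FALSE)
  out <- rbind(direct, assigned[!assigned$gene_id %in% direct$gene_id, ,
                                drop = FALSE])
  out <- out[order(out$gene_id), , drop = FALSE]
  out$source <- "reference"
  rownames(out) <- NULL
  out
}

# column-normalize a sparse matrix, guarding all-zero columns with a
# diagonal unit (an isolated attractor)
col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering of a weighted similarity graph
#'
#' Iterates expansion (`M %*% M`) and inflation (elementwise power
#' `inflation` followed by column renormalization) on the column-stochastic
#' transition matrix of the graph (self-loops set to each node's maximum
#' incident weight), pruning entries below `prune` each iteration, until the
#' maximum absolute change falls below `tol`. Clusters are the connected
#' components of the converged attractor's nonzero support. Output is
#' deterministic: nodes are processed in lexicographic order.
#'
#' @param graph an `mf_simgraph` (or a data frame of edges `a`, `b`,
#'   `weight`).
#' @param inflation inflation exponent (> 1; default 1.5).
#' @param max_iter maximum iterations (default 100). If the iteration has
#'   not converged, the current attractor components are returned with a
#'   warning and `attr(,"converged") == FALSE`.
#' @param tol convergence tolerance on the max absolute matrix change.
#' @param prune entries below this are zeroed each iteration.
#' @return list of clusters (character vectors of node ids, each sorted),
#'   ordered by their smallest member; every node is in exactly one cluster
#'   and isolated nodes form singletons. Attribute `converged` reports
#'   convergence.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-6,
                        prune = 1e-5) {
  if (is.data.frame(graph)) graph <- similarity_graph(graph)
  stopifnot(inherits(graph, "mf_simgraph"))
  if (inflation <= 1) abort("'inflation' must be > 1")
  nodes <- graph$nodes
  if (length(nodes) == 0) return(structure(list(), converged = TRUE))
  edges <- graph$edges

  # isolated nodes are singleton clusters without entering the iteration
  connected <- sort(unique(c(edges$a, edges$b)))
  singles <- setdiff(nodes, connected)
  clusters <- lapply(singles, identity)

  converged_all <- TRUE
  if (length(connected)) {
    ig <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                        vertices = connected)
    comp <- igraph::components(ig)$membership[connected]
    for (cid in sort(unique(comp))) {
      cn <- sort(connected[comp == cid])
      ce <- edges[edges$a %in% cn, , drop = FALSE]
      ia <- match(ce$a, cn); ib <- match(ce$b, cn)
      A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                                x = rep(ce$weight, 2),
                                dims = c(length(cn), length(cn)))
      # self-loops at each node's maximum incident weight
      loops <- apply(A, 2, max)
      Matrix::diag(A) <- pmax(loops, .Machine$double.eps)
      M <- col_normalize(A)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        M2 <- M %*% M                      # expansion
        M2@x <- M2@x^inflation             # inflation
        M2 <- col_normalize(M2)
        M2@x[M2@x < prune] <- 0            # pruning for sparsity
        M2 <- Matrix::drop0(M2)
        M2 <- col_normalize(M2)
        if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
        M <- M2
      }
      converged_all <- converged_all && converged
      supp <- Matrix::summary(methods::as(M, "TsparseMatrix"))
      sg <- igraph::graph_from_data_frame(
        data.frame(a = cn[supp$i], b = cn[supp$j]),
        directed = FALSE, vertices = cn)
      mem <- igraph::components(sg)$membership[cn]
      clusters <- c(clusters, unname(split(cn, mem)))
    }
  }
  if (!converged_all)
    warning("MCL did not converge within max_iter; returning current attractor components",
            call. = FALSE)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  structure(clusters, converged = converged_all)
}

#' Cluster reference-unassigned genes de novo and complete the assignment
#'
#' The subgraph induced on genes without a reference family is Markov
#' clustered; clusters of two or more genes become de novo families
#' (`DNV0001`, ... numbered by smallest member id); genes left alone are
#' orphan candidates (source `"none"`).
#'
#' @param graph an `mf_simgraph` over all genes.
#' @param reference_assignment data frame from
#'   [assign_reference_families()].
#' @param inflation MCL inflation (default 1.5).
#' @param all_genes optional character vector of every gene id under study;
#'   genes absent from the graph are appended as orphan candidates.
#' @return complete family assignment: data frame with columns gene_id,
#'   species, family_id, source (`reference`, `de_novo`, or `none`; the
#'   family of `none` genes is [NO_FAMILY]).
#' @export
cluster_unassigned <- function(graph, reference_assignment, inflation = 1.5,
                               all_genes = NULL) {
  stopifnot(inherits(graph, "mf_simgraph"))
  universe <- sort(unique(c(graph$nodes, all_genes,
                            reference_assignment$gene_id)))
  un <- setdiff(universe, reference_assignment$gene_id)
  sub_edges <- graph$edges[graph$edges$a %in% un & graph$edges$b %in% un, ,
                           drop = FALSE]
  sub <- similarity_graph(sub_edges, nodes = intersect(un, graph$nodes))
  cl <- mcl_cluster(sub, inflation = inflation)
  fams <- Filter(function(x) length(x) >= 2, cl)
  fam_ids <- sprintf("DNV%04d", seq_along(fams))
  denovo <- if (length(fams)) data.frame(
    gene_id = unlist(fams),
    family_id = rep(fam_ids, lengths(fams)), source = "de_novo",
    stringsAsFactors = FALSE) else
    data.frame(gene_id = character(), family_id = character(),
               source = character(), stringsAsFactors = FALSE)
  rest <- setdiff(un, denovo$gene_id)
  none <- data.frame(gene_id = rest, family_id = NO_FAMILY, source = "none",
                     stringsAsFactors = FALSE)
  ref <- reference_assignment[, c("gene_id", "family_id", "source")]
  out <- rbind(ref, denovo, none)
  sp <- graph$species
  out$species <- ifelse(out$gene_id %in% names(sp), sp[out$gene_id],
                        sub("_.*$", "", out$gene_id))
  out <- out[order(out$gene_id), c("gene_id", "species", "family_id", "source")]
  rownames(out) <- NULL
  out
}

#' One-call family assignment: reference best-hit plus de novo MCL
#'
#' @param hits BLAST-style all-vs-all hit table.
#' @param reference_members reference membership table (member_id, family).
#' @param all_genes optional full gene universe (hit-less genes become
#'   orphan candidates).
#' @param evalue_cutoff,weight_cap,inflation see
#'   [normalize_similarity_graph()] and [mcl_cluster()].
#' @return complete family assignment data frame (see
#'   [cluster_unassigned()]).
#' @export
assign_families <- function(hits, reference_members, all_genes = NULL,
                            evalue_cutoff = 1e-5, weight_cap = 300,
                            inflation = 1.5) {
  g <- normalize_similarity_graph(hits, evalue_cutoff = evalue_cutoff,
                                  weight_cap = weight_cap)
  ref <- assign_reference_families(hits, reference_members,
                                   evalue_cutoff = evalue_cutoff)
  cluster_unassigned(g, ref, inflation = inflation, all_genes = all_genes)
}
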