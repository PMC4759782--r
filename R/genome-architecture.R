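# Genome architecture: tandem-array detection, ordered gene-cluster layout
# reports (Hox/ParaHox/Wnt style), and assembly summary statistics.

#' Detect tandem arrays of family members on scaffolds
#'
#' Genes on each scaffold are ranked by start coordinate (ties by end, then
#' id). Two genes of the same family are linked when at most
#' `max_intervening` other genes lie between their ranks; arrays are the
#' connected components of this linkage with at least two members, reported
#' maximal.
#'
#' @param genes data frame with columns id, scaffold, start, family (end
#'   optional for tie-breaks). Genes with family `NA` or [NO_FAMILY] are
#'   treated as non-members.
#' @param max_intervening maximum intervening non-member genes between
#'   consecutive array members (default 1).
#' @return data frame with one row per array: scaffold, family, n_members,
#'   max_intervening_observed, and a list column `members` of gene ids in
#'   rank order.
#' @export
detect_tandem_arrays <- function(genes, max_intervening = 1L) {
  stopifnot(all(c("id", "scaffold", "start", "family") %in% names(genes)))
  if (anyDuplicated(genes$id))
    abort("duplicated gene id '%s'", genes$id[duplicated(genes$id)][1])
  if (max_intervening < 0) abort("'max_intervening' must be >= 0")
  if (is.null(genes$end)) genes$end <- genes$start
  out <- list()
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start, g$end, g$id), , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g <- g[!is.na(g$family) & g$family != NO_FAMILY, , drop = FALSE]
    for (fam in unique(g$family)) {
      r <- g$rank[g$family == fam]
      ids <- g$id[g$family == fam]
      if (length(r) < 2) next
      # split where the rank gap exceeds the window
      brk <- cumsum(c(0L, diff(r) > max_intervening + 1L))
      for (piece in split(seq_along(r), brk)) {
        if (length(piece) < 2) next
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, family = fam, n_members = length(piece),
          max_intervening_observed = max(diff(r[piece])) - 1L,
          members = I(list(ids[piece])), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), family = character(),
                      n_members = integer(),
                      max_intervening_observed = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ordered layout of labeled gene clusters on scaffolds
#'
#' For every scaffold carrying at least one labeled gene, reports the genes
#' in coordinate order with their labels (unlabeled genes as
#' `"NON_MEMBER"`), strand, and the interruption runs: the counts of
#' consecutive non-member models flanking and between consecutive members.
#' A cluster spread over several scaffolds is reported as split.
#'
#' @param genes data frame with columns id, scaffold, start, strand (end
#'   optional).
#' @param labels named character vector (names = gene ids) or data frame
#'   with columns gene_id, label.
#' @return object of class `mf_layout`: list with `layouts` (one entry per
#'   scaffold: scaffold, entries data frame, interruptions integer vector of
#'   length members + 1) and `n_scaffolds`.
#' @export
cluster_layout_report <- function(genes, labels) {
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$gene_id)
  unknown <- setdiff(names(labels), genes$id)
  if (length(unknown)) abort("label references unknown gene '%s'", unknown[1])
  if (is.null(genes$end)) genes$end <- genes$start
  layouts <- list()
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start, g$end, g$id), , drop = FALSE]
    lab <- ifelse(g$id %in% names(labels), labels[g$id], "NON_MEMBER")
    if (!any(lab != "NON_MEMBER")) next
    member <- lab != "NON_MEMBER"
    # run-length over the member mask gives flanking/intervening counts
    runs <- rle(member)
    interruptions <- integer(sum(member) + 1L)
    slot <- 1L
    for (i in seq_along(runs$lengths)) {
      if (runs$values[i]) slot <- slot + runs$lengths[i]
      else interruptions[slot] <- runs$lengths[i]
    }
    layouts[[length(layouts) + 1L]] <- list(
      scaffold = sc,
      entries = data.frame(id = g$id, label = lab, strand = g$strand,
                           start = g$start, stringsAsFactors = FALSE),
      interruptions = interruptions)
  }
  out <- list(layouts = layouts, n_scaffolds = length(layouts))
  class(out) <- "mf_layout"
  out
}

#' @export
print.mf_layout <- function(x, ...) {
  cat(sprintf("gene-cluster layout: labeled genes on %d scaffold(s)%s\n",
              x$n_scaffolds,
              if (x$n_scaffolds > 1) " (cluster is split)" else ""))
  for (ly in x$layouts) {
    mm <- ly$entries[ly$entries$label != "NON_MEMBER", ]
    cat(sprintf("  %s: %s\n", ly$scaffold,
                paste(sprintf("%s(%s)", mm$label, mm$strand), collapse = " - ")))
    cat(sprintf("    interruptions (flank/between/flank): %s\n",
                paste(ly$interruptions, collapse = ", ")))
  }
  invisible(x)
}

#' Assembly sequence set
#'
#' @param lengths positive sequence lengths in bases.
#' @param gaps per-sequence gap (N-run) lengths in bases; recycled 0.
#' @return object of class `mf_assembly`.
#' @export
assembly_set <- function(lengths, gaps = 0) {
  if (length(lengths) && any(lengths <= 0)) abort("sequence lengths must be positive")
  gaps <- rep_len(gaps, length(lengths))
  if (any(gaps > lengths)) abort("gap length exceeds sequence length")
  l <- as.numeric(lengths); names(l) <- names(lengths)
  g <- as.numeric(gaps); names(g) <- names(lengths)
  structure(list(lengths = l, gaps = g), class = "mf_assembly")
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together cover at
#' least half the total assembly length.
#'
#' @param lengths positive sequence lengths.
#' @return the N50 (always one of the input lengths).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) abort("sequence lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param assembly an `mf_assembly` (see [assembly_set()],
#'   [read_assembly_fasta()]).
#' @return list with n_sequences, total_length, total_gap_length,
#'   average_length, n50 (all in bases) and the kb/Mb renderings rounded
#'   half-up to one decimal (average_length_kb, n50_kb, total_length_mb,
#'   total_gap_mb).
#' @export
assembly_summary <- function(assembly) {
  stopifnot(inherits(assembly, "mf_assembly"))
  total <- sum(assembly$lengths)
  cnt <- length(assembly$lengths)
  v <- n50(assembly$lengths)
  list(n_sequences = cnt,
       total_length = total,
       total_gap_length = sum(assembly$gaps),
       average_length = total / cnt,
       n50 = v,
       average_length_kb = round_half_up(total / cnt / 1e3, 1),
       n50_kb = round_half_up(v / 1e3, 1),
       total_length_mb = round_half_up(total / 1e6, 1),
       total_gap_mb = round_half_up(sum(assembly$gaps) / 1e6, 1))
}
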