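# Hypergeometric GO-term enrichment of a foreground gene set against a
# background, following the convention of flagging on the raw upper-tail
# p-value (p < alpha) while also reporting Benjamini-Hochberg q-values.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts annotated genes among `n` drawn without
#' replacement from `N` genes of which `K` are annotated.
#'
#' @param N background size.
#' @param K background genes carrying the term.
#' @param n foreground size.
#' @param k foreground genes carrying the term.
#' @return the tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (K < 0 || K > N) abort("bounds violated: need 0 <= K <= N")
  if (n < 0 || n > N) abort("bounds violated: need 0 <= n <= N")
  if (k < 0 || k > min(n, K)) abort("bounds violated: need 0 <= k <= min(n, K)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO-term enrichment of a foreground against a background
#'
#' One test per term occurring in the background. Genes with no annotation
#' stay in the urn unless `annotated_only = TRUE`, which restricts both sets
#' to annotated genes (the "percentage of all annotated genes" convention).
#'
#' @param foreground character vector of foreground gene ids (must be a
#'   subset of the background).
#' @param background character vector of background gene ids.
#' @param go data frame with columns gene_id, term (see [read_go_table()]).
#' @param alpha raw-p significance threshold for the `enriched` flag
#'   (default 0.01).
#' @param annotated_only restrict the universe to annotated genes.
#' @return data frame with one row per term: term, K, k, p_raw, q_bh,
#'   enriched; sorted by p_raw. Attributes `N` and `n` carry the universe
#'   and foreground sizes used.
#' @export
enrich_go_terms <- function(foreground, background, go, alpha = 0.01,
                            annotated_only = FALSE) {
  stopifnot(all(c("gene_id", "term") %in% names(go)))
  foreground <- unique(foreground)
  background <- unique(background)
  missing_fg <- setdiff(foreground, background)
  if (length(missing_fg))
    abort("foreground gene '%s' absent from background", missing_fg[1])
  go <- unique(go[go$gene_id %in% background, c("gene_id", "term")])
  if (annotated_only) {
    annotated <- unique(go$gene_id)
    background <- intersect(background, annotated)
    foreground <- intersect(foreground, annotated)
  }
  N <- length(background)
  n <- length(foreground)
  terms <- sort(unique(go$term))
  if (length(terms) == 0) abort("no GO terms occur in the background")
  K <- vapply(split(go$gene_id, go$term), length, integer(1))[terms]
  in_fg <- go$gene_id %in% foreground
  kk <- table(factor(go$term[in_fg], levels = terms))
  k <- as.integer(kk)
  p <- vapply(seq_along(terms), function(i)
    hypergeometric_tail(N, K[[i]], n, k[i]), numeric(1))
  out <- data.frame(term = terms, K = as.integer(K), k = k, p_raw = p,
                    q_bh = stats::p.adjust(p, method = "BH"),
                    enriched = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term), ]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "n") <- n
  out
}
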