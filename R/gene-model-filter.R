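# Gene-model retention cascade with stage-by-stage accounting, and
# version-to-version synonymy mapping.
#
# The cascade mirrors how predicted gene models are audited before
# comparative analysis: discard models shorter than 50 aa, discard models
# matching transposable elements, then discard "orphan" models (ones that
# clustered with nothing) lacking transcriptomic evidence. The ledger
# records every stage so that totals like "29,353 retained" are reproducible
# arithmetic rather than narrative.

#' Construct a gene-model table
#'
#' @param id,species,scaffold,start,end,strand,protein_length,has_start_codon,has_stop_codon
#'   vectors of equal length describing predicted gene models (1-based
#'   inclusive coordinates).
#' @return data frame of class `mf_gene_models`.
#' @export
gene_models <- function(id, species, scaffold = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_, protein_length,
                        has_start_codon = NA, has_stop_codon = NA) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   species = rep_len(as.character(species), n),
                   scaffold = rep_len(scaffold, n),
                   start = rep_len(start, n), end = rep_len(end, n),
                   strand = rep_len(strand, n),
                   protein_length = rep_len(protein_length, n),
                   has_start_codon = rep_len(has_start_codon, n),
                   has_stop_codon = rep_len(has_stop_codon, n),
                   stringsAsFactors = FALSE)
  dup <- df[duplicated(df[c("id", "species")]), "id"]
  if (length(dup)) abort("duplicated model id within species: '%s'", dup[1])
  bad <- which(!is.na(df$start) & !is.na(df$end) & df$start > df$end)
  if (length(bad)) abort("model '%s': start > end", df$id[bad[1]])
  class(df) <- c("mf_gene_models", "data.frame")
  df
}

#' Retain gene models encoding at least `min_aa` amino acids
#'
#' @param models gene-model data frame (needs `id` and `protein_length`).
#' @param min_aa minimum protein length kept (default 50, i.e. models
#'   encoding more than 49 amino acids are retained).
#' @return list with `kept` and `removed` data frames (disjoint, exhaustive).
#' @export
apply_length_filter <- function(models, min_aa = 50L) {
  if (any(is.na(models$protein_length)))
    abort("model '%s' has no protein_length",
          models$id[which(is.na(models$protein_length))[1]])
  keep <- models$protein_length >= min_aa
  list(kept = models[keep, , drop = FALSE],
       removed = models[!keep, , drop = FALSE])
}

#' Remove gene models flagged as transposable-element-like
#'
#' @param models gene-model data frame.
#' @param te_hits character vector of model ids with significant TE
#'   similarity. Ids not present among the models are tolerated with a
#'   warning.
#' @return list with `kept` and `removed` data frames.
#' @export
apply_te_filter <- function(models, te_hits) {
  te_hits <- unique(as.character(te_hits))
  unknown <- setdiff(te_hits, models$id)
  if (length(unknown))
    warning(sprintf("%d TE hit id(s) not among the models (e.g. '%s')",
                    length(unknown), unknown[1]), call. = FALSE)
  rm <- models$id %in% te_hits
  list(kept = models[!rm, , drop = FALSE], removed = models[rm, , drop = FALSE])
}

#' Remove orphan gene models lacking transcriptomic evidence
#'
#' Only models that clustered with nothing (`clusterless_ids`) are candidates
#' for removal; among those, the ones absent from the transcript-evidence set
#' are discarded as faulty predictions. Clustered models are kept regardless
#' of evidence.
#'
#' @param models gene-model data frame.
#' @param clusterless_ids ids that joined no family ("orphan candidates").
#' @param evidence_ids ids with transcriptomic evidence.
#' @return list with `kept` and `removed` data frames.
#' @export
apply_orphan_evidence_filter <- function(models, clusterless_ids, evidence_ids) {
  rm <- models$id %in% clusterless_ids & !models$id %in% evidence_ids
  list(kept = models[!rm, , drop = FALSE], removed = models[rm, , drop = FALSE])
}

#' Full-length and database-annotation statistics of a retained model set
#'
#' Full-length means both a start and a stop codon. Percentages are
#' `100 * count / n_retained`, rounded half-up to one decimal as printed in
#' genome-paper tables.
#'
#' @param retained retained gene-model data frame.
#' @param db_hit_ids ids with a database (e.g. UniProtKB, E <= 1e-5) hit.
#' @return list with n_full_length, pct_full_length, n_db_annotated,
#'   pct_db_annotated.
#' @export
model_statistics <- function(retained, db_hit_ids) {
  n <- nrow(retained)
  if (n == 0)
    abort("percentages are undefined for an empty retained set")
  full <- !is.na(retained$has_start_codon) & retained$has_start_codon &
          !is.na(retained$has_stop_codon) & retained$has_stop_codon
  n_full <- sum(full)
  n_db <- sum(retained$id %in% db_hit_ids)
  list(n_full_length = n_full,
       pct_full_length = round_half_up(100 * n_full / n, 1),
       n_db_annotated = n_db,
       pct_db_annotated = round_half_up(100 * n_db / n, 1))
}

#' Run the full gene-model retention cascade
#'
#' Stages are applied in the fixed order length -> transposable element ->
#' orphan evidence, with every model accounted for in exactly one bin.
#'
#' @param models gene-model data frame.
#' @param te_hits ids with TE similarity.
#' @param clusterless_ids ids that clustered with nothing.
#' @param evidence_ids ids with transcriptomic evidence.
#' @param db_hit_ids ids with a protein-database hit (for the statistics
#'   block; optional).
#' @param min_aa minimum protein length (default 50).
#' @return list with `ledger` (class `mf_filter_ledger`) and `retained`
#'   (data frame). The ledger satisfies
#'   `n_initial == n_removed_short + n_removed_te + n_removed_no_evidence + n_retained`.
#' @export
run_cascade <- function(models, te_hits = character(0),
                        clusterless_ids = character(0),
                        evidence_ids = character(0),
                        db_hit_ids = character(0), min_aa = 50L) {
  s1 <- apply_length_filter(models, min_aa)
  stray <- setdiff(te_hits, models$id)
  if (length(stray))
    warning(sprintf("%d TE hit id(s) not among the models (e.g. '%s')",
                    length(stray), stray[1]), call. = FALSE)
  # ids already removed by the length stage are not stray: stay silent
  s2 <- suppressWarnings(apply_te_filter(s1$kept, te_hits))
  s3 <- apply_orphan_evidence_filter(s2$kept, clusterless_ids, evidence_ids)
  retained <- s3$kept
  n_orphan_candidates <- sum(s2$kept$id %in% clusterless_ids)
  stats <- if (nrow(retained) > 0) model_statistics(retained, db_hit_ids) else
    list(n_full_length = 0L, pct_full_length = NA_real_,
         n_db_annotated = 0L, pct_db_annotated = NA_real_)
  ledger <- c(list(n_initial = nrow(models),
                   n_removed_short = nrow(s1$removed),
                   n_removed_te = nrow(s2$removed),
                   n_orphan_candidates = n_orphan_candidates,
                   n_removed_no_evidence = nrow(s3$removed),
                   n_retained = nrow(retained)),
              stats)
  stopifnot(ledger$n_initial == ledger$n_removed_short + ledger$n_removed_te +
              ledger$n_removed_no_evidence + ledger$n_retained)
  class(ledger) <- "mf_filter_ledger"
  list(ledger = ledger, retained = retained)
}

#' @export
print.mf_filter_ledger <- function(x, ...) {
  cat(sprintf(paste0(
    "gene-model filter ledger\n",
    "  initial models:        %d\n",
    "  removed (< min aa):    %d\n",
    "  removed (TE-like):     %d\n",
    "  orphan candidates:     %d\n",
    "  removed (no evidence): %d\n",
    "  retained:              %d\n",
    "  full length:           %d (%s %%)\n",
    "  database annotated:    %d (%s %%)\n"),
    x$n_initial, x$n_removed_short, x$n_removed_te, x$n_orphan_candidates,
    x$n_removed_no_evidence, x$n_retained, x$n_full_length,
    format(x$pct_full_length), x$n_db_annotated, format(x$pct_db_annotated)))
  invisible(x)
}

#' Map new gene-model ids to their best-matching old ids
#'
#' For each query the subject with maximal bitscore is taken as the synonym;
#' ties go to the lower e-value, then to the lexicographically smaller
#' subject id. Queries with no hits are absent from the mapping.
#'
#' @param hits BLAST-style data frame with columns qseqid, sseqid, evalue,
#'   bitscore (e.g. from [read_blast_tab()]).
#' @return named character vector: `mapping[new_id] == old_id`.
#' @export
map_synonyms <- function(hits) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    abort("hit table must have columns %s", paste(need, collapse = ", "))
  bad <- which(is.na(hits$bitscore) | is.na(hits$evalue))
  if (length(bad)) abort("malformed hit row at line %d", bad[1])
  if (nrow(hits) == 0) return(setNames(character(0), character(0)))
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, ]
  best <- h[!duplicated(h$qseqid), ]
  setNames(best$sseqid, best$qseqid)
}
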