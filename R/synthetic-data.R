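# Synthetic three-genome generator with planted family structure.
#
# Every downstream stage of the pipeline (filtering, clustering,
# classification, enrichment, architecture, tree calls) is validated against
# fixtures produced here, where the complete ground truth is known.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the length-1 numeric pitfall
sample_from <- function(v, n = 1, replace = FALSE)
  v[sample.int(length(v), n, replace = replace)]

# Sub-stream offsets: changing one config field must not perturb unrelated
# tables, so each generator stage draws from its own stream.
.STREAM <- c(families = 1L, edges = 2L, annotations = 3L, trees = 4L,
             sequences = 5L)

#' Configuration for the synthetic multi-genome generator
#'
#' Defines the planted structure of a three-genome benchmark: reference-shared
#' families (present in an external ortholog database), mollusc-shared de novo
#' families (in at least two species but absent from the reference), expanded
#' lineage-specific families, orphan genes, planted tandem arrays, enriched GO
#' terms, and deliberately faulty gene models (short and transposon-like).
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param species character vector of 3 unique short species codes. Gene
#'   identifiers are prefixed with the code followed by an underscore.
#' @param n_reference_families number of families present in the reference
#'   ortholog database (and in all species).
#' @param n_shared_families number of de novo families shared by >= 2 species.
#' @param n_lineage_specific number of expanded single-species families per
#'   species.
#' @param expansion_copies integer pair, min/max gene copies per
#'   lineage-specific family (min >= 2).
#' @param n_orphans orphan genes (no family, no similarity) per species.
#' @param within_family_weight_range positive pair: similarity weights
#'   (-log10 E-value) drawn uniformly for within-family hits.
#' @param between_family_edge_prob probability of a spurious hit between two
#'   genes of different families.
#' @param between_family_weight_range positive pair: weight range for
#'   spurious between-family hits.
#' @param edge_dropout_prob probability that a within-family ordered hit is
#'   not emitted.
#' @param n_scaffolds scaffolds per species (must be >= the largest family
#'   copy number within one species, so that non-tandem relatives can be
#'   placed on distinct scaffolds).
#' @param tandem_arrays list of planted arrays, each a list with elements
#'   `family`, `scaffold`, `copies`, `max_intervening`. Defaults to two
#'   arrays in the first lineage-specific family of the first two species;
#'   empty when `n_lineage_specific` is 0.
#' @param go_term_universe number of GO terms in the universe.
#' @param background_term_prob per-gene probability of carrying any given
#'   non-enriched term (and of background genes carrying an enriched term).
#' @param enriched_terms data frame with columns `term`, `fg_prob`: terms
#'   attached to foreground genes at `fg_prob` instead of the background
#'   probability. Foreground = genes of shared families private to the first
#'   two species (the "bivalve-specific" set).
#' @param evidence_missing_prob probability that a planted orphan lacks
#'   transcript evidence (and is therefore removed by the evidence filter).
#' @param short_model_count total planted faulty models with protein length
#'   < 50 aa (split round-robin across species).
#' @param te_model_count total planted transposable-element-like models.
#' @return an object of class `mf_config` (a validated list).
#' @seealso [generate_truth()]
#' @export
truth_config <- function(seed = 1L,
                         species = c("pfu", "cgi", "lgi"),
                         n_reference_families = 60L,
                         n_shared_families = 20L,
                         n_lineage_specific = 12L,
                         expansion_copies = c(2L, 6L),
                         n_orphans = 20L,
                         within_family_weight_range = c(20, 180),
                         between_family_edge_prob = 0.01,
                         between_family_weight_range = c(1, 6),
                         edge_dropout_prob = 0.05,
                         n_scaffolds = 8L,
                         tandem_arrays = NULL,
                         go_term_universe = 50L,
                         background_term_prob = 0.05,
                         enriched_terms = NULL,
                         evidence_missing_prob = 0.25,
                         short_model_count = 9L,
                         te_model_count = 9L) {
  if (!is.character(species) || length(species) != 3 || anyDuplicated(species))
    abort("'species' must be 3 unique short codes")
  if (grepl("_", paste(species, collapse = "")))
    abort("'species' codes must not contain underscores")
  check_count(seed, "seed")
  check_count(n_reference_families, "n_reference_families")
  check_count(n_shared_families, "n_shared_families")
  check_count(n_lineage_specific, "n_lineage_specific")
  check_count(n_orphans, "n_orphans")
  check_count(n_scaffolds, "n_scaffolds", min = 1)
  check_count(go_term_universe, "go_term_universe")
  check_count(short_model_count, "short_model_count")
  check_count(te_model_count, "te_model_count")
  check_prob(between_family_edge_prob, "between_family_edge_prob")
  check_prob(edge_dropout_prob, "edge_dropout_prob")
  check_prob(background_term_prob, "background_term_prob")
  check_prob(evidence_missing_prob, "evidence_missing_prob")
  check_range(within_family_weight_range, "within_family_weight_range")
  check_range(between_family_weight_range, "between_family_weight_range")
  if (!is.numeric(expansion_copies) || length(expansion_copies) != 2 ||
      expansion_copies[1] < 2 || expansion_copies[1] > expansion_copies[2])
    abort("'expansion_copies' must be an ordered pair with min >= 2")

  if (is.null(tandem_arrays)) {
    tandem_arrays <- if (n_lineage_specific >= 1) list(
      list(family = sprintf("LSP_%s_001", species[1]),
           scaffold = sprintf("%s_s01", species[1]),
           copies = 3L, max_intervening = 1L),
      list(family = sprintf("LSP_%s_001", species[2]),
           scaffold = sprintf("%s_s01", species[2]),
           copies = 2L, max_intervening = 0L)
    ) else list()
  }
  for (ta in tandem_arrays) {
    if (!all(c("family", "scaffold", "copies", "max_intervening") %in% names(ta)))
      abort("'tandem_arrays' entries need family, scaffold, copies, max_intervening")
    if (ta$copies < 2) abort("'tandem_arrays': copies must be >= 2")
    if (ta$max_intervening < 0) abort("'tandem_arrays': max_intervening must be >= 0")
  }

  if (is.null(enriched_terms)) {
    enriched_terms <- if (go_term_universe >= 33)
      data.frame(term = sprintf("GO:%07d", c(5L, 12L, 33L)),
                 fg_prob = 0.5, stringsAsFactors = FALSE)
    else data.frame(term = character(), fg_prob = numeric())
  }
  if (nrow(enriched_terms) > 0) {
    if (!all(c("term", "fg_prob") %in% names(enriched_terms)))
      abort("'enriched_terms' must have columns term, fg_prob")
    vapply(enriched_terms$fg_prob, check_prob, numeric(1), name = "enriched_terms$fg_prob")
  }

  cfg <- list(seed = as.integer(seed), species = species,
              n_reference_families = as.integer(n_reference_families),
              n_shared_families = as.integer(n_shared_families),
              n_lineage_specific = as.integer(n_lineage_specific),
              expansion_copies = as.integer(expansion_copies),
              n_orphans = as.integer(n_orphans),
              within_family_weight_range = as.numeric(within_family_weight_range),
              between_family_edge_prob = between_family_edge_prob,
              between_family_weight_range = as.numeric(between_family_weight_range),
              edge_dropout_prob = edge_dropout_prob,
              n_scaffolds = as.integer(n_scaffolds),
              tandem_arrays = tandem_arrays,
              go_term_universe = as.integer(go_term_universe),
              background_term_prob = background_term_prob,
              enriched_terms = enriched_terms,
              evidence_missing_prob = evidence_missing_prob,
              short_model_count = as.integer(short_model_count),
              te_model_count = as.integer(te_model_count))
  class(cfg) <- "mf_config"
  cfg
}

#' Generate the planted ground truth for a synthetic benchmark
#'
#' Draws the gene inventory, family memberships, reference-database
#' representatives, tandem-array memberships, the enrichment foreground, and
#' the per-family tree plan (expansion clades and ortholog pairs). All
#' randomness comes from the `families` sub-stream of `config$seed`, so the
#' same config always yields the identical truth set.
#'
#' @param config an [truth_config()] object.
#' @return an object of class `mf_truth`: a list with elements `genes`
#'   (data frame: id, species, family, category, protein_length, has_start,
#'   has_stop), `families` (data frame: family, category, species_combo,
#'   n_members), `reference_members` (data frame: member_id, family),
#'   `tandem` (list of planted arrays with member gene ids), `trees` (per
#'   family: member table, planted expansions, planted ortholog pairs),
#'   `foreground` (gene ids for GO enrichment), `enriched_terms`, `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "mf_config"))
  with_seed(config$seed + .STREAM[["families"]], {
    S <- config$species
    counters <- setNames(rep(0L, 3), S)
    gene_rows <- list()
    fam_rows <- list()

    new_genes <- function(sp, n, family, category, len_range = c(100L, 600L)) {
      ids <- sprintf("%s_g%04d", sp, counters[[sp]] + seq_len(n))
      counters[[sp]] <<- counters[[sp]] + n
      data.frame(id = ids, species = sp, family = family, category = category,
                 protein_length = sample(len_range[1]:len_range[2], n, replace = TRUE),
                 has_start = runif(n) < 0.9, has_stop = runif(n) < 0.9,
                 stringsAsFactors = FALSE)
    }

    # how many copies each tandem spec demands of its family
    tandem_demand <- setNames(
      vapply(config$tandem_arrays, function(ta) as.integer(ta$copies), integer(1)),
      vapply(config$tandem_arrays, function(ta) ta$family, character(1)))

    # reference families: present in all species, 1-2 copies each
    for (i in seq_len(config$n_reference_families)) {
      fam <- sprintf("REF%03d", i)
      for (sp in S) gene_rows[[length(gene_rows) + 1L]] <-
        new_genes(sp, sample(1:2, 1), fam, "reference")
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family = fam, category = "reference",
                   species_combo = species_combo_key(S))
    }

    # shared de novo families: species subsets cycle so all pairwise and the
    # triple combination are planted; first-two-species private families form
    # the enrichment foreground
    combos <- list(S[c(1, 2)], S[c(2, 3)], S[c(1, 3)], S)
    for (i in seq_len(config$n_shared_families)) {
      fam <- sprintf("SHA%03d", i)
      combo <- combos[[((i - 1L) %% 4L) + 1L]]
      for (sp in combo) gene_rows[[length(gene_rows) + 1L]] <-
        new_genes(sp, sample(1:3, 1), fam, "shared")
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family = fam, category = "shared",
                   species_combo = species_combo_key(combo))
    }

    # lineage-specific expanded families
    for (sp in S) for (i in seq_len(config$n_lineage_specific)) {
      fam <- sprintf("LSP_%s_%03d", sp, i)
      copies <- sample_from(config$expansion_copies[1]:config$expansion_copies[2])
      if (fam %in% names(tandem_demand)) copies <- max(copies, tandem_demand[[fam]])
      if (copies > config$n_scaffolds)
        abort("'n_scaffolds' (%d) must be >= family copy number (%d)",
              config$n_scaffolds, copies)
      gene_rows[[length(gene_rows) + 1L]] <- new_genes(sp, copies, fam, "lineage_specific")
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family = fam, category = "lineage_specific", species_combo = sp)
    }

    # orphans and planted faulty models (no family)
    for (sp in S) if (config$n_orphans > 0)
      gene_rows[[length(gene_rows) + 1L]] <-
        new_genes(sp, config$n_orphans, NO_FAMILY, "orphan")
    for (k in seq_len(config$short_model_count))
      gene_rows[[length(gene_rows) + 1L]] <-
        new_genes(S[((k - 1L) %% 3L) + 1L], 1L, NO_FAMILY, "short",
                  len_range = c(20L, 49L))
    for (k in seq_len(config$te_model_count))
      gene_rows[[length(gene_rows) + 1L]] <-
        new_genes(S[((k - 1L) %% 3L) + 1L], 1L, NO_FAMILY, "te")

    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else data.frame(
      id = character(), species = character(), family = character(),
      category = character(), protein_length = integer(),
      has_start = logical(), has_stop = logical(), stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
      data.frame(family = character(), category = character(),
                 species_combo = character(), stringsAsFactors = FALSE)
    tab <- table(genes$family[genes$family != NO_FAMILY])
    families$n_members <- as.integer(tab[families$family])

    # reference database table: roughly half of each reference family's
    # members (at least one) act as database-listed representatives
    ref_members <- list()
    for (fam in families$family[families$category == "reference"]) {
      ids <- genes$id[genes$family == fam]
      take <- sort(sample(ids, max(1L, ceiling(length(ids) / 2))))
      ref_members[[fam]] <- data.frame(member_id = take, family = fam,
                                       stringsAsFactors = FALSE)
    }
    reference_members <- if (length(ref_members)) do.call(rbind, ref_members) else
      data.frame(member_id = character(), family = character(), stringsAsFactors = FALSE)
    rownames(reference_members) <- NULL

    # planted tandem arrays: the first `copies` members of the family within
    # the scaffold's species
    tandem <- lapply(config$tandem_arrays, function(ta) {
      sp <- sub("_s[0-9]+$", "", ta$scaffold)
      if (!sp %in% S)
        abort("tandem array scaffold '%s' does not match any species", ta$scaffold)
      if (!ta$family %in% families$family)
        abort("tandem array references unknown family '%s'", ta$family)
      ids <- genes$id[genes$family == ta$family & genes$species == sp]
      if (length(ids) < ta$copies)
        abort("family '%s' has %d genes in %s, tandem array needs %d",
              ta$family, length(ids), sp, ta$copies)
      list(family = ta$family, scaffold = ta$scaffold,
           members = ids[seq_len(ta$copies)],
           max_intervening = as.integer(ta$max_intervening))
    })

    # tree plan: multi-species families with >= 3 members; per-species groups
    # of size >= 2 are planted expansions; families where the first two
    # species both contribute exactly one gene host a planted ortholog pair
    trees <- list()
    for (fam in families$family) {
      ids <- genes$id[genes$family == fam]
      sps <- genes$species[genes$family == fam]
      if (length(ids) < 3 || length(unique(sps)) < 2) next
      groups <- split(ids, sps)
      expansions <- groups[vapply(groups, length, integer(1)) >= 2]
      pairs <- NULL
      if (!is.null(groups[[S[1]]]) && length(groups[[S[1]]]) == 1 &&
          !is.null(groups[[S[2]]]) && length(groups[[S[2]]]) == 1) {
        pairs <- data.frame(leaf_a = groups[[S[1]]], leaf_b = groups[[S[2]]],
                            support = sample(80:100, 1), stringsAsFactors = FALSE)
      }
      trees[[fam]] <- list(family = fam, members = ids, species = sps,
                           expansions = expansions, pairs = pairs)
    }

    fg_fams <- families$family[families$category == "shared" &
                               families$species_combo == species_combo_key(S[1:2])]
    foreground <- genes$id[genes$family %in% fg_fams]

    out <- list(genes = genes, families = families,
                reference_members = reference_members, tandem = tandem,
                trees = trees, foreground = foreground,
                enriched_terms = config$enriched_terms, config = config)
    class(out) <- "mf_truth"
    out
  })
}

#' @export
print.mf_truth <- function(x, ...) {
  cat(sprintf("mf_truth: %d genes, %d families (%s)\n", nrow(x$genes),
              nrow(x$families),
              paste(sprintf("%s=%d", names(table(x$families$category)),
                            table(x$families$category)), collapse = ", ")))
  invisible(x)
}

#' Emit a BLAST-style all-vs-all similarity table for a truth set
#'
#' Within-family ordered pairs are emitted with probability
#' `1 - edge_dropout_prob`, with E-values `10^-w`, `w` uniform on the
#' within-family weight range. Spurious between-family ordered pairs are
#' emitted with probability `between_family_edge_prob` from the (much weaker)
#' between-family range. Orphan and faulty models take part only in the
#' spurious pool. No self-hits are emitted.
#'
#' @param truth an [generate_truth()] result.
#' @param config generator config; defaults to the one inside `truth`.
#' @return data frame in 12-column BLAST tabular layout (qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore).
#' @export
generate_similarity_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mf_truth"))
  with_seed(config$seed + .STREAM[["edges"]], {
    g <- truth$genes
    len <- setNames(g$protein_length, g$id)
    rows <- list()

    emit <- function(q, s, w, within) {
      n <- length(q)
      if (n == 0) return(NULL)
      alen <- pmin(len[q], len[s])
      pid <- if (within) runif(n, 70, 99) else runif(n, 25, 40)
      data.frame(qseqid = q, sseqid = s,
                 pident = round(pid, 2), length = as.integer(alen),
                 mismatch = as.integer(round(alen * (1 - pid / 100))),
                 gapopen = 0L, qstart = 1L, qend = as.integer(alen),
                 sstart = 1L, send = as.integer(alen),
                 evalue = 10^(-w), bitscore = round(2 * w + 30, 1),
                 stringsAsFactors = FALSE)
    }

    # within-family ordered pairs, thinned by dropout
    fams <- split(g$id[g$family != NO_FAMILY], g$family[g$family != NO_FAMILY])
    for (ids in fams) {
      m <- length(ids)
      if (m < 2) next
      pr <- expand.grid(q = ids, s = ids, stringsAsFactors = FALSE)
      pr <- pr[pr$q != pr$s, ]
      keep <- runif(nrow(pr)) >= config$edge_dropout_prob
      pr <- pr[keep, ]
      if (nrow(pr) == 0) next
      w <- runif(nrow(pr), config$within_family_weight_range[1],
                 config$within_family_weight_range[2])
      rows[[length(rows) + 1L]] <- emit(pr$q, pr$s, w, within = TRUE)
    }

    # spurious between-family ordered pairs, sampled by expected count
    n_genes <- nrow(g)
    if (config$between_family_edge_prob > 0 && n_genes >= 2) {
      fam_of <- setNames(g$family, g$id)
      n_within <- sum(vapply(fams, function(ids) length(ids) * (length(ids) - 1),
                             numeric(1)))
      n_between <- n_genes * (n_genes - 1) - n_within
      k <- rbinom(1, n_between, config$between_family_edge_prob)
      got <- character(0)
      q_acc <- s_acc <- character(0)
      while (length(got) < k) {
        need <- k - length(got)
        qi <- g$id[sample.int(n_genes, 2 * need + 10, replace = TRUE)]
        si <- g$id[sample.int(n_genes, 2 * need + 10, replace = TRUE)]
        ok <- qi != si &
          (fam_of[qi] == NO_FAMILY | fam_of[si] == NO_FAMILY | fam_of[qi] != fam_of[si])
        key <- paste(qi, si)[ok]
        new <- !key %in% got & !duplicated(key)
        add <- utils::head(which(new), need)
        got <- c(got, key[add])
        q_acc <- c(q_acc, qi[ok][add])
        s_acc <- c(s_acc, si[ok][add])
      }
      if (k > 0) {
        w <- runif(k, config$between_family_weight_range[1],
                   config$between_family_weight_range[2])
        rows[[length(rows) + 1L]] <- emit(q_acc, s_acc, w, within = FALSE)
      }
    }

    out <- if (length(rows)) do.call(rbind, rows) else
      emit(character(0), character(0), numeric(0), TRUE)
    if (is.null(out)) out <- data.frame(
      qseqid = character(), sseqid = character(), pident = numeric(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = numeric(), bitscore = numeric(),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a GO annotation table with planted enriched terms
#'
#' Every gene carries each non-enriched term with the background probability.
#' Enriched terms are carried by foreground genes at their stated foreground
#' probability and by all other genes at the background probability.
#'
#' @param gene_ids all gene identifiers (the annotation universe).
#' @param foreground_ids subset of `gene_ids` in which terms are enriched.
#' @param n_terms size of the term universe (terms are `GO:0000001` ...).
#' @param background_prob background carry probability.
#' @param enriched_terms data frame with columns `term`, `fg_prob`.
#' @return data frame with columns `gene_id`, `term`.
#' @export
simulate_go_annotations <- function(gene_ids, foreground_ids, n_terms,
                                    background_prob, enriched_terms) {
  if (length(setdiff(foreground_ids, gene_ids)))
    abort("foreground genes missing from the universe")
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  fg <- gene_ids %in% foreground_ids
  rows <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    p <- rep(background_prob, length(gene_ids))
    hit <- match(terms[i], enriched_terms$term)
    if (!is.na(hit)) p[fg] <- enriched_terms$fg_prob[hit]
    carry <- runif(length(gene_ids)) < p
    if (any(carry)) rows[[i]] <- data.frame(gene_id = gene_ids[carry],
                                            term = terms[i],
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(gene_id = character(), term = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate coordinates, GO, evidence, TE and domain tables for a truth set
#'
#' Places genes on scaffolds (planted tandem arrays as near-consecutive ranks
#' with at most the specified number of intervening genes; all other relatives
#' of a family on distinct scaffolds so no accidental arrays arise), derives
#' non-overlapping 1-based coordinates with a fixed 500-bp intergenic spacing,
#' and emits GO, transcript-evidence, transposable-element and Pfam-style
#' domain-hit tables consistent with the planted design.
#'
#' @param truth an [generate_truth()] result.
#' @param config generator config; defaults to the one inside `truth`.
#' @return an object of class `mf_annotations`: list with `coords` (gene
#'   coordinate data frame), `go`, `evidence`, `te_hits`, `domains` (hit
#'   tables), `domain_min_length` (named length thresholds used for the
#'   planted counts) and `domain_counts` (the planted species x domain truth).
#' @export
generate_annotations <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mf_truth"))
  with_seed(config$seed + .STREAM[["annotations"]], {
    g <- truth$genes
    S <- config$species
    scaf_names <- function(sp) sprintf("%s_s%02d", sp, seq_len(config$n_scaffolds))

    coords_rows <- list()
    for (sp in S) {
      scafs <- scaf_names(sp)
      sp_genes <- g[g$species == sp, ]
      order_on <- setNames(vector("list", length(scafs)), scafs)

      tandem_here <- Filter(function(ta) ta$scaffold %in% scafs, truth$tandem)
      tandem_ids <- unlist(lapply(tandem_here, `[[`, "members"))

      # family members go to distinct scaffolds so the only arrays are the
      # planted ones; familyless genes are scattered freely
      pool <- setdiff(sp_genes$id, tandem_ids)
      fam_of <- setNames(sp_genes$family, sp_genes$id)
      array_scaf_of <- setNames(vapply(tandem_here, `[[`, "", "scaffold"),
                                vapply(tandem_here, `[[`, "", "family"))
      for (ids in split(pool, fam_of[pool])) {
        fam <- fam_of[[ids[1]]]
        if (fam == NO_FAMILY) {
          to <- sample(scafs, length(ids), replace = TRUE)
        } else {
          # keep leftover relatives off the scaffold hosting the family's
          # planted array, so the array stays exactly as planted
          avail <- setdiff(scafs, array_scaf_of[fam])
          if (length(ids) > length(avail))
            abort("n_scaffolds too small for family placement")
          to <- sample_from(avail, length(ids))
        }
        for (j in seq_along(ids))
          order_on[[to[j]]] <- c(order_on[[to[j]]], ids[j])
      }
      order_on <- lapply(order_on, function(ids) if (length(ids)) sample(ids) else ids)

      # splice each planted array in as a contiguous block with at most
      # max_intervening familyless genes between consecutive members
      for (ta in tandem_here) {
        block <- ta$members[1]
        host <- order_on[[ta$scaffold]]
        spacers_ok <- host[fam_of[host] == NO_FAMILY]
        for (m in ta$members[-1]) {
          n_iv <- if (ta$max_intervening > 0)
            sample(0:ta$max_intervening, 1) else 0L
          n_iv <- min(n_iv, length(spacers_ok))
          if (n_iv > 0) {
            iv <- spacers_ok[seq_len(n_iv)]
            spacers_ok <- spacers_ok[-seq_len(n_iv)]
            host <- setdiff(host, iv)
            block <- c(block, iv)
          }
          block <- c(block, m)
        }
        at <- if (length(host)) sample(0:length(host), 1) else 0L
        order_on[[ta$scaffold]] <- append(host, block, after = at)
      }

      for (sc in scafs) {
        ids <- order_on[[sc]]
        if (!length(ids)) next
        glen <- g$protein_length[match(ids, g$id)] * 3L + 3L
        start <- cumsum(c(1L, utils::head(glen, -1) + 500L))
        coords_rows[[length(coords_rows) + 1L]] <- data.frame(
          id = ids, species = sp, scaffold = sc,
          start = start, end = start + glen - 1L,
          strand = sample(c("+", "-"), length(ids), replace = TRUE),
          rank = seq_along(ids), stringsAsFactors = FALSE)
      }
    }
    coords <- if (length(coords_rows)) do.call(rbind, coords_rows) else
      data.frame(id = character(), species = character(), scaffold = character(),
                 start = integer(), end = integer(), strand = character(),
                 rank = integer(), stringsAsFactors = FALSE)
    rownames(coords) <- NULL

    go <- simulate_go_annotations(g$id, truth$foreground,
                                  config$go_term_universe,
                                  config$background_term_prob,
                                  truth$enriched_terms)

    # transcript evidence: all family genes have it; orphans lack it with the
    # configured probability; faulty models are a coin flip
    has_ev <- rep(TRUE, nrow(g))
    orphan <- g$category == "orphan"
    has_ev[orphan] <- runif(sum(orphan)) >= config$evidence_missing_prob
    faulty <- g$category %in% c("short", "te")
    has_ev[faulty] <- runif(sum(faulty)) < 0.5
    evidence <- data.frame(model_id = g$id[has_ev],
                           transcript_id = sprintf("tx_%s", g$id[has_ev]),
                           evalue = rep(1e-30, sum(has_ev)),
                           stringsAsFactors = FALSE)

    te_ids <- g$id[g$category == "te"]
    te_hits <- data.frame(model_id = te_ids,
                          te_class = if (length(te_ids))
                            sample(c("DNA", "LINE", "LTR"), length(te_ids),
                                   replace = TRUE) else character(0),
                          score = if (length(te_ids))
                            round(runif(length(te_ids), 100, 900)) else numeric(0),
                          stringsAsFactors = FALSE)

    # domain hits: lineage-specific family i (any species) carries domain
    # pool[i]; qualifying hits are long, decoys are sub-threshold
    dom_pool <- c("HSP70", "C1q", "Lectin_C", "FReD", "EGF", "Kunitz_BPTI",
                  "Chitin_bind", "Peroxidase", "Tyrosinase", "fn3",
                  "Glyco_hydro", "PAN")
    dom_rows <- list()
    counts <- list()
    min_len <- 50L
    ls_fams <- truth$families[truth$families$category == "lineage_specific", ]
    if (nrow(ls_fams)) {
      idx <- as.integer(sub(".*_(\\d+)$", "\\1", ls_fams$family))
      dom <- dom_pool[((idx - 1L) %% length(dom_pool)) + 1L]
      for (i in seq_len(nrow(ls_fams))) {
        ids <- g$id[g$family == ls_fams$family[i]]
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          gene_id = ids, species = ls_fams$species_combo[i], domain = dom[i],
          length = sample(100:250, length(ids), replace = TRUE),
          score = round(runif(length(ids), 50, 300), 1), stringsAsFactors = FALSE)
        key <- paste(ls_fams$species_combo[i], dom[i])
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + length(ids)
        # two sub-threshold decoy hits per planted family on random outsiders
        out_ids <- sample(setdiff(g$id, ids), min(2L, max(0L, nrow(g) - length(ids))))
        if (length(out_ids))
          dom_rows[[length(dom_rows) + 1L]] <- data.frame(
            gene_id = out_ids, species = g$species[match(out_ids, g$id)],
            domain = dom[i], length = sample(10:45, length(out_ids), replace = TRUE),
            score = round(runif(length(out_ids), 5, 20), 1), stringsAsFactors = FALSE)
      }
    }
    domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
      data.frame(gene_id = character(), species = character(), domain = character(),
                 length = integer(), score = numeric(), stringsAsFactors = FALSE)
    rownames(domains) <- NULL
    domain_counts <- if (length(counts)) {
      ks <- strsplit(names(counts), " ")
      data.frame(species = vapply(ks, `[`, "", 1), domain = vapply(ks, `[`, "", 2),
                 count = as.integer(unlist(counts)), stringsAsFactors = FALSE)
    } else data.frame(species = character(), domain = character(),
                      count = integer(), stringsAsFactors = FALSE)

    out <- list(coords = coords, go = go, evidence = evidence,
                te_hits = te_hits, domains = domains,
                domain_min_length = min_len, domain_counts = domain_counts)
    class(out) <- "mf_annotations"
    out
  })
}

# Build a Newick string for one planned family tree. Planted expansions are
# pure single-species caterpillar clades (root support 80-100); planted
# ortholog pairs are cross-species cherries at their planned support; the
# backbone joins remaining units round-robin by species with supports 30-79,
# so no unplanted node can masquerade as a high-support cross-species pair.
build_family_newick <- function(plan) {
  groups <- split(plan$members, plan$species)
  units <- list()   # each: list(txt, species or "mixed", planted)
  clade_txt <- function(ids, root_sup) {
    t <- ids[1]
    for (i in seq_along(ids)[-1]) {
      sup <- if (i == length(ids)) root_sup else sample(50:100, 1)
      t <- sprintf("(%s,%s)%d", t, ids[i], sup)
    }
    t
  }
  paired <- character(0)
  if (!is.null(plan$pairs)) {
    for (i in seq_len(nrow(plan$pairs))) {
      pr <- plan$pairs[i, ]
      units[[length(units) + 1L]] <- list(
        txt = sprintf("(%s,%s)%d", pr$leaf_a, pr$leaf_b, pr$support),
        species = "mixed")
      paired <- c(paired, pr$leaf_a, pr$leaf_b)
    }
  }
  for (sp in names(groups)) {
    ids <- setdiff(groups[[sp]], paired)
    if (!length(ids)) next
    if (length(ids) >= 2) {
      units[[length(units) + 1L]] <- list(txt = clade_txt(ids, sample(80:100, 1)),
                                          species = sp)
    } else {
      units[[length(units) + 1L]] <- list(txt = ids, species = sp)
    }
  }
  if (length(units) == 1) return(paste0(units[[1]]$txt, ";"))
  # round-robin by species class so sibling units always differ in species
  cls <- vapply(units, `[[`, "", "species")
  ord <- unlist(lapply(seq_len(max(table(cls))), function(k) {
    idx <- unlist(lapply(unique(cls), function(cc) which(cls == cc)[k]))
    idx[!is.na(idx)]
  }))
  units <- units[ord]
  t <- sprintf("(%s,%s)%d", units[[1]]$txt, units[[2]]$txt, sample(30:79, 1))
  for (i in seq_along(units)[-(1:2)])
    t <- sprintf("(%s,%s)%d", t, units[[i]]$txt, sample(30:79, 1))
  paste0(t, ";")
}

#' Generate Newick gene trees realizing the planted tree plan
#'
#' One tree per multi-species family with at least three members. Planted
#' single-species expansions appear as monophyletic clades; planted ortholog
#' pairs as two-leaf cross-species cherries with bootstrap support >= 80.
#' Supports are integers 0-100 stored as internal node labels.
#'
#' @param truth an [generate_truth()] result.
#' @param config generator config; defaults to the one inside `truth`.
#' @return named character vector of Newick strings (names = family ids).
#' @export
generate_gene_trees <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mf_truth"))
  with_seed(config$seed + .STREAM[["trees"]], {
    vapply(truth$trees, build_family_newick, character(1))
  })
}

#' Write a complete fixture bundle to disk
#'
#' Emits per-species protein FASTA (dummy sequences of the recorded lengths)
#' and GFF3 coordinates, the all-vs-all hit table, the reference family
#' table, GO / evidence / TE / domain tables, Newick trees, the serialized
#' truth, and a manifest of MD5 checksums.
#'
#' @param truth an [generate_truth()] result.
#' @param path output directory (created if missing).
#' @param similarity optional precomputed [generate_similarity_table()] result.
#' @param annotations optional precomputed [generate_annotations()] result.
#' @param trees optional precomputed [generate_gene_trees()] result.
#' @return invisibly, the manifest data frame (file, md5, bytes).
#' @export
write_fixture_bundle <- function(truth, path,
                                 similarity = generate_similarity_table(truth),
                                 annotations = generate_annotations(truth),
                                 trees = generate_gene_trees(truth)) {
  stopifnot(inherits(truth, "mf_truth"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "trees"), showWarnings = FALSE)
  if (!dir.exists(path)) abort("cannot create output directory '%s'", path)
  cfg <- truth$config
  g <- truth$genes
  files <- character(0)

  with_seed(cfg$seed + .STREAM[["sequences"]], {
    for (sp in cfg$species) {
      ids <- g$id[g$species == sp]
      lens <- g$protein_length[g$species == sp]
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      seqs <- vapply(lens, function(n) paste(sample(aa, n, replace = TRUE),
                                             collapse = ""), character(1))
      ss <- Biostrings::AAStringSet(setNames(seqs, ids))
      f <- file.path(path, sprintf("%s.proteins.fasta", sp))
      Biostrings::writeXStringSet(ss, f)
      files <- c(files, f)

      co <- annotations$coords[annotations$coords$species == sp, ]
      co$has_start_codon <- g$has_start[match(co$id, g$id)]
      co$has_stop_codon <- g$has_stop[match(co$id, g$id)]
      f <- file.path(path, sprintf("%s.genes.gff3", sp))
      write_gff3_genes(co, f)
      files <- c(files, f)
    }
  })

  w <- function(df, name, header) {
    f <- file.path(path, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = header)
    files <<- c(files, f)
  }
  w(similarity, "allvsall.tsv", header = FALSE)
  w(truth$reference_members, "reference_families.tsv", header = TRUE)
  w(annotations$go, "go.tsv", header = FALSE)
  w(annotations$evidence, "evidence.tsv", header = TRUE)
  w(annotations$te_hits, "te_hits.tsv", header = TRUE)
  w(annotations$domains, "domains.tsv", header = TRUE)

  for (fam in names(trees)) {
    f <- file.path(path, "trees", paste0(fam, ".nwk"))
    writeLines(trees[[fam]], f)
    files <- c(files, f)
  }

  truth_json <- list(
    gene_to_family = as.list(setNames(g$family, g$id)),
    gene_category = as.list(setNames(g$category, g$id)),
    families = truth$families,
    tandem = lapply(truth$tandem, function(ta)
      ta[c("family", "scaffold", "members", "max_intervening")]),
    enriched_terms = truth$enriched_terms,
    foreground = truth$foreground,
    trees = lapply(truth$trees, function(tr)
      list(family = tr$family, expansions = tr$expansions, pairs = tr$pairs)),
    domain_counts = annotations$domain_counts)
  f <- file.path(path, "truth.json")
  jsonlite::write_json(truth_json, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files), stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(path, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
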