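# Lineage-sharing classification of gene families and per-species gene
# composition accounting.
#
# Categories follow the two-stage presentation of comparative gene-family
# figures: "common" families were assigned from the reference ortholog
# database; de novo families shared by at least two species are "shared";
# de novo families confined to one species are "lineage_specific"; genes in
# no family are orphans. A de novo family is never promoted to common even
# if its members weakly resemble reference families below the cutoff.

#' Classify families by lineage sharing
#'
#' @param assignment complete family assignment (data frame with gene_id,
#'   species, family_id, source) as produced by [cluster_unassigned()].
#' @return list with `families` (data frame: family, source, category,
#'   species_combo, n_members) and `combos` (data frame: species_combo,
#'   n_families — the de novo species-combination counts, e.g. a pairwise
#'   key for "bivalve-specific" families).
#' @export
classify_families <- function(assignment) {
  stopifnot(all(c("gene_id", "species", "family_id", "source") %in%
                names(assignment)))
  if (any(is.na(assignment$species) | assignment$species == ""))
    abort("every gene needs a species")
  fam <- assignment[assignment$source != "none", , drop = FALSE]
  if (nrow(fam) == 0)
    return(list(families = data.frame(family = character(), source = character(),
                                      category = character(),
                                      species_combo = character(),
                                      n_members = integer(),
                                      stringsAsFactors = FALSE),
                combos = data.frame(species_combo = character(),
                                    n_families = integer())))
  if (any(fam$family_id == NO_FAMILY))
    abort("family with zero members: '%s' is the reserved no-family token",
          NO_FAMILY)
  sp_by_fam <- split(fam$species, fam$family_id)
  src_by_fam <- vapply(split(fam$source, fam$family_id), `[`, "", 1)
  families <- data.frame(
    family = names(sp_by_fam),
    source = unname(src_by_fam),
    species_combo = vapply(sp_by_fam, species_combo_key, ""),
    n_members = lengths(sp_by_fam),
    stringsAsFactors = FALSE)
  n_species <- vapply(sp_by_fam, function(s) length(unique(s)), integer(1))
  families$category <- ifelse(families$source == "reference", "common",
                       ifelse(n_species >= 2, "shared", "lineage_specific"))
  families <- families[order(families$family),
                       c("family", "source", "category", "species_combo",
                         "n_members")]
  rownames(families) <- NULL
  dn <- families[families$source == "de_novo", , drop = FALSE]
  tab <- table(dn$species_combo)
  combos <- data.frame(species_combo = names(tab),
                       n_families = as.integer(tab), stringsAsFactors = FALSE)
  list(families = families, combos = combos)
}

#' Per-species gene composition by family category
#'
#' Counts each gene exactly once under its family's category (common /
#' shared / lineage-specific) or as an orphan, per species, with fractions
#' of that species' retained gene total.
#'
#' @param assignment complete family assignment data frame.
#' @param families classified family table from [classify_families()].
#' @return data frame with one row per species: n_common, n_shared,
#'   n_lineage_specific, n_orphan, n_total and the corresponding fractions.
#' @export
gene_composition <- function(assignment, families) {
  if (is.list(families) && !is.data.frame(families)) families <- families$families
  cat_of <- setNames(families$category, families$family)
  in_family <- assignment$source != "none"
  unknown <- setdiff(assignment$family_id[in_family], families$family)
  if (length(unknown))
    abort("gene references unknown family '%s'", unknown[1])
  category <- ifelse(in_family, cat_of[assignment$family_id], "orphan")
  tab <- table(factor(assignment$species),
               factor(category, levels = c("common", "shared",
                                           "lineage_specific", "orphan")))
  out <- data.frame(species = rownames(tab),
                    n_common = as.integer(tab[, "common"]),
                    n_shared = as.integer(tab[, "shared"]),
                    n_lineage_specific = as.integer(tab[, "lineage_specific"]),
                    n_orphan = as.integer(tab[, "orphan"]),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_common + out$n_shared + out$n_lineage_specific +
    out$n_orphan
  for (col in c("common", "shared", "lineage_specific", "orphan"))
    out[[paste0("frac_", col)]] <- out[[paste0("n_", col)]] / out$n_total
  rownames(out) <- NULL
  out
}

#' Partition accounting for the reference / de novo / orphan split
#'
#' Reproduces the additive arithmetic of family assignment: of `n_total`
#' retained models, `n_reference_assigned` joined a reference family; of the
#' remainder, `n_de_novo_clustered` joined a de novo family; the residue are
#' orphan gene models.
#'
#' @param n_total retained gene models.
#' @param n_reference_assigned models assigned to reference families.
#' @param n_de_novo_clustered models clustered into de novo families.
#' @return list with `n_unassigned_after_reference` and `n_orphan`.
#' @export
partition_accounting <- function(n_total, n_reference_assigned,
                                 n_de_novo_clustered) {
  check_count(n_total, "n_total")
  check_count(n_reference_assigned, "n_reference_assigned")
  check_count(n_de_novo_clustered, "n_de_novo_clustered")
  n_unassigned <- n_total - n_reference_assigned
  if (n_unassigned < 0)
    abort("n_reference_assigned (%d) exceeds n_total (%d)",
          n_reference_assigned, n_total)
  n_orphan <- n_unassigned - n_de_novo_clustered
  if (n_orphan < 0)
    abort("n_de_novo_clustered (%d) exceeds the %d models left unassigned",
          n_de_novo_clustered, n_unassigned)
  list(n_unassigned_after_reference = n_unassigned, n_orphan = n_orphan)
}
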