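# Readers and writers for the standard formats the pipeline consumes:
# BLAST 12-column tabular, GFF3 gene coordinates, FASTA, plain TSV tables,
# and Newick gene trees.

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column BLAST tabular hit file
#'
#' @param path file with `-outfmt 6` style rows (no header).
#' @return data frame with the standard column names.
#' @export
read_blast_tab <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    abort("'%s': expected 12 BLAST tabular columns, found %d", path, ncol(df))
  names(df) <- BLAST_COLS
  bad <- which(is.na(df$evalue) | is.na(df$bitscore) | !is.finite(df$evalue))
  if (length(bad))
    abort("'%s': malformed hit row at line %d", path, bad[1])
  if (any(df$evalue < 0))
    abort("'%s': negative e-value at line %d", path, which(df$evalue < 0)[1])
  df
}

#' Write gene coordinates as GFF3
#'
#' @param coords data frame with columns id, scaffold, start, end, strand.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3_genes <- function(coords, path) {
  if (nrow(coords) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = coords$scaffold,
    ranges = IRanges::IRanges(start = coords$start, end = coords$end),
    strand = coords$strand)
  S4Vectors::mcols(gr)$source <- rep("molluscfam", length(gr))
  S4Vectors::mcols(gr)$type <- rep("gene", length(gr))
  S4Vectors::mcols(gr)$ID <- coords$id
  for (flag in c("has_start_codon", "has_stop_codon"))
    if (!is.null(coords[[flag]]))
      S4Vectors::mcols(gr)[[flag]] <- ifelse(coords[[flag]], "true", "false")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene coordinates from a GFF3 file
#'
#' Keeps `gene` features (or all features when no `type` is present) and
#' returns 1-based inclusive coordinates in rank order per scaffold.
#'
#' @param path GFF3 file.
#' @param species species code; default parses the prefix before the first
#'   underscore of each gene id.
#' @return data frame with columns id, species, scaffold, start, end, strand.
#' @export
read_gff3_genes <- function(path, species = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
        else as.character(seq_along(gr))
  df <- data.frame(id = id,
                   species = if (is.null(species)) sub("_.*$", "", id) else species,
                   scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  for (flag in c("has_start_codon", "has_stop_codon"))
    if (flag %in% names(S4Vectors::mcols(gr)))
      df[[flag]] <- as.character(S4Vectors::mcols(gr)[[flag]]) == "true"
  df[order(df$scaffold, df$start, df$end, df$id), , drop = FALSE]
}

#' Read protein lengths from a FASTA file
#'
#' @param path protein FASTA.
#' @return named integer vector of sequence lengths (names cut at the first
#'   whitespace).
#' @export
read_protein_lengths <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(Biostrings::width(ss), sub("\\s.*$", "", names(ss)))
}

#' Read an assembly FASTA into sequence lengths and gap lengths
#'
#' Handles multi-line records and lowercase bases; every run of N/n of length
#' >= 1 counts toward the gap total.
#'
#' @param path nucleotide FASTA.
#' @return an `AssemblySet`: list with `lengths` and `gaps` (bases of N per
#'   sequence), both named.
#' @export
read_assembly_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  gaps <- rowSums(Biostrings::letterFrequency(ss, letters = c("N", "n")))
  assembly_set(setNames(Biostrings::width(ss), nm), setNames(gaps, nm))
}

#' Read a two-column gene-to-GO-term table
#'
#' @param path TSV with `gene_id<TAB>term_id`, one pair per line, no header.
#' @return data frame with columns gene_id, term.
#' @export
read_go_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("'%s': expected gene_id and term_id columns", path)
  data.frame(gene_id = as.character(df[[1]]), term = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read Newick gene trees
#'
#' Bootstrap supports are taken from internal node labels. Trees whose
#' supports are all on the 0-1 scale are rescaled to 0-100 with a notice.
#'
#' @param paths one or more Newick files (one tree per file).
#' @return a list of `phylo` objects named by file base name.
#' @export
read_gene_trees <- function(paths) {
  out <- lapply(paths, function(p) {
    tr <- ape::read.tree(p)
    rescale_supports(tr)
  })
  names(out) <- sub("\\.nwk$|\\.tree$|\\.newick$", "", basename(paths))
  out
}

# supports on 0-1 are rescaled to the 0-100 integer convention
rescale_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(tree)
  sup <- suppressWarnings(as.numeric(lab))
  if (any(!is.na(sup)) && all(sup[!is.na(sup)] >= 0) &&
      all(sup[!is.na(sup)] <= 1) && any(sup[!is.na(sup)] > 0)) {
    message("rescaling fractional bootstrap supports to the 0-100 scale")
    tree$node.label <- ifelse(is.na(sup), lab, format(round(sup * 100)))
  }
  tree
}
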