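#' Read protein sequences from a FASTA file
#'
#' The id of each record is the header token before the first whitespace;
#' sequences are uppercased. Duplicate ids and empty sequences are hard
#' errors (a silently deduplicated proteome would corrupt peptide-to-parent
#' mapping downstream).
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence for FASTA record(s): ",
         paste(ids[empty], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(!is.null(names(proteins)))
  aa <- Biostrings::AAStringSet(toupper(proteins))
  names(aa) <- names(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `genotype`, `light`, `replicate`.
#' @return Validated design data.frame.
#' @export
read_design_tsv <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(design)
  design$replicate <- as.integer(design$replicate)
  design
}

#' @rdname read_design_tsv
#' @param design design table.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.peptide_cols <- c("peptide_id", "sequence", "parent", "start", "end",
                   "proteotypic")

#' Read a peptide- or protein-level quantification matrix from TSV
#'
#' The file must carry one id column (`feature_id` at protein level; the
#' peptide annotation columns `peptide_id`, `sequence`, `parent`, `start`,
#' `end`, `proteotypic` at peptide level) followed by one column per design
#' sample. Empty cells, `NA` and `NaN` are missing; on the raw scale `0` is
#' treated as missing by MS convention unless `zero_is_value = TRUE`.
#'
#' @param path TSV file.
#' @param design sample design; its samples must all be present as columns,
#'   and column order in the result follows the design order.
#' @param level `"peptide"` or `"protein"`.
#' @param scale `"raw"` or `"log2"`.
#' @param zero_is_value keep raw zeros as observed values instead of missing.
#' @return For protein level, a `quant_matrix`. For peptide level, a list
#'   with elements `matrix` (quant_matrix) and `peptides` (record table).
#' @export
read_quant_tsv <- function(path, design, level = c("peptide", "protein"),
                           scale = c("raw", "log2"), zero_is_value = FALSE) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  design <- validate_design(design)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", "NaN", ""))
  id_cols <- if (level == "protein") "feature_id" else .peptide_cols
  missing_ids <- setdiff(id_cols, names(tab))
  if (length(missing_ids) > 0L) {
    stop("quant table is missing id column(s): ",
         paste(missing_ids, collapse = ", "))
  }
  absent <- setdiff(design$sample_id, names(tab))
  if (length(absent) > 0L) {
    stop("design sample(s) absent from quant table: ",
         paste(absent, collapse = ", "))
  }
  vals <- tab[, design$sample_id, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1L], design$sample_id[j], col[bad[1L]]))
      }
      col <- num
    }
    vals[[j]] <- col
  }
  values <- as.matrix(vals)
  storage.mode(values) <- "double"
  if (scale == "raw" && !zero_is_value) values[values == 0] <- NA_real_
  feature_ids <- if (level == "protein") tab$feature_id else tab$peptide_id
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids in quant table")
  rownames(values) <- feature_ids
  qm <- quant_matrix(values, design, scale = scale, level = level)
  if (level == "protein") return(qm)
  peptides <- tab[, .peptide_cols]
  peptides$start <- as.integer(peptides$start)
  peptides$end <- as.integer(peptides$end)
  peptides$proteotypic <- as.logical(peptides$proteotypic)
  validate_peptides(peptides)
  list(matrix = qm, peptides = peptides)
}

#' Write a quantification matrix to TSV
#'
#' Inverse of [read_quant_tsv()]: `write_quant_tsv()` then `read_quant_tsv()`
#' reproduces values and missingness pattern exactly.
#'
#' @param qm quant_matrix.
#' @param path output file.
#' @param peptides peptide record table, required at peptide level.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(qm, path, peptides = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  # %.17g round-trips doubles exactly; write.table's default 15 significant
  # digits would break the write->read identity
  chr <- matrix(sprintf("%.17g", qm$values), nrow(qm$values),
                dimnames = dimnames(qm$values))
  chr[is.na(qm$values)] <- "NA"
  vals <- as.data.frame(chr, check.names = FALSE)
  if (qm$level == "protein") {
    out <- cbind(data.frame(feature_id = rownames(qm$values),
                            stringsAsFactors = FALSE), vals)
  } else {
    if (is.null(peptides)) stop("peptide-level output requires peptide records")
    peptides <- validate_peptides(peptides)
    idx <- match(rownames(qm$values), peptides$peptide_id)
    if (anyNA(idx)) stop("peptide records missing for some matrix rows")
    out <- cbind(peptides[idx, .peptide_cols], vals)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.compartments <- c("thylakoid_lumen", "thylakoid_membrane", "stroma",
                   "envelope", "other")

#' Read targeting-sequence annotations
#'
#' Per-protein boundaries of the bipartite presequence: `ctp_end` is the last
#' residue of the chloroplast transit peptide (cTP, cleaved by the stromal
#' processing peptidase), `ltp_end` the last residue of the lumenal targeting
#' peptide (lTP, cleaved by the thylakoid processing peptidase). Stromal
#' proteins carry only a cTP; either boundary may be absent (empty cell), and
#' an lTP without a cTP is invalid. `terms` holds semicolon-separated
#' GO/KEGG-style category labels, deduplicated on read.
#'
#' @param path TSV with columns `protein_id`, `ctp_end`, `ltp_end`,
#'   `compartment`, `terms`.
#' @return data.frame keyed by `protein_id`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("protein_id", "ctp_end", "ltp_end", "compartment", "terms")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$protein_id)) stop("duplicated protein_id in annotations")
  ann$ctp_end <- as.integer(ann$ctp_end)
  ann$ltp_end <- as.integer(ann$ltp_end)
  bad_comp <- !is.na(ann$compartment) & !(ann$compartment %in% .compartments)
  if (any(bad_comp)) {
    stop("unknown compartment label(s): ",
         paste(unique(ann$compartment[bad_comp]), collapse = ", "))
  }
  orphan_ltp <- !is.na(ann$ltp_end) & is.na(ann$ctp_end)
  if (any(orphan_ltp)) {
    stop("ltp_end without ctp_end for: ",
         paste(ann$protein_id[orphan_ltp], collapse = ", "))
  }
  both <- !is.na(ann$ctp_end) & !is.na(ann$ltp_end)
  bad_order <- both & ann$ltp_end <= ann$ctp_end
  if (any(bad_order)) {
    stop("ltp_end must exceed ctp_end; violated for: ",
         paste(ann$protein_id[bad_order], collapse = ", "))
  }
  if (any(!is.na(ann$ctp_end) & ann$ctp_end < 1L)) {
    stop("ctp_end must be >= 1")
  }
  ann$terms <- vapply(ann$terms, function(x) {
    if (is.na(x)) return("")
    paste(unique(strsplit(x, ";", fixed = TRUE)[[1L]]), collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  ann
}

#' @rdname read_annotations
#' @param annotations annotation table.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expand annotation terms into a term -> protein-id map
#'
#' @param annotations annotation table from [read_annotations()].
#' @return Named list mapping each category label to the character vector of
#'   member protein ids.
#' @export
term_map_from_annotations <- function(annotations) {
  pieces <- strsplit(annotations$terms, ";", fixed = TRUE)
  ids <- rep(annotations$protein_id, lengths(pieces))
  terms <- unlist(pieces, use.names = FALSE)
  keep <- !is.na(terms) & terms != ""
  split(ids[keep], terms[keep])
}
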