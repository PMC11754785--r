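#' Validate a sample design table
#'
#' A sample design describes the columns of a quantification matrix: one row
#' per MS run with the genotype, light regime and replicate number. Light is
#' restricted to the two regimes used throughout the package: moderate white
#' light (`WL`) and monochromatic red light (`RL`).
#'
#' @param design data.frame with columns `sample_id`, `genotype`, `light`,
#'   `replicate`.
#' @return The design, invisibly, with `replicate` coerced to integer.
#' @export
validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  required <- c("sample_id", "genotype", "light", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0L) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    dup <- unique(design$sample_id[duplicated(design$sample_id)])
    stop("duplicated sample_id in design: ", paste(dup, collapse = ", "))
  }
  bad_light <- setdiff(unique(design$light), c("WL", "RL"))
  if (length(bad_light) > 0L) {
    stop("unknown light level(s): ", paste(bad_light, collapse = ", "),
         " (expected WL or RL)")
  }
  rep_int <- suppressWarnings(as.integer(design$replicate))
  if (anyNA(rep_int) || any(rep_int < 1L)) {
    stop("replicate must be a positive integer for every sample")
  }
  design$replicate <- rep_int
  invisible(design)
}

#' Condition labels for a design
#'
#' @param design validated design table.
#' @return Character vector `genotype_light`, one per sample.
#' @export
design_groups <- function(design) {
  paste(design$genotype, design$light, sep = "_")
}

#' Construct a quantification matrix
#'
#' The container every pipeline stage transforms: a numeric features x
#' samples grid together with its sample design, scale (`raw` intensities or
#' `log2`) and summarization level (`peptide` or `protein`). Missing values
#' are explicit `NA`s, never zeros; on the raw scale all observed values must
#' be positive.
#'
#' @param values numeric matrix, rownames = feature ids, one column per
#'   design row (matched by `sample_id`).
#' @param design sample design table (see [validate_design()]).
#' @param scale `"raw"` or `"log2"`.
#' @param level `"peptide"` or `"protein"`.
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `design`, `scale`, `level`.
#' @export
quant_matrix <- function(values, design, scale = c("raw", "log2"),
                         level = c("peptide", "protein")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  design <- validate_design(design)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("values must have feature ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids in values")
  if (ncol(values) != nrow(design)) {
    stop("values has ", ncol(values), " columns but design has ",
         nrow(design), " samples")
  }
  if (!is.null(colnames(values))) {
    if (!identical(colnames(values), design$sample_id)) {
      if (!setequal(colnames(values), design$sample_id)) {
        stop("column names of values do not match design sample ids")
      }
      values <- values[, design$sample_id, drop = FALSE]
    }
  } else {
    colnames(values) <- design$sample_id
  }
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw-scale intensities must be >= 0 or missing")
  }
  structure(
    list(values = values, design = design, scale = scale, level = level),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf(
    "quant_matrix: %d %s features x %d samples [%s scale], %d missing (%.1f%%)\n",
    nrow(x$values), x$level, ncol(x$values), x$scale,
    n_missing, 100 * n_missing / length(x$values)
  ))
  groups <- table(design_groups(x$design))
  cat("groups:", paste(sprintf("%s (n=%d)", names(groups), groups),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Subset a quant_matrix by feature ids
#'
#' @param qm quant_matrix.
#' @param feature_ids character vector of row ids to keep (order respected).
#' @return quant_matrix restricted to the requested features.
#' @export
subset_features <- function(qm, feature_ids) {
  stopifnot(inherits(qm, "quant_matrix"))
  missing_ids <- setdiff(feature_ids, rownames(qm$values))
  if (length(missing_ids) > 0L) {
    stop("feature id(s) not present: ", paste(utils::head(missing_ids, 5L),
                                              collapse = ", "))
  }
  qm$values <- qm$values[feature_ids, , drop = FALSE]
  qm
}

#' Validate peptide records against their parent proteins
#'
#' Peptide coordinates are 1-based and inclusive on both ends, expressed in
#' the full (unprocessed) preprotein sequence. Each record must satisfy
#' `end - start + 1 == nchar(sequence)` and, when the parent sequence is
#' available, match the parent substring at `[start, end]`.
#'
#' @param peptides data.frame with columns `peptide_id`, `sequence`, `parent`,
#'   `start`, `end` and optionally `proteotypic` (logical, default `TRUE`).
#' @param proteins optional named character vector of parent sequences.
#' @return The peptide table, invisibly, with `proteotypic` filled in.
#' @export
validate_peptides <- function(peptides, proteins = NULL) {
  stopifnot(is.data.frame(peptides))
  required <- c("peptide_id", "sequence", "parent", "start", "end")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0L) {
    stop("peptide table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(peptides$peptide_id)) stop("duplicated peptide_id")
  if (is.null(peptides$proteotypic)) peptides$proteotypic <- TRUE
  len_ok <- peptides$end - peptides$start + 1L == nchar(peptides$sequence)
  if (!all(len_ok)) {
    stop("peptide length does not match coordinates for: ",
         paste(utils::head(peptides$peptide_id[!len_ok], 5L), collapse = ", "))
  }
  if (any(peptides$start < 1L)) stop("peptide start must be >= 1")
  if (!is.null(proteins)) {
    unknown <- setdiff(unique(peptides$parent), names(proteins))
    if (length(unknown) > 0L) {
      stop("peptide parent(s) absent from proteome: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    sub <- substr(proteins[peptides$parent], peptides$start, peptides$end)
    mismatch <- sub != peptides$sequence
    if (any(mismatch)) {
      stop("peptide sequence does not match parent at stated position for: ",
           paste(utils::head(peptides$peptide_id[mismatch], 5L),
                 collapse = ", "))
    }
  }
  invisible(peptides)
}
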