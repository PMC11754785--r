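#' Log2-transform a raw intensity matrix
#'
#' @param qm raw-scale `quant_matrix` with positive or missing values.
#' @return log2-scale `quant_matrix`; missing cells preserved.
#' @export
log2_transform <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "raw") stop("matrix is already on the log2 scale")
  if (any(qm$values == 0, na.rm = TRUE)) {
    stop("zero intensities present: log2 undefined ",
         "(zeros kept as values instead of missing?)")
  }
  qm$values <- log2(qm$values)
  qm$scale <- "log2"
  qm
}

#' Invert a log2 transform back to raw intensities
#'
#' @param qm log2-scale `quant_matrix`.
#' @return raw-scale `quant_matrix`.
#' @export
unlog2_transform <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") stop("matrix is not on the log2 scale")
  qm$values <- 2^qm$values
  qm$scale <- "raw"
  qm
}

#' Filter features on minimum valid values per condition
#'
#' Keeps a feature iff it has at least `min_reps` non-missing values in at
#' least one (genotype, light) group, the usual "quantified in a minimum of
#' n replicates per condition" rule. Row order is preserved and the filter
#' is idempotent.
#'
#' @param qm `quant_matrix`.
#' @param min_reps required non-missing count; 0 keeps everything.
#' @return Filtered `quant_matrix`.
#' @export
filter_min_valid <- function(qm, min_reps = 3L) {
  stopifnot(inherits(qm, "quant_matrix"))
  groups <- design_groups(qm$design)
  if (min_reps > max(table(groups))) {
    stop("min_reps (", min_reps, ") exceeds the largest group size (",
         max(table(groups)), ")")
  }
  if (min_reps <= 0L) return(qm)
  valid <- !is.na(qm$values)
  keep <- rep(FALSE, nrow(qm$values))
  for (g in unique(groups)) {
    keep <- keep | rowSums(valid[, groups == g, drop = FALSE]) >= min_reps
  }
  qm$values <- qm$values[keep, , drop = FALSE]
  qm
}

#' Impute missing values from a down-shifted normal distribution
#'
#' The standard left-censored MS imputation: per targeted sample column with
#' observed mean `mu` and standard deviation `sigma`, each missing cell is
#' replaced by a draw from `Normal(mu - shift * sigma, (width * sigma)^2)`.
#' Defaults `width = 0.3`, `shift = 1.8` are the conventional parameters of
#' this scheme. Observed values are never altered.
#'
#' @param qm log2-scale `quant_matrix`.
#' @param width,shift distribution parameters in units of the per-column sd.
#' @param columns `"all"` or a character vector of sample ids to impute
#'   (e.g. only the reference-condition columns for peptide fold changes);
#'   missing cells in other columns are left missing.
#' @param seed optional integer; draws are deterministic under a seed and
#'   the global RNG state is left untouched.
#' @return `quant_matrix` with missing cells in the targeted columns filled.
#' @export
impute_downshift <- function(qm, width = 0.3, shift = 1.8, columns = "all",
                             seed = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") stop("impute_downshift expects a log2-scale matrix")
  if (width <= 0) stop("width must be > 0")
  if (shift < 0) stop("shift must be >= 0")
  target <- if (identical(columns, "all")) qm$design$sample_id else columns
  unknown <- setdiff(target, qm$design$sample_id)
  if (length(unknown) > 0L) {
    stop("unknown sample id(s) in columns: ", paste(unknown, collapse = ", "))
  }
  draw <- function() {
    for (s in target) {
      col <- qm$values[, s]
      obs <- col[!is.na(col)]
      if (anyNA(col)) {
        if (length(obs) < 2L) {
          stop("column '", s, "' has fewer than 2 observed values; ",
               "imputation sd undefined")
        }
        mu <- mean(obs)
        sigma <- stats::sd(obs)
        n_miss <- sum(is.na(col))
        col[is.na(col)] <- stats::rnorm(n_miss, mu - shift * sigma,
                                        width * sigma)
        qm$values[, s] <<- col
      }
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  qm
}

#' Median-normalize samples
#'
#' Subtracts each sample's median and adds back the grand median of the
#' pre-normalization per-sample medians, so all per-sample medians are equal
#' afterwards and the overall intensity location is preserved.
#'
#' @param qm log2-scale `quant_matrix`.
#' @return Normalized `quant_matrix`.
#' @export
median_normalize <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") stop("median_normalize expects a log2-scale matrix")
  med <- apply(qm$values, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("all-missing sample column(s): ",
         paste(colnames(qm$values)[is.na(med)], collapse = ", "))
  }
  grand <- stats::median(med)
  qm$values <- sweep(qm$values, 2L, med - grand)
  qm
}

#' Summarize peptide intensities to protein-group quantities
#'
#' Protein quantity per sample is the sum of its assigned non-missing
#' peptide intensities (raw scale); the protein is missing in a sample only
#' when all members are missing there. Non-proteotypic (shared) peptides are
#' excluded to avoid double counting.
#'
#' @param qm raw-scale peptide `quant_matrix`.
#' @param peptides peptide record table mapping rows to parents.
#' @return raw-scale protein `quant_matrix` (proteins in first-appearance
#'   order of the peptide table).
#' @export
summarize_protein <- function(qm, peptides) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "raw") stop("summarize_protein expects raw intensities")
  if (qm$level != "peptide") stop("summarize_protein expects a peptide matrix")
  peptides <- validate_peptides(peptides)
  idx <- match(rownames(qm$values), peptides$peptide_id)
  if (anyNA(idx)) {
    stop("peptide(s) without a record: ",
         paste(utils::head(rownames(qm$values)[is.na(idx)], 5L),
               collapse = ", "))
  }
  parent <- peptides$parent[idx]
  keep <- peptides$proteotypic[idx]
  vals <- qm$values[keep, , drop = FALSE]
  parent <- parent[keep]
  parent_f <- factor(parent, levels = unique(parent))
  sums <- rowsum(ifelse(is.na(vals), 0, vals), parent_f)
  n_obs <- rowsum((!is.na(vals)) * 1L, parent_f)
  sums[n_obs == 0L] <- NA_real_
  quant_matrix(as.matrix(sums), qm$design, scale = "raw", level = "protein")
}

#' Difference of group means per feature
#'
#' The pipeline's log2 fold-change estimator: mean over the samples of group
#' `a` minus mean over group `b`, using available (non-missing) values.
#'
#' @param qm log2-scale `quant_matrix`.
#' @param comparison length-2 character vector `c(a, b)` of condition labels
#'   (`genotype_light`).
#' @return Named numeric vector of `a - b` log2 differences; `NA` where a
#'   group has no observed value.
#' @export
group_mean_diff <- function(qm, comparison) {
  stopifnot(inherits(qm, "quant_matrix"), length(comparison) == 2L)
  groups <- design_groups(qm$design)
  missing_grp <- setdiff(comparison, groups)
  if (length(missing_grp) > 0L) {
    stop("comparison group(s) absent from design: ",
         paste(missing_grp, collapse = ", "))
  }
  a <- rowMeans(qm$values[, groups == comparison[1L], drop = FALSE],
                na.rm = TRUE)
  b <- rowMeans(qm$values[, groups == comparison[2L], drop = FALSE],
                na.rm = TRUE)
  out <- a - b
  out[is.nan(out)] <- NA_real_
  out
}
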