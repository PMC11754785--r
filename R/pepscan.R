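#' Thresholds for the ratio-gap detection of processing intermediates
#'
#' A peptide is a processing-intermediate candidate when its parent protein
#' is depleted (protein log2 ratio below `protein_ratio_max`) while the
#' peptide's own log2 ratio exceeds the protein's by at least
#' `ratio_gap_min`. `extended` mode applies exactly this rule; `strict` mode
#' additionally requires the peptide change to be individually significant
#' (`q_value < peptide_q_max`) and positive (the "opposite trend" rule:
#' the peptide goes up while its protein goes down).
#'
#' @param protein_ratio_max log2 ceiling on the protein ratio (default
#'   -0.4).
#' @param ratio_gap_min minimum log2 gap between peptide and protein ratio
#'   (default 1.0).
#' @param peptide_q_max q-value ceiling, strict mode only.
#' @param mode `"extended"` or `"strict"`.
#' @return List of class `detection_thresholds`.
#' @export
detection_thresholds <- function(protein_ratio_max = -0.4,
                                 ratio_gap_min = 1.0,
                                 peptide_q_max = 0.05,
                                 mode = c("extended", "strict")) {
  mode <- match.arg(mode)
  if (ratio_gap_min <= 0) stop("ratio_gap_min must be > 0")
  structure(
    list(protein_ratio_max = protein_ratio_max,
         ratio_gap_min = ratio_gap_min,
         peptide_q_max = peptide_q_max, mode = mode),
    class = "detection_thresholds"
  )
}

#' Normalize peptide intensities by parent-protein quantity
#'
#' Divides every peptide cell by its parent protein's quantity in the same
#' sample, giving each peptide's fractional contribution to the protein
#' signal. Where the parent is missing the result is missing.
#'
#' @param pep_qm raw-scale peptide `quant_matrix`.
#' @param prot_qm raw-scale protein `quant_matrix` over the same samples.
#' @param peptides peptide record table mapping rows to parents.
#' @return raw-scale peptide `quant_matrix` of protein-relative values.
#' @export
normalize_peptides_by_protein <- function(pep_qm, prot_qm, peptides) {
  stopifnot(inherits(pep_qm, "quant_matrix"), inherits(prot_qm, "quant_matrix"))
  if (pep_qm$scale != "raw" || prot_qm$scale != "raw") {
    stop("protein-relative normalization works on raw intensities")
  }
  if (!identical(pep_qm$design$sample_id, prot_qm$design$sample_id)) {
    stop("peptide and protein matrices must share the same samples in order")
  }
  peptides <- validate_peptides(peptides)
  parent <- peptides$parent[match(rownames(pep_qm$values),
                                  peptides$peptide_id)]
  if (anyNA(parent)) stop("peptide(s) without a record in the peptide table")
  missing_parent <- setdiff(unique(parent), rownames(prot_qm$values))
  if (length(missing_parent) > 0L) {
    stop("parent protein(s) absent from protein matrix: ",
         paste(utils::head(missing_parent, 5L), collapse = ", "))
  }
  denom <- prot_qm$values[parent, , drop = FALSE]
  if (any(denom == 0, na.rm = TRUE)) {
    stop("parent protein intensity of 0 encountered; division undefined")
  }
  pep_qm$values <- pep_qm$values / denom
  pep_qm
}

#' Peptide-level log2 ratios with reference-only imputation
#'
#' For one condition pair (mutant vs control), imputes missing values from
#' the down-shifted normal only in the designated columns (by default the
#' control group, where preprotein-derived peptides are expected to be
#' left-censored), then computes per-peptide log2 difference of means,
#' Student's t-test and Benjamini-Hochberg q-values across all peptides in
#' the comparison, and attaches the parent protein's log2 ratio and the
#' resulting gap. Peptides with fewer than 2 observed values in either group
#' after imputation are excluded with a reported count (attribute
#' `n_excluded`), not an error.
#'
#' @param pep_qm log2-scale peptide `quant_matrix`.
#' @param peptides peptide record table.
#' @param protein_ratios named numeric vector of parent log2 ratios for the
#'   same comparison (e.g. from [group_mean_diff()] on the processed
#'   protein matrix).
#' @param comparison `c(mutant, control)` condition labels.
#' @param impute_columns sample ids to impute; defaults to the control
#'   group's samples; `NULL` disables imputation.
#' @param width,shift,seed imputation parameters (see
#'   [impute_downshift()]).
#' @return data.frame of peptide ratio records: `peptide_id`, `parent`,
#'   `start`, `end`, `peptide_ratio`, `protein_ratio`, `gap`
#'   (`peptide_ratio - protein_ratio`), `p_value`, `q_value`.
#' @export
peptide_ratios <- function(pep_qm, peptides, protein_ratios, comparison,
                           impute_columns = NULL, width = 0.3, shift = 1.8,
                           seed = NULL) {
  stopifnot(inherits(pep_qm, "quant_matrix"), length(comparison) == 2L)
  if (pep_qm$scale != "log2") stop("peptide_ratios expects a log2-scale matrix")
  peptides <- validate_peptides(peptides)
  groups <- design_groups(pep_qm$design)
  missing_grp <- setdiff(comparison, groups)
  if (length(missing_grp) > 0L) {
    stop("comparison group(s) absent from design: ",
         paste(missing_grp, collapse = ", "))
  }
  control_samples <- pep_qm$design$sample_id[groups == comparison[2L]]
  if (is.null(impute_columns)) impute_columns <- control_samples
  if (length(impute_columns) > 0L) {
    outside <- setdiff(impute_columns, pep_qm$design$sample_id)
    if (length(outside) > 0L) {
      stop("impute_columns contain unknown sample id(s): ",
           paste(outside, collapse = ", "))
    }
    pep_qm <- impute_downshift(pep_qm, width = width, shift = shift,
                               columns = impute_columns, seed = seed)
  }
  x <- pep_qm$values[, groups == comparison[1L], drop = FALSE]
  y <- pep_qm$values[, groups == comparison[2L], drop = FALSE]
  enough <- rowSums(!is.na(x)) >= 2L & rowSums(!is.na(y)) >= 2L
  n_excluded <- sum(!enough)
  if (n_excluded > 0L) {
    message(n_excluded,
            " peptide(s) excluded: < 2 observed values in a group")
  }
  x <- x[enough, , drop = FALSE]
  y <- y[enough, , drop = FALSE]
  tt <- .row_t_pooled(x, y)
  q <- bh_adjust(tt$p)
  idx <- match(rownames(x), peptides$peptide_id)
  prot_ratio <- unname(protein_ratios[peptides$parent[idx]])
  out <- data.frame(
    peptide_id = rownames(x),
    parent = peptides$parent[idx],
    start = peptides$start[idx], end = peptides$end[idx],
    peptide_ratio = tt$diff,
    protein_ratio = prot_ratio,
    gap = tt$diff - prot_ratio,
    p_value = tt$p, q_value = q,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "comparison") <- comparison
  out
}

#' Apply the ratio-gap filter to peptide ratio records
#'
#' @param records peptide ratio records from [peptide_ratios()].
#' @param thresholds [detection_thresholds()].
#' @return The subset of records passing the rule for the configured mode.
#' @export
detect_candidates <- function(records,
                              thresholds = detection_thresholds()) {
  stopifnot(inherits(thresholds, "detection_thresholds"))
  keep <- !is.na(records$protein_ratio) & !is.na(records$gap) &
    records$protein_ratio < thresholds$protein_ratio_max &
    records$gap >= thresholds$ratio_gap_min
  if (thresholds$mode == "strict") {
    keep <- keep & !is.na(records$q_value) &
      records$q_value < thresholds$peptide_q_max &
      records$peptide_ratio > 0
  }
  records[keep, , drop = FALSE]
}

#' Map a peptide onto targeting-sequence regions
#'
#' Computes the residue overlap of `[start, end]` with the chloroplast
#' transit peptide `[1, ctp_end]`, the lumenal targeting peptide
#' `[ctp_end + 1, ltp_end]` and the mature region beyond, labels the
#' peptide by maximal overlap (ties broken toward the more N-terminal
#' region), and flags targeting evidence when at least one residue falls in
#' the cTP or lTP. Proteins without annotation map entirely to `mature`.
#'
#' @param start,end 1-based inclusive peptide coordinates in the
#'   preprotein.
#' @param ctp_end,ltp_end annotation boundaries; `NA` when absent (an lTP
#'   without a cTP is invalid).
#' @return List with `overlap_cTP`, `overlap_lTP`, `overlap_mature`
#'   (residue counts), `primary` (`"cTP"`, `"lTP"` or `"mature"`) and
#'   `targeting_evidence` (logical).
#' @export
map_peptide_to_region <- function(start, end, ctp_end = NA, ltp_end = NA) {
  if (is.na(start) || is.na(end) || end < start || start < 1L) {
    stop("invalid peptide coordinates: start=", start, ", end=", end)
  }
  if (!is.na(ltp_end) && is.na(ctp_end)) stop("ltp_end without ctp_end")
  overlap <- function(lo, hi) {
    if (is.na(lo) || is.na(hi) || hi < lo) return(0L)
    max(0L, min(end, hi) - max(start, lo) + 1L)
  }
  o_ctp <- if (is.na(ctp_end)) 0L else overlap(1L, ctp_end)
  o_ltp <- if (is.na(ltp_end)) 0L else overlap(ctp_end + 1L, ltp_end)
  mature_start <- if (!is.na(ltp_end)) ltp_end + 1L
    else if (!is.na(ctp_end)) ctp_end + 1L else 1L
  o_mat <- overlap(mature_start, end)
  counts <- c(cTP = o_ctp, lTP = o_ltp, mature = o_mat)
  primary <- names(counts)[which.max(counts)]  # ties -> most N-terminal
  list(overlap_cTP = o_ctp, overlap_lTP = o_ltp, overlap_mature = o_mat,
       primary = primary, targeting_evidence = (o_ctp + o_ltp) >= 1L)
}

#' Region labels for a table of peptide records
#'
#' Vectorized wrapper around [map_peptide_to_region()] joining records to
#' the annotation table by parent protein; unannotated parents get
#' `primary = "mature"` and no targeting evidence, and are flagged
#' `unmapped`.
#'
#' @param records data.frame with `parent`, `start`, `end`.
#' @param annotations annotation table (see [read_annotations()]).
#' @return `records` with columns `region`, `targeting_evidence`,
#'   `unmapped` appended.
#' @export
map_records_to_regions <- function(records, annotations) {
  idx <- match(records$parent, annotations$protein_id)
  region <- character(nrow(records))
  evidence <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    ctp <- if (is.na(idx[i])) NA else annotations$ctp_end[idx[i]]
    ltp <- if (is.na(idx[i])) NA else annotations$ltp_end[idx[i]]
    m <- map_peptide_to_region(records$start[i], records$end[i], ctp, ltp)
    region[i] <- m$primary
    evidence[i] <- m$targeting_evidence
  }
  records$region <- region
  records$targeting_evidence <- evidence
  records$unmapped <- is.na(idx)
  records
}

#' Positional ratio profile for one protein
#'
#' @param records peptide ratio records.
#' @param protein_id parent protein to profile.
#' @param alpha q-value threshold marking individually significant peptides.
#' @return data.frame sorted by `start` with `start`, `end`,
#'   `peptide_ratio`, `significant` — ratio versus sequence position,
#'   ready for plotting.
#' @export
positional_profile <- function(records, protein_id, alpha = 0.05) {
  rec <- records[records$parent == protein_id, , drop = FALSE]
  rec <- rec[order(rec$start, rec$end), , drop = FALSE]
  data.frame(
    start = rec$start, end = rec$end, peptide_ratio = rec$peptide_ratio,
    significant = !is.na(rec$q_value) & rec$q_value < alpha,
    row.names = NULL
  )
}

#' Call preprotein accumulators from candidate peptides
#'
#' A protein is called an accumulator when it has at least one candidate
#' peptide with targeting-region evidence and its protein ratio is below
#' the depletion ceiling. `mature_consistent` flags (but does not gate)
#' whether every quantified peptide lying wholly C-terminal of the
#' presequence stays below the gap threshold — the expected pattern for a
#' genuine processing intermediate, whose mature peptides should follow the
#' depleted protein.
#' Candidates on unannotated proteins are counted and flagged `unmapped`,
#' never dropped.
#'
#' @param candidates output of [detect_candidates()].
#' @param all_records full set of peptide ratio records (superset of
#'   `candidates`).
#' @param annotations annotation table.
#' @param thresholds [detection_thresholds()].
#' @return data.frame, one row per parent protein present in
#'   `all_records`: `protein_id`, `protein_ratio`,
#'   `n_targeting_candidates`, `mature_consistent`, `unmapped`, `verdict`
#'   (`"accumulator"` or `"none"`).
#' @export
call_processing_intermediates <- function(candidates, all_records,
                                          annotations,
                                          thresholds = detection_thresholds()) {
  stopifnot(inherits(thresholds, "detection_thresholds"))
  key <- function(d) paste(d$parent, d$peptide_id, sep = "\r")
  if (!all(key(candidates) %in% key(all_records))) {
    stop("candidates must be a subset of all_records")
  }
  cand <- map_records_to_regions(candidates, annotations)
  all_r <- map_records_to_regions(all_records, annotations)
  proteins <- unique(all_records$parent)
  rows <- lapply(proteins, function(p) {
    cp <- cand[cand$parent == p, , drop = FALSE]
    ap <- all_r[all_r$parent == p, , drop = FALSE]
    prot_ratio <- ap$protein_ratio[1L]
    n_targeting <- sum(cp$targeting_evidence)
    # wholly mature peptides only: a boundary-spanning peptide still carries
    # presequence residues and may legitimately accumulate
    mature <- ap[!ap$targeting_evidence & !ap$unmapped, , drop = FALSE]
    mature_ok <- nrow(mature) == 0L ||
      all(mature$gap < thresholds$ratio_gap_min, na.rm = TRUE)
    verdict <- if (n_targeting >= 1L && !is.na(prot_ratio) &&
                   prot_ratio < thresholds$protein_ratio_max) {
      "accumulator"
    } else {
      "none"
    }
    data.frame(
      protein_id = p, protein_ratio = prot_ratio,
      n_targeting_candidates = n_targeting,
      n_candidates = nrow(cp),
      mature_consistent = mature_ok,
      unmapped = any(cp$unmapped),
      verdict = verdict,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
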