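#' Reported significance counts for the red-light proteome comparisons
#'
#' The published per-comparison counts of protein groups passing the
#' BH-corrected t-test (q < 0.05) in the Arabidopsis red-light study of
#' Col-0, abc1k1 and var2 seedlings, against the common denominator of 9086
#' quantified protein groups. Shipped as a plain-text reference input for
#' [summarize_significance()]-style percentage reporting.
#'
#' @return data.frame with `comparison`, `n_significant`, `total`.
#' @export
reported_significance_counts <- function() {
  path <- system.file("extdata", "significance_counts.tsv",
                      package = "preproscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reported targeting-sequence-spanning peptides (abc1k1 RL vs Col RL)
#'
#' The published table of chloroplast-protein peptides that pass the
#' ratio-gap selection (protein log2 ratio below -0.4 and peptide ratio at
#' least 1.0 log2 above it) in the abc1k1 versus Col-0 red-light
#' comparison: 24 peptides over 20 proteins, with peptide start positions
#' in the preprotein, sequences, and a thylakoid-lumen flag. Used as a
#' reference input for validating [detect_candidates()].
#'
#' @return data.frame in peptide-ratio-record form (`peptide_id`, `parent`,
#'   `start`, `end`, `peptide_ratio`, `protein_ratio`, `gap`) plus the
#'   original annotation columns.
#' @export
reported_targeting_peptides <- function() {
  path <- system.file("extdata", "targeting_peptides.tsv",
                      package = "preproscan", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    peptide_id = sprintf("%s_%d_%s", tab$gene, tab$start, tab$sequence),
    parent = tab$araport_id,
    start = tab$start,
    end = tab$start + nchar(tab$sequence) - 1L,
    peptide_ratio = tab$peptide_ratio,
    protein_ratio = tab$protein_ratio,
    gap = tab$peptide_ratio - tab$protein_ratio,
    p_value = NA_real_, q_value = NA_real_,
    gene = tab$gene, uniprot_id = tab$uniprot_id,
    sequence = tab$sequence, thylakoid_lumen = tab$thylakoid_lumen,
    stringsAsFactors = FALSE
  )
}
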