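#' Assemble a full-run configuration
#'
#' One serializable object holding every knob of a simulate -> preprocess ->
#' differential -> peptide-scan run. Outputs are a deterministic function of
#' the configuration: the master `seed` is expanded into fixed per-stage
#' seeds (simulation, protein imputation, peptide imputation) so stages can
#' be rerun independently with identical results.
#'
#' @param seed master integer seed.
#' @param sim [simulation_params()]; its own seed is overridden by the
#'   master seed.
#' @param min_reps minimum valid values per condition for the protein-level
#'   filter.
#' @param impute_width,impute_shift down-shifted imputation parameters.
#' @param alpha significance threshold for differential tests.
#' @param enrich_q,enrich_min_size 1D enrichment q threshold and minimum
#'   term size.
#' @param comparison `c(mutant, control)` pair for the peptide scan.
#' @param thresholds [detection_thresholds()] for the ratio-gap filter.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = simulation_params(),
                       min_reps = 3L,
                       impute_width = 0.3, impute_shift = 1.8,
                       alpha = 0.05,
                       enrich_q = 0.02, enrich_min_size = 10L,
                       comparison = c("abc1k1_RL", "Col_RL"),
                       thresholds = detection_thresholds()) {
  stopifnot(inherits(sim, "simulation_params"),
            inherits(thresholds, "detection_thresholds"))
  seed <- as.integer(seed)
  sim$seed <- seed
  structure(
    list(seed = seed, sim = sim, min_reps = as.integer(min_reps),
         impute_width = impute_width, impute_shift = impute_shift,
         alpha = alpha, enrich_q = enrich_q,
         enrich_min_size = as.integer(enrich_min_size),
         comparison = comparison, thresholds = thresholds),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `seed`, `min_reps`, `impute_width`,
#' `impute_shift`, `alpha`, `enrich_q`, `enrich_min_size`, `comparison`
#' (2-element list), plus nested mappings `sim` (fields of
#' [simulation_params()]) and `thresholds` (fields of
#' [detection_thresholds()]).
#'
#' @param path YAML file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$class_fractions)) {
    sim_args$class_fractions <- unlist(sim_args$class_fractions)
  }
  if (!is.null(sim_args$protein_effect_log2)) {
    sim_args$protein_effect_log2 <-
      lapply(sim_args$protein_effect_log2, unlist)
  }
  sim <- do.call(simulation_params, sim_args %||% list())
  thr <- do.call(detection_thresholds, y$thresholds %||% list())
  args <- y[setdiff(names(y), c("sim", "thresholds"))]
  if (!is.null(args$comparison)) args$comparison <- unlist(args$comparison)
  do.call(run_config, c(args, list(sim = sim, thresholds = thr)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline into a directory
#'
#' Simulates a peptide-level DIA experiment, summarizes to protein groups
#' (sum of assigned peptide intensities), processes the protein table
#' (log2 -> minimum-valid filter -> down-shifted imputation -> median
#' normalization), computes all pairwise differential statistics, PCA and
#' 1D annotation enrichment, then runs the peptide-centric preprotein scan
#' (reference-only imputation, ratio-gap filter, region mapping, calls).
#' All outputs are TSV; a `run.log` echoes parameters and seeds. Outputs
#' are byte-identical across runs with the same configuration.
#'
#' @param config [run_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `protein_processed`, `differential`, `summary`, `pca`, `enrichment`,
#'   `peptide_records`, `candidates`, `calls`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed_impute_protein <- config$seed + 1000L
  seed_impute_peptide <- config$seed + 2000L

  proteome <- stage("proteome", generate_proteome(config$sim))
  sim <- stage("simulate", simulate_experiment(config$sim, proteome))
  write_fasta(proteome$proteins, file.path(out_dir, "proteome.fasta"))
  write_design_tsv(sim$design, file.path(out_dir, "design.tsv"))
  write_quant_tsv(sim$matrix, file.path(out_dir, "quant.tsv"),
                  peptides = sim$peptides)
  write_annotations(proteome$annotations,
                    file.path(out_dir, "annotations.tsv"))
  .write_tsv(sim$truth$proteins, file.path(out_dir, "truth_proteins.tsv"))
  .write_tsv(sim$truth$peptides, file.path(out_dir, "truth_peptides.tsv"))

  prot <- stage("preprocess", {
    prot <- summarize_protein(sim$matrix, sim$peptides)
    prot <- log2_transform(prot)
    prot <- filter_min_valid(prot, config$min_reps)
    prot <- impute_downshift(prot, width = config$impute_width,
                             shift = config$impute_shift,
                             seed = seed_impute_protein)
    median_normalize(prot)
  })
  write_quant_tsv(prot, file.path(out_dir, "processed_protein.tsv"))

  diff <- stage("differential", pairwise_ttests(prot, alpha = config$alpha))
  .write_tsv(diff, file.path(out_dir, "differential.tsv"))
  signif_summary <- summarize_significance(diff, total = nrow(prot$values))
  .write_tsv(signif_summary, file.path(out_dir, "summary.tsv"))

  pca <- stage("pca", pca_samples(prot))
  pca_tab <- data.frame(sample_id = rownames(pca$scores),
                        condition = design_groups(prot$design),
                        pca$scores[, seq_len(min(3L, ncol(pca$scores))),
                                   drop = FALSE])
  .write_tsv(pca_tab, file.path(out_dir, "pca.tsv"))
  .write_tsv(data.frame(component = seq_along(pca$var_fraction_all),
                        var_fraction = pca$var_fraction_all),
             file.path(out_dir, "pca_variance.tsv"))

  term_map <- term_map_from_annotations(proteome$annotations)
  cmp_key <- diff$group_a == config$comparison[1L] &
    diff$group_b == config$comparison[2L]
  if (!any(cmp_key)) {
    cmp_key <- diff$group_a == config$comparison[2L] &
      diff$group_b == config$comparison[1L]
    diff_vec <- -diff$diff_means[cmp_key]
  } else {
    diff_vec <- diff$diff_means[cmp_key]
  }
  names(diff_vec) <- diff$feature_id[cmp_key]
  enr <- stage("enrichment",
               enrich_1d(diff_vec, term_map,
                         min_size = config$enrich_min_size,
                         q_threshold = config$enrich_q))
  .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  records <- stage("pepscan", {
    pep_log2 <- log2_transform(sim$matrix)
    prot_ratios <- group_mean_diff(prot, config$comparison)
    peptide_ratios(pep_log2, sim$peptides, prot_ratios,
                   comparison = config$comparison,
                   width = config$impute_width, shift = config$impute_shift,
                   seed = seed_impute_peptide)
  })
  .write_tsv(records, file.path(out_dir, "peptide_ratios.tsv"))
  candidates <- detect_candidates(records, config$thresholds)
  .write_tsv(map_records_to_regions(candidates, proteome$annotations),
             file.path(out_dir, "candidates.tsv"))
  calls <- call_processing_intermediates(candidates, records,
                                         proteome$annotations,
                                         config$thresholds)
  .write_tsv(calls, file.path(out_dir, "calls.tsv"))

  called <- calls$protein_id[calls$verdict == "accumulator"]
  profiles <- do.call(rbind, lapply(called, function(p) {
    cbind(protein_id = p, positional_profile(records, p, config$alpha))
  }))
  if (is.null(profiles)) {
    profiles <- data.frame(protein_id = character(0), start = integer(0),
                           end = integer(0), peptide_ratio = numeric(0),
                           significant = logical(0))
  }
  .write_tsv(profiles, file.path(out_dir, "profiles.tsv"))

  log_lines <- c(
    paste0("preproscan ", as.character(utils::packageVersion("preproscan"))),
    paste0("R ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("stage seeds: simulate=", config$seed,
           " impute_protein=", seed_impute_protein,
           " impute_peptide=", seed_impute_peptide),
    paste0("n_proteins: ", config$sim$n_proteins),
    paste0("n_peptides: ", nrow(sim$matrix$values)),
    paste0("proteins after filter: ", nrow(prot$values)),
    paste0("comparison: ", paste(config$comparison, collapse = " vs ")),
    paste0("thresholds: protein_ratio_max=",
           config$thresholds$protein_ratio_max,
           " ratio_gap_min=", config$thresholds$ratio_gap_min,
           " mode=", config$thresholds$mode),
    paste0("candidates: ", nrow(candidates)),
    paste0("accumulator calls: ", length(called))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(sim = sim, protein_processed = prot, differential = diff,
                 summary = signif_summary, pca = pca, enrichment = enr,
                 peptide_records = records, candidates = candidates,
                 calls = calls, profiles = profiles))
}

#' Build diagnostic figures for a completed run
#'
#' Reads the stage outputs of [run_all()] from `run_dir` and constructs
#' three figures: a volcano plot of the configured comparison (log2
#' difference vs -log10 p, with the significance band), the ratio-gap
#' plane (peptide gap vs protein ratio with the threshold guides), and
#' positional profiles (peptide ratio vs sequence position) for called
#' accumulators. Figures are returned as ggplot objects and, when
#' `save = TRUE`, also written as PNGs next to the tables (failures to
#' open a graphics device degrade to a warning; the tables are the record
#' of the run).
#'
#' @param run_dir directory written by [run_all()].
#' @param thresholds [detection_thresholds()] used for guide lines.
#' @param alpha significance threshold shown on the volcano plot.
#' @param save write PNG files into `run_dir`.
#' @return Named list of ggplot objects (`volcano`, `gap`, `profiles`).
#' @export
make_report <- function(run_dir, thresholds = detection_thresholds(),
                        alpha = 0.05, save = TRUE) {
  need <- c("differential.tsv", "peptide_ratios.tsv", "calls.tsv",
            "profiles.tsv")
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent) > 0L) {
    stop("missing stage output(s) in ", run_dir, ": ",
         paste(absent, collapse = ", "))
  }
  diff <- utils::read.delim(file.path(run_dir, "differential.tsv"))
  records <- utils::read.delim(file.path(run_dir, "peptide_ratios.tsv"))
  profiles <- utils::read.delim(file.path(run_dir, "profiles.tsv"))

  volcano <- ggplot2::ggplot(
    diff, ggplot2::aes(x = diff_means, y = -log10(p_value),
                       colour = significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "black")) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 difference of means", y = "-log10 p-value",
                  title = "Protein-level differential abundance") +
    ggplot2::theme_minimal()

  gap_plot <- ggplot2::ggplot(
    records, ggplot2::aes(x = protein_ratio, y = gap)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_vline(xintercept = thresholds$protein_ratio_max,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = thresholds$ratio_gap_min,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "protein ratio (log2)",
                  y = "peptide - protein ratio gap (log2)",
                  title = "Ratio-gap plane") +
    ggplot2::theme_minimal()

  if (nrow(profiles) > 0L) {
    profile_plot <- ggplot2::ggplot(
      profiles, ggplot2::aes(x = start, y = peptide_ratio,
                             colour = significant)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::facet_wrap(~protein_id, scales = "free_x") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                              `TRUE` = "red")) +
      ggplot2::labs(x = "peptide start position (residue)",
                    y = "peptide ratio (log2)",
                    title = "Positional profiles of called accumulators") +
      ggplot2::theme_minimal()
  } else {
    profile_plot <- ggplot2::ggplot() +
      ggplot2::labs(title = "No accumulator calls") +
      ggplot2::theme_void()
  }

  plots <- list(volcano = volcano, gap = gap_plot, profiles = profile_plot)
  if (save) {
    for (nm in names(plots)) {
      tryCatch(
        suppressMessages(ggplot2::ggsave(
          file.path(run_dir, paste0(nm, ".png")), plots[[nm]],
          width = 7, height = 5, dpi = 150)),
        error = function(e) warning("could not save ", nm, ".png: ",
                                    conditionMessage(e))
      )
    }
  }
  plots
}
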