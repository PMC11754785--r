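make_records <- function(protein_ratio, peptide_ratio, parent = "P1",
                         start = 10L, len = 10L, q = NA_real_) {
  n <- length(peptide_ratio)
  data.frame(
    peptide_id = sprintf("pep%02d", seq_len(n)),
    parent = rep_len(parent, n), start = rep_len(start, n),
    end = rep_len(start, n) + rep_len(len, n) - 1L,
    peptide_ratio = peptide_ratio,
    protein_ratio = rep_len(protein_ratio, n),
    gap = peptide_ratio - rep_len(protein_ratio, n),
    p_value = rep_len(q, n), q_value = rep_len(q, n),
    stringsAsFactors = FALSE
  )
}

test_that("protein-relative normalization is elementwise division", {
  design <- toy_design(genotypes = "Col", n_rep = 2L)
  pep_vals <- matrix(c(100, 200, 300, 600), 2L, byrow = TRUE,
                     dimnames = list(c("p1", "p2"), design$sample_id))
  prot_vals <- matrix(c(400, 800), 1L, dimnames = list("P1", design$sample_id))
  peptides <- data.frame(peptide_id = c("p1", "p2"),
                         sequence = strrep("A", 5L), parent = "P1",
                         start = 1L, end = 5L, proteotypic = TRUE)
  pep <- quant_matrix(pep_vals, design, scale = "raw", level = "peptide")
  prot <- quant_matrix(prot_vals, design, scale = "raw", level = "protein")
  norm <- normalize_peptides_by_protein(pep, prot, peptides)
  expect_equal(norm$values["p1", 1L], 0.25)
  expect_equal(norm$values, pep_vals / prot_vals[c(1L, 1L), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # fully observed peptides of one parent sum to 1 after normalization
  expect_equal(unname(colSums(norm$values)), c(1, 1), tolerance = 1e-12)

  prot0 <- prot
  prot0$values[1L, 1L] <- 0
  expect_error(normalize_peptides_by_protein(pep, prot0, peptides),
               "division undefined")
  prot_na <- prot
  prot_na$values[1L, 2L] <- NA_real_
  norm_na <- normalize_peptides_by_protein(pep, prot_na, peptides)
  expect_true(all(is.na(norm_na$values[, 2L])))
})

test_that("the ratio-gap filter applies the published rule", {
  thr <- detection_thresholds()  # protein < -0.4, gap >= 1.0, extended
  # printed pairs: strongly depleted protein with a +4.14 targeting peptide,
  # and the boundary-near case with gap 1.13
  rec <- make_records(c(-1.50, -1.03, 0.0),
                      peptide_ratio = c(4.14, 0.10, 5.0))
  rec$protein_ratio <- c(-1.50, -1.03, 0.0)
  rec$gap <- rec$peptide_ratio - rec$protein_ratio
  kept <- detect_candidates(rec, thr)
  expect_identical(kept$peptide_id, c("pep01", "pep02"))

  # one-line set-comprehension oracle
  oracle <- rec[rec$protein_ratio < -0.4 &
                  rec$peptide_ratio - rec$protein_ratio >= 1.0, ]
  expect_identical(kept$peptide_id, oracle$peptide_id)
})

test_that("all 24 published targeting peptides pass in extended mode", {
  tab <- reported_targeting_peptides()
  kept <- detect_candidates(tab, detection_thresholds(mode = "extended"))
  expect_identical(nrow(kept), 24L)
  # perturbing either criterion ejects a row
  bump <- tab
  bump$protein_ratio[1L] <- -0.3
  bump$gap[1L] <- bump$peptide_ratio[1L] - bump$protein_ratio[1L]
  expect_identical(nrow(detect_candidates(bump)), 23L)
  shrink <- tab
  shrink$peptide_ratio[5L] <- shrink$protein_ratio[5L] + 0.99
  shrink$gap[5L] <- 0.99
  expect_identical(nrow(detect_candidates(shrink)), 23L)
})

test_that("raising the gap threshold never adds candidates", {
  withr::with_seed(141L, {
    rec <- make_records(runif(200L, -3, 1), peptide_ratio = runif(200L, -3, 5))
    rec$protein_ratio <- runif(200L, -3, 1)
    rec$gap <- rec$peptide_ratio - rec$protein_ratio
  })
  prev <- detect_candidates(rec, detection_thresholds(ratio_gap_min = 0.5))
  for (g in c(1, 1.5, 2, 3)) {
    cur <- detect_candidates(rec, detection_thresholds(ratio_gap_min = g))
    expect_true(all(cur$peptide_id %in% prev$peptide_id))
    prev <- cur
  }
})

test_that("strict mode additionally demands significance and a positive ratio", {
  rec <- make_records(-1.5, peptide_ratio = c(2.0, 2.0, -0.2),
                      q = c(0.01, 0.2, 0.01))
  strict <- detection_thresholds(mode = "strict")
  kept <- detect_candidates(rec, strict)
  expect_identical(kept$peptide_id, "pep01")
  # extended mode keeps all three (gap >= 1, protein depleted)
  expect_identical(nrow(detect_candidates(rec)), 3L)
})

test_that("peptides map onto cTP/lTP/mature regions by maximal overlap", {
  # an N-terminal peptide ending exactly at the cTP boundary
  m <- map_peptide_to_region(37L, 46L, ctp_end = 46L, ltp_end = 85L)
  expect_identical(m$primary, "cTP")
  expect_true(m$targeting_evidence)
  expect_identical(m$overlap_cTP, 10L)

  # far downstream: mature, no evidence
  m2 <- map_peptide_to_region(200L, 215L, ctp_end = 46L, ltp_end = 85L)
  expect_identical(m2$primary, "mature")
  expect_false(m2$targeting_evidence)

  # spanning the cTP/lTP boundary: 6 residues cTP, 5 lTP -> cTP wins
  m3 <- map_peptide_to_region(40L, 50L, ctp_end = 45L, ltp_end = 85L)
  expect_identical(c(m3$overlap_cTP, m3$overlap_lTP), c(6L, 5L))
  expect_identical(m3$primary, "cTP")

  # cTP-only (stromal) protein: evidence from the cTP alone
  m4 <- map_peptide_to_region(10L, 30L, ctp_end = 40L, ltp_end = NA)
  expect_identical(m4$primary, "cTP")
  expect_true(m4$targeting_evidence)

  # unannotated protein: everything is mature
  m5 <- map_peptide_to_region(1L, 20L)
  expect_identical(m5$primary, "mature")
  expect_false(m5$targeting_evidence)

  expect_error(map_peptide_to_region(10L, 5L, 40L, 80L), "invalid")
  expect_error(map_peptide_to_region(5L, 10L, NA, 80L), "without ctp_end")
})

test_that("region overlap counts agree with residue-by-residue counting", {
  withr::with_seed(151L, {
    for (i in 1:50) {
      ctp <- sample(25:60, 1L)
      ltp <- ctp + sample(15:45, 1L)
      start <- sample(1:150, 1L)
      end <- start + sample(0:40, 1L)
      m <- map_peptide_to_region(start, end, ctp, ltp)
      residues <- start:end
      expect_identical(m$overlap_cTP, sum(residues <= ctp))
      expect_identical(m$overlap_lTP, sum(residues > ctp & residues <= ltp))
      expect_identical(m$overlap_mature, sum(residues > ltp))
    }
  })
})

test_that("positional profiles are ordered by start position", {
  rec <- make_records(-1, peptide_ratio = c(3, 1, 2))
  rec$start <- c(50L, 5L, 20L)
  rec$end <- rec$start + 9L
  prof <- positional_profile(rec, "P1")
  expect_identical(prof$start, c(5L, 20L, 50L))
  expect_identical(nrow(positional_profile(rec, "nobody")), 0L)
})

test_that("gap from protein-relative ratios equals raw peptide minus protein ratio", {
  p <- simulation_params(n_proteins = 15L, n_accumulators = 2L,
                         dropout_prob = 0, seed = 161L)
  proteome <- generate_proteome(p)
  sim <- simulate_experiment(p, proteome)
  prot_raw <- summarize_protein(sim$matrix, sim$peptides)
  comparison <- c("abc1k1_RL", "Col_RL")
  prot_ratios <- group_mean_diff(log2_transform(prot_raw), comparison)
  rec <- peptide_ratios(log2_transform(sim$matrix), sim$peptides,
                        prot_ratios, comparison, impute_columns = character(0))
  norm <- normalize_peptides_by_protein(sim$matrix, prot_raw, sim$peptides)
  gap_norm <- group_mean_diff(log2_transform(norm), comparison)
  expect_equal(unname(gap_norm[rec$peptide_id]), rec$gap, tolerance = 1e-9)
})

test_that("peptide ratio records are reproducible and censoring-aware", {
  p <- simulation_params(n_proteins = 25L, n_accumulators = 3L, seed = 171L)
  sim <- simulate_experiment(p)
  prot <- median_normalize(impute_downshift(
    filter_min_valid(log2_transform(summarize_protein(sim$matrix,
                                                      sim$peptides)), 3L),
    seed = 1L))
  pr <- group_mean_diff(prot, c("abc1k1_RL", "Col_RL"))
  pep <- log2_transform(sim$matrix)
  r1 <- suppressMessages(peptide_ratios(pep, sim$peptides, pr,
                                        c("abc1k1_RL", "Col_RL"), seed = 5L))
  r2 <- suppressMessages(peptide_ratios(pep, sim$peptides, pr,
                                        c("abc1k1_RL", "Col_RL"), seed = 5L))
  expect_identical(r1, r2)
  expect_identical(r1$gap, r1$peptide_ratio - r1$protein_ratio)
  # control columns were imputed: every surviving record has full control data
  expect_true(all(rowSums(!is.na(
    pep$values[r1$peptide_id, sim$design$genotype == "abc1k1"])) >= 2L))
})

test_that("a fully censored control yields a large positive imputed ratio", {
  design <- toy_design(n_rep = 4L)
  withr::with_seed(181L, {
    vals <- matrix(rnorm(50L * 8L, 20, 1), 50L,
                   dimnames = list(sprintf("p%02d", 1:50), design$sample_id))
  })
  # peptide p01: strong in the mutant, never observed in the control
  vals["p01", design$genotype == "abc1k1"] <- 24
  vals["p01", design$genotype == "Col"] <- NA_real_
  qm <- quant_matrix(vals, design, scale = "log2", level = "peptide")
  peptides <- data.frame(peptide_id = rownames(vals),
                         sequence = strrep("A", 5L), parent = "P1",
                         start = 1L, end = 5L, proteotypic = TRUE)
  pr <- c(P1 = -1)
  rec <- peptide_ratios(qm, peptides, pr, c("abc1k1_RL", "Col_RL"),
                        seed = 9L)
  r <- rec[rec$peptide_id == "p01", ]
  # imputed control sits near mean - 1.8 sd, so the ratio is large positive
  expect_gt(r$peptide_ratio, 3)
})

test_that("accumulator calls recover the planted truth on one simulation", {
  p <- simulation_params(seed = 191L)
  res <- run_detection(p)
  truth <- res$truth$proteins
  planted <- truth$protein_id[truth$is_accumulator]
  called <- res$calls$protein_id[res$calls$verdict == "accumulator"]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.8)
  if (length(called) > 0L) {
    expect_lte(length(setdiff(called, planted)) / length(called), 0.2)
  }
  # positional check: candidate targeting peptides start inside the
  # annotated presequence
  ann <- res$annotations
  cand <- map_records_to_regions(res$candidates, ann)
  tp <- cand[cand$targeting_evidence, ]
  lim <- ifelse(is.na(ann$ltp_end), ann$ctp_end, ann$ltp_end)
  names(lim) <- ann$protein_id
  expect_true(all(tp$start <= lim[tp$parent]))
})

test_that("called accumulators have consistent mature peptides without dropout", {
  # with no censoring (hence no imputation noise) mature-region peptides of
  # a genuine intermediate follow the depleted protein, so no mature gap
  # reaches the threshold
  p <- simulation_params(n_proteins = 100L, n_accumulators = 10L,
                         dropout_prob = 0, seed = 195L)
  res <- run_detection(p)
  acc <- res$calls[res$calls$verdict == "accumulator", ]
  expect_gt(nrow(acc), 0L)
  expect_true(all(acc$mature_consistent))
})

test_that("verdicts require targeting evidence and annotation", {
  thr <- detection_thresholds()
  ann <- data.frame(protein_id = "P1", ctp_end = 40L, ltp_end = 80L,
                    compartment = "thylakoid_lumen", terms = "x")
  # candidate in the mature region only -> no accumulator call
  rec <- make_records(-1.5, peptide_ratio = 2, start = 200L)
  calls <- call_processing_intermediates(rec, rec, ann, thr)
  expect_identical(calls$verdict, "none")

  # unannotated protein: flagged unmapped, never called
  rec2 <- make_records(-1.5, peptide_ratio = 2, parent = "GHOST",
                       start = 10L)
  calls2 <- call_processing_intermediates(rec2, rec2, ann, thr)
  expect_identical(calls2$verdict, "none")
  expect_true(calls2$unmapped)

  # targeting candidate on a depleted, annotated protein -> accumulator
  rec3 <- make_records(-1.5, peptide_ratio = 2, start = 10L)
  calls3 <- call_processing_intermediates(rec3, rec3, ann, thr)
  expect_identical(calls3$verdict, "accumulator")
  expect_identical(calls3$n_targeting_candidates, 1L)

  expect_error(
    call_processing_intermediates(rec2, rec3, ann, thr),
    "subset"
  )
})
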