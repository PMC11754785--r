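# Shared builders and independent oracles used across test files.

toy_design <- function(genotypes = c("Col", "abc1k1"), lights = "RL",
                       n_rep = 3L) {
  conds <- expand.grid(genotype = genotypes, light = lights,
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_r%d", conds$genotype[i], conds$light[i],
                          seq_len(n_rep)),
      genotype = conds$genotype[i], light = conds$light[i],
      replicate = seq_len(n_rep), stringsAsFactors = FALSE
    )
  }))
}

toy_matrix <- function(n_feat = 10L, design = toy_design(), scale = "log2",
                       level = "protein", seed = 1L, mean = 20, sd = 1) {
  withr::with_seed(seed, {
    vals <- matrix(stats::rnorm(n_feat * nrow(design), mean, sd), n_feat,
                   dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                                   design$sample_id))
    if (scale == "raw") vals <- 2^vals
    quant_matrix(vals, design, scale = scale, level = level)
  })
}

# Step-up BH oracle: q_(m) = p_(m); q_(i) = min(q_(i+1), (m / i) * p_(i)).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  ps <- p[ord]
  q_sorted[m] <- min(1, ps[m])
  if (m > 1L) {
    for (i in (m - 1L):1L) {
      q_sorted[i] <- min(q_sorted[i + 1L], m / i * ps[i])
    }
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Exhaustive digestion oracle: every substring whose boundaries are valid
# Trypsin/P cut points, with missed-cleavage and length filters.
digest_oracle <- function(sequence, min_len = 7L, max_len = 52L,
                          max_missed = 2L) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  is_site <- chars %in% c("K", "R")
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      start_ok <- i == 1L || is_site[i - 1L]
      end_ok <- j == n || is_site[j]
      len <- j - i + 1L
      if (start_ok && end_ok && len >= min_len && len <= max_len) {
        # internal missed cleavages: K/R at positions i..j-1
        missed <- if (j > i) sum(is_site[i:(j - 1L)]) else 0L
        if (missed <= max_missed) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = paste(chars[i:j], collapse = ""),
            start = i, end = j, missed = missed
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  }
  do.call(rbind, out)
}

random_aa_sequence <- function(len, kr_prob = 0.1) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1L]]
  paste(ifelse(stats::runif(len) < kr_prob,
               sample(c("K", "R"), len, replace = TRUE),
               sample(aa, len, replace = TRUE)),
        collapse = "")
}

# Naive O(n^3) average-linkage (UPGMA) agglomeration on a Euclidean
# distance matrix; returns merge heights in order of agglomeration.
average_linkage_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# End-to-end detection on one simulated experiment; returns call table and
# planted truth.
run_detection <- function(params, thresholds = detection_thresholds()) {
  proteome <- generate_proteome(params)
  sim <- simulate_experiment(params, proteome)
  prot <- summarize_protein(sim$matrix, sim$peptides)
  prot <- log2_transform(prot)
  prot <- filter_min_valid(prot, min_reps = 3L)
  prot <- impute_downshift(prot, seed = params$seed + 1000L)
  prot <- median_normalize(prot)
  comparison <- c(params$preprotein_condition,
                  setdiff(names(params$protein_effect_log2),
                          params$preprotein_condition)[1L])
  prot_ratios <- group_mean_diff(prot, comparison)
  pep <- log2_transform(sim$matrix)
  records <- suppressMessages(
    peptide_ratios(pep, sim$peptides, prot_ratios, comparison,
                   seed = params$seed + 2000L)
  )
  candidates <- detect_candidates(records, thresholds)
  calls <- call_processing_intermediates(candidates, records,
                                         proteome$annotations, thresholds)
  list(calls = calls, truth = sim$truth, records = records,
       candidates = candidates, annotations = proteome$annotations)
}
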