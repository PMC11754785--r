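test_that("pooled t-tests match stats::t.test to 1e-12", {
  design <- toy_design(n_rep = 4L)
  qm <- toy_matrix(100L, design, seed = 61L)
  rec <- pairwise_ttests(qm)
  groups <- design_groups(design)
  for (i in sample(nrow(rec), 25L)) {
    x <- qm$values[rec$feature_id[i], groups == rec$group_a[i]]
    y <- qm$values[rec$feature_id[i], groups == rec$group_b[i]]
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(rec$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(rec$diff_means[i], mean(x) - mean(y), tolerance = 1e-12)
  }
})

test_that("t-test edge cases: identical groups, clear separation, zero variance", {
  design <- toy_design(n_rep = 3L)
  base <- matrix(rep(c(10, 11, 12), 2L), 3L, 6L, byrow = FALSE)
  vals <- rbind(same = c(base[1L, ]))
  vals <- matrix(c(10, 11, 12, 10, 11, 12), 1L,
                 dimnames = list("same", design$sample_id))
  qm <- quant_matrix(vals, design, scale = "log2", level = "protein")
  rec <- pairwise_ttests(qm)
  expect_equal(rec$diff_means, 0)
  expect_equal(rec$p_value, 1)

  withr::with_seed(3L, {
    sep <- matrix(c(10, 10, 10, 12, 12, 12) + rnorm(6L, 0, 1e-3), 1L,
                  dimnames = list("sep", design$sample_id))
  })
  qm2 <- quant_matrix(sep, design, scale = "log2", level = "protein")
  expect_lt(pairwise_ttests(qm2)$p_value, 1e-6)

  flat <- matrix(rep(c(1, 2), each = 3L), 1L,
                 dimnames = list("flat", design$sample_id))
  qm3 <- quant_matrix(flat, design, scale = "log2", level = "protein")
  expect_error(pairwise_ttests(qm3), "zero variance")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up oracle and is monotone", {
  withr::with_seed(71L, {
    for (i in 1:100) {
      p <- runif(sample(1:80, 1L))^sample(1:3, 1L)
      q <- bh_adjust(p)
      expect_identical(q, bh_oracle(p))
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-15))
      expect_true(all(q >= 0 & q <= 1))
    }
  })
})

test_that("significance summaries render percent of total half-up", {
  rec <- data.frame(
    group_a = rep(c("a", "b"), c(9086L, 9086L)),
    group_b = rep(c("x", "y"), c(9086L, 9086L)),
    significant = c(rep(c(TRUE, FALSE), c(4363L, 9086L - 4363L)),
                    rep(c(TRUE, FALSE), c(965L, 9086L - 965L)))
  )
  s <- summarize_significance(rec, total = 9086L)
  s <- s[order(s$comparison), ]
  expect_equal(s$percent[s$comparison == "a-x"], 48.02)
  expect_equal(s$percent[s$comparison == "b-y"], 10.62)

  none <- data.frame(group_a = "a", group_b = "b", significant = FALSE)
  expect_equal(summarize_significance(none, 10L)$percent, 0)
  expect_error(summarize_significance(none, 0L), "total")

  expect_equal(round_half_up(0.005, 2L), 0.01)  # base round() gives 0
  expect_equal(round_half_up(-0.005, 2L), -0.01)
})

test_that("sample PCA matches the covariance eigendecomposition", {
  design <- toy_design(n_rep = 6L)
  qm <- toy_matrix(100L, design, seed = 81L)
  pc <- pca_samples(qm)
  expect_equal(sum(pc$var_fraction_all), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$var_fraction_all) <= 1e-12))

  centered <- qm$values - rowMeans(qm$values)
  ev <- eigen(stats::cov(t(centered)), symmetric = TRUE)$values
  frac <- ev[seq_along(pc$var_fraction_all)] / sum(ev[ev > 1e-12])
  expect_equal(pc$var_fraction_all, frac, tolerance = 1e-9)

  # duplicated samples project identically
  dup <- qm
  dup$values[, 2L] <- dup$values[, 1L]
  sc <- pca_samples(dup)$scores
  expect_equal(sc[1L, ], sc[2L, ], tolerance = 1e-9)

  # a rank-1 matrix concentrates all variance on the first axis
  rank1 <- outer(rnorm(30L), seq_len(12L))
  rownames(rank1) <- sprintf("F%02d", 1:30)
  qm1 <- quant_matrix(rank1 + 20, design, scale = "log2", level = "protein")
  expect_equal(pca_samples(qm1)$var_fraction_all[1L], 1, tolerance = 1e-9)

  expect_error(pca_samples(qm, n_components = 1000L), "components")
})

test_that("row z-scoring standardizes rows and names constant offenders", {
  m <- matrix(c(1, 2, 3), 1L, dimnames = list("r1", NULL))
  expect_equal(zscore_rows(m)[1L, ], c(-1, 0, 1) / sd(c(1, 2, 3)),
               tolerance = 1e-12)

  design <- toy_design(n_rep = 3L)
  qm <- toy_matrix(20L, design, seed = 19L)
  z <- zscore_rows(qm)
  expect_lt(max(abs(rowMeans(z$values))), 1e-12)
  expect_lt(max(abs(apply(z$values, 1L, sd) - 1)), 1e-12)
  expect_equal(zscore_rows(z)$values, z$values, tolerance = 1e-12)

  qm$values["F005", ] <- 7
  expect_error(zscore_rows(qm), "F005")
})

test_that("average-linkage clustering matches a naive O(n^3) oracle", {
  withr::with_seed(91L, {
    x <- matrix(rnorm(20L * 6L), 20L,
                dimnames = list(sprintf("F%02d", 1:20), NULL))
  })
  hc <- hier_cluster(x)
  expect_equal(hc$height, average_linkage_oracle(x), tolerance = 1e-9)

  # identical rows merge at height zero; colinear points merge nearest first
  y <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hcy <- hier_cluster(y)
  expect_equal(hcy$height[1L], 0)
  z <- cbind(c(0, 1, 10))
  rownames(z) <- c("p0", "p1", "p10")
  hcz <- hier_cluster(z)
  expect_identical(sort(hcz$merge[1L, ]), c(-2L, -1L))

  expect_error(hier_cluster(x[1L, , drop = FALSE]), ">= 2")
  expect_error(hier_cluster(x, require_zscored = TRUE), "z-scored")
})

test_that("1D enrichment scores are rank-biserial with the right extremes", {
  diff <- c(rnorm(30L, 5, 0.1), rnorm(70L, -5, 0.1))
  names(diff) <- sprintf("F%03d", 1:100)
  tm <- list(high = names(diff)[1:30], all = names(diff))
  enr <- enrich_1d(diff, tm["high"], min_size = 10L)
  expect_equal(enr$score, 1)
  expect_true(enr$significant)
  expect_equal(enr$median_diff, median(diff[1:30]))

  expect_error(enrich_1d(diff, tm["all"]), "covers all features")
  small <- list(tiny = names(diff)[1:3])
  expect_identical(nrow(enrich_1d(diff, small, min_size = 10L)), 0L)
})

test_that("enrichment score is centred under random assignment", {
  withr::with_seed(101L, {
    diff <- rnorm(100L)
    names(diff) <- sprintf("F%03d", 1:100)
    scores <- replicate(1000L, {
      tm <- list(t = sample(names(diff), 20L))
      enrich_1d(diff, tm, min_size = 10L, q_threshold = 0.02)$score
    })
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("enrichment score sign tracks the in/out rank shift", {
  # U exceeds n_in*n_out/2 exactly when the mean in-term rank exceeds the
  # mean out-of-term rank, so the rank-biserial sign must follow that shift
  withr::with_seed(111L, {
    for (i in 1:25) {
      diff <- rnorm(60L)
      names(diff) <- sprintf("F%02d", 1:60)
      members <- sample(names(diff), 15L)
      enr <- enrich_1d(diff, list(t = members), min_size = 10L)
      r <- rank(diff)
      shift <- mean(r[members]) - mean(r[setdiff(names(diff), members)])
      if (abs(shift) > 1e-9) {
        expect_identical(sign(enr$score), sign(shift))
      }
    }
  })
})

test_that("category medians are plain medians of member fold changes", {
  diff <- c(a = -1, b = -2, c = -3, d = 5)
  tm <- list(down = c("a", "b", "c"), single = "d", ghost = character(0))
  cm <- category_medians(diff, tm, c("down", "single"))
  expect_equal(cm$median_diff, c(-2, 5))
  expect_error(category_medians(diff, tm, "ghost"), "no quantified members")
  expect_error(category_medians(diff, tm, "missing_term"), "absent")

  withr::with_seed(121L, {
    vals <- rnorm(50L)
    names(vals) <- sprintf("F%02d", 1:50)
    members <- sample(names(vals), 21L)
    cm2 <- category_medians(vals, list(x = members))
    srt <- sort(vals[members])
    expect_equal(cm2$median_diff, srt[11L], tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("BH keeps the false-positive fraction controlled under the global null", {
  # pooled over simulated null datasets the q<0.05 fraction stays near zero
  withr::with_seed(131L, {
    n_feat <- 100L
    design <- toy_design(n_rep = 4L)
    frac <- replicate(40L, {
      qm <- quant_matrix(
        matrix(rnorm(n_feat * 8L, 20, 1), n_feat,
               dimnames = list(sprintf("F%03d", 1:n_feat),
                               design$sample_id)),
        design, scale = "log2", level = "protein")
      mean(pairwise_ttests(qm)$q_value < 0.05)
    })
  })
  se <- sqrt(0.05 * 0.95 / (40L * n_feat))
  expect_lte(mean(frac), 0.05 + 3 * se)
})
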