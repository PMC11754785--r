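#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.005 -> 0.01), the rule
#' used when rendering percentage tables; base `round()` rounds half to
#' even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

.row_t_pooled <- function(x, y) {
  # two-sample Student's t with pooled variance, rowwise; NA-tolerant
  na_x <- is.na(x); na_y <- is.na(y)
  nx <- rowSums(!na_x); ny <- rowSums(!na_y)
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1L, 1L)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1L, 1L)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  stat <- (mx - my) / se
  p <- 2 * stats::pt(-abs(stat), df)
  p[nx < 2L | ny < 2L] <- NA_real_
  list(diff = mx - my, statistic = stat, p = p, df = df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return q-values in input order, clipped to 1 and monotone in the sorted
#'   order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise two-sample t-tests over condition groups
#'
#' Student's t with pooled variance for every feature and every requested
#' pair of (genotype, light) groups, with Benjamini-Hochberg correction
#' applied within each comparison separately (each comparison is its own
#' family, tested against the same full feature set).
#'
#' @param qm log2-scale `quant_matrix` without missing values (impute
#'   first); each group needs >= 2 samples.
#' @param comparisons list of `c(a, b)` condition pairs; default all pairs
#'   in design order.
#' @param alpha significance threshold on the q-value.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return data.frame of differential records: `feature_id`, `group_a`,
#'   `group_b`, `diff_means` (log2, a - b), `p_value`, `q_value`,
#'   `significant`.
#' @export
pairwise_ttests <- function(qm, comparisons = NULL, alpha = 0.05,
                            welch = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") stop("pairwise_ttests expects a log2-scale matrix")
  groups <- design_groups(qm$design)
  if (is.null(comparisons)) {
    lv <- unique(groups)
    comparisons <- utils::combn(lv, 2L, simplify = FALSE)
  }
  out <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    missing_grp <- setdiff(cmp, groups)
    if (length(missing_grp) > 0L) {
      stop("comparison group(s) absent from design: ",
           paste(missing_grp, collapse = ", "))
    }
    x <- qm$values[, groups == cmp[1L], drop = FALSE]
    y <- qm$values[, groups == cmp[2L], drop = FALSE]
    if (ncol(x) < 2L || ncol(y) < 2L) {
      stop("groups must have >= 2 samples: ", paste(cmp, collapse = " vs "))
    }
    if (welch) {
      res <- lapply(seq_len(nrow(x)), function(i) {
        t <- stats::t.test(x[i, ], y[i, ], var.equal = FALSE)
        c(diff = unname(t$estimate[1L] - t$estimate[2L]), p = t$p.value)
      })
      diff <- vapply(res, `[[`, numeric(1L), "diff")
      p <- vapply(res, `[[`, numeric(1L), "p")
    } else {
      zero_var <- apply(x, 1L, stats::var) == 0 | apply(y, 1L, stats::var) == 0
      if (all(zero_var)) {
        stop("a group has zero variance in every feature; ",
             "t-statistics undefined (use group_mean_diff for the ",
             "zero-noise limit)")
      }
      tt <- .row_t_pooled(x, y)
      diff <- tt$diff
      p <- tt$p
    }
    q <- bh_adjust(p)
    data.frame(
      feature_id = rownames(qm$values), group_a = cmp[1L], group_b = cmp[2L],
      diff_means = diff, p_value = p, q_value = q,
      significant = !is.na(q) & q < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Per-comparison significance counts and percentages
#'
#' @param records differential records from [pairwise_ttests()], or a
#'   data.frame with columns `group_a`, `group_b`, `significant`.
#' @param total total number of tested features (the denominator).
#' @return data.frame with `comparison`, `n_significant` and `percent`
#'   (100 x count / total, rounded half-up to two decimals).
#' @export
summarize_significance <- function(records, total) {
  if (total <= 0) stop("total must be > 0")
  key <- paste(records$group_a, records$group_b, sep = "-")
  counts <- tapply(records$significant, key, sum)
  data.frame(
    comparison = names(counts),
    n_significant = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / total, 2L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Principal component analysis of samples
#'
#' Features are centered; samples are projected onto the principal axes of
#' the feature-space covariance.
#'
#' @param qm log2-scale `quant_matrix` without missing values.
#' @param n_components number of components to return (default: all,
#'   `min(n_samples - 1, n_features)`).
#' @return List with `scores` (samples x components matrix) and
#'   `var_fraction` (variance fractions, non-increasing, summing to 1 over
#'   all components).
#' @export
pca_samples <- function(qm, n_components = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (anyNA(qm$values)) stop("PCA requires a complete matrix; impute first")
  if (ncol(qm$values) < 2L) stop("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(qm$values), center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- length(frac)
  if (!is.null(n_components)) {
    if (n_components > k) {
      stop("requested ", n_components, " components but only ", k,
           " are available")
    }
    k <- n_components
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_fraction = frac[seq_len(k)], var_fraction_all = frac)
}

#' Z-score rows of a matrix
#'
#' @param x numeric matrix (or `quant_matrix`).
#' @return Same shape with each row centered to mean 0 and scaled to sd 1.
#' @export
zscore_rows <- function(x) {
  vals <- if (inherits(x, "quant_matrix")) x$values else x
  stopifnot(is.matrix(vals))
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- rownames(vals)[sds == 0 | is.na(sds)]
    stop("constant or undefined row(s), z-score undefined: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- (vals - rowMeans(vals)) / sds
  if (inherits(x, "quant_matrix")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Agglomerative hierarchical clustering (Euclidean, average linkage)
#'
#' @param x numeric matrix, typically z-scored; rows are clustered for
#'   `axis = "features"`, columns for `axis = "samples"`.
#' @param axis which margin to cluster.
#' @param kmeans_k optional k: pre-aggregate rows into k centroids by
#'   k-means before clustering (a speed device for large matrices; off by
#'   default at desk scale).
#' @param require_zscored check that rows are z-scored (mean 0, sd 1).
#' @return An `hclust` object (merge history, heights, leaf order).
#' @export
hier_cluster <- function(x, axis = c("features", "samples"), kmeans_k = NULL,
                         require_zscored = FALSE) {
  axis <- match.arg(axis)
  vals <- if (inherits(x, "quant_matrix")) x$values else x
  stopifnot(is.matrix(vals))
  if (require_zscored) {
    ok <- max(abs(rowMeans(vals))) < 1e-8 &&
      max(abs(apply(vals, 1L, stats::sd) - 1)) < 1e-8
    if (!ok) stop("input rows are not z-scored; call zscore_rows() first")
  }
  if (axis == "samples") vals <- t(vals)
  if (!is.null(kmeans_k)) {
    km <- stats::kmeans(vals, centers = kmeans_k, nstart = 5L)
    vals <- km$centers
    rownames(vals) <- paste0("cluster", seq_len(nrow(vals)))
  }
  if (nrow(vals) < 2L) stop("clustering needs >= 2 items")
  stats::hclust(stats::dist(vals, method = "euclidean"), method = "average")
}

#' 1D annotation enrichment on fold changes
#'
#' For each category, a two-sided Mann-Whitney test of the in-term versus
#' out-of-term log2 differences, with the rank-biserial effect size
#' `score = 2 U / (n_in * n_out) - 1` (positive when in-term members tend to
#' have larger fold changes), the plain median of in-term differences, and
#' Benjamini-Hochberg control across terms.
#'
#' @param diff_means named numeric vector of per-feature log2 differences.
#' @param term_map named list: term -> character vector of member feature
#'   ids (non-members of `diff_means` are ignored).
#' @param min_size smallest in-term membership to test.
#' @param q_threshold significance threshold on the q-value.
#' @return data.frame of enrichment records: `term`, `size`, `score`,
#'   `median_diff`, `p_value`, `q_value`, `significant`.
#' @export
enrich_1d <- function(diff_means, term_map, min_size = 10L,
                      q_threshold = 0.02) {
  stopifnot(!is.null(names(diff_means)))
  diff_means <- diff_means[!is.na(diff_means)]
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(term_map[[term]], names(diff_means))
    n_in <- length(members)
    if (n_in < min_size) return(NULL)
    n_out <- length(diff_means) - n_in
    if (n_out == 0L) {
      stop("term '", term, "' covers all features; enrichment undefined")
    }
    x_in <- diff_means[members]
    x_out <- diff_means[setdiff(names(diff_means), members)]
    wt <- stats::wilcox.test(x_in, x_out, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
    u <- unname(wt$statistic)  # number of (in > out) pairs, ties as 1/2
    data.frame(
      term = term, size = n_in,
      score = 2 * u / (n_in * n_out) - 1,
      median_diff = stats::median(x_in),
      p_value = wt$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), size = integer(0),
                      score = numeric(0), median_diff = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_threshold
  out
}

#' Median log2 difference per category
#'
#' @param diff_means named numeric vector of per-feature log2 differences.
#' @param term_map named list: term -> member feature ids.
#' @param terms categories to report (must exist in `term_map`).
#' @return data.frame with `term`, `size`, `median_diff`.
#' @export
category_medians <- function(diff_means, term_map, terms = names(term_map)) {
  missing_terms <- setdiff(terms, names(term_map))
  if (length(missing_terms) > 0L) {
    stop("term(s) absent from term_map: ",
         paste(missing_terms, collapse = ", "))
  }
  rows <- lapply(terms, function(term) {
    members <- intersect(term_map[[term]], names(diff_means))
    vals <- diff_means[members]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) stop("term '", term, "' has no quantified members")
    data.frame(term = term, size = length(vals),
               median_diff = stats::median(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
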