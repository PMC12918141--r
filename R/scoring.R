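#' Default subscore weights
#'
#' Breadth +0.50, level +0.25, variation -0.25: the default composite
#' configuration. Breadth carries the largest weight (ubiquity proper), level
#' rewards robust expression, and variation is negatively weighted to
#' emphasize invariance.
#'
#' @return Named numeric vector of length 3.
#' @export
default_weights <- function() {
  c(breadth = 0.50, level = 0.25, variation = -0.25)
}

#' Scoring configuration
#'
#' One criterion per class plus signed weights defines a scoring variant. The
#' defaults (breadth = fraction of samples at or above the per-sample 95th
#' percentile, level = median of positive values, variation = quartile-based
#' coefficient of variation, weights +0.50/+0.25/-0.25) define the default
#' ubiquity score.
#'
#' @param breadth One of `"above_p95"`, `"above_median"`, `"above_zero"`.
#' @param level One of `"median"`, `"mean"`.
#' @param variation One of `"qcv"`, `"iqr"`, `"cv"`, `"sd"`.
#' @param weights Named or positional numeric vector `(breadth, level,
#'   variation)`; breadth and level weights must be >= 0, the variation weight
#'   <= 0, and not all zero.
#' @return A `ubiq_config` list.
#' @export
scoring_config <- function(breadth = c("above_p95", "above_median", "above_zero"),
                           level = c("median", "mean"),
                           variation = c("qcv", "iqr", "cv", "sd"),
                           weights = default_weights()) {
  breadth <- match.arg(breadth)
  level <- match.arg(level)
  variation <- match.arg(variation)
  weights <- validate_weights(weights)
  structure(list(breadth = breadth, level = level, variation = variation,
                 weights = weights), class = "ubiq_config")
}

validate_weights <- function(weights) {
  if (length(weights) != 3L || !is.numeric(weights) || anyNA(weights))
    stop("`weights` must be 3 finite numbers (breadth, level, variation)",
         call. = FALSE)
  weights <- stats::setNames(as.numeric(weights),
                             c("breadth", "level", "variation"))
  if (weights[["breadth"]] < 0 || weights[["level"]] < 0)
    stop("breadth and level weights must be >= 0", call. = FALSE)
  if (weights[["variation"]] > 0)
    stop("variation weight must be <= 0", call. = FALSE)
  if (all(weights == 0))
    stop("weights must not all be zero", call. = FALSE)
  weights
}

#' Per-sample expression thresholds
#'
#' The breadth criterion compares each gene against a threshold computed
#' separately for every sample, which makes the subscore independent of
#' overall expression levels. `above_p95` uses the 95th percentile of all
#' values of the sample (zeros included, linear-interpolation quantile),
#' `above_median` the per-sample median (zeros included), `above_zero` is the
#' constant 0.
#'
#' @param m Expression matrix.
#' @param criterion Breadth criterion name.
#' @return Named numeric vector, one threshold per sample.
#' @export
sample_thresholds <- function(m, criterion = c("above_p95", "above_median",
                                               "above_zero")) {
  criterion <- match.arg(criterion)
  m <- validate_expression_matrix(m)
  th <- switch(criterion,
    above_p95 = apply(m, 2L, stats::quantile, probs = 0.95, names = FALSE),
    above_median = apply(m, 2L, stats::median),
    above_zero = rep(0, ncol(m))
  )
  stats::setNames(as.numeric(th), colnames(m))
}

#' Breadth subscore
#'
#' Fraction of samples (denominator: all samples) in which the gene meets or
#' exceeds the sample-specific threshold. For `above_p95`/`above_median` the
#' comparison is `>=` ("meets or exceeds"); for `above_zero` it is strict
#' (`> 0` — a zero value is not expressed). Values lie in \[0, 1\] by
#' construction and are used as-is in the composite (no re-normalization).
#'
#' @inheritParams sample_thresholds
#' @return Named numeric vector in \[0, 1\], one value per gene.
#' @export
breadth_subscore <- function(m, criterion = c("above_p95", "above_median",
                                              "above_zero")) {
  criterion <- match.arg(criterion)
  th <- sample_thresholds(m, criterion)
  hits <- if (criterion == "above_zero") m > 0
          else sweep(m, 2L, th, `>=`)
  rowMeans(hits)
}

#' Level subscore (raw)
#'
#' Median or mean of each gene's strictly positive values; zeros are excluded
#' so the statistic is independent of the threshold-based breadth criterion.
#' A gene with no positive value gets raw level 0.
#'
#' @inheritParams sample_thresholds
#' @param criterion `"median"` or `"mean"`.
#' @return Named numeric vector of raw levels per gene.
#' @export
level_subscore <- function(m, criterion = c("median", "mean")) {
  criterion <- match.arg(criterion)
  m <- validate_expression_matrix(m)
  fun <- if (criterion == "median") stats::median else mean
  apply(m, 1L, function(x) {
    pos <- x[x > 0]
    if (!length(pos)) 0 else fun(pos)
  })
}

#' Variation subscore (raw)
#'
#' Dispersion of each gene's strictly positive values: `qcv` = interquartile
#' range / median (quartile-based coefficient of variation), `iqr`, `cv` =
#' sd/mean, `sd` (sample standard deviation, n-1 denominator). Quartiles use
#' linear interpolation between order statistics. A gene with exactly one
#' positive value gets 0; a gene with no positive value is assigned the
#' dataset's maximum raw variation (worst case), so undefined dispersion can
#' never promote an unexpressed gene.
#'
#' @inheritParams sample_thresholds
#' @param criterion `"qcv"`, `"iqr"`, `"cv"` or `"sd"`.
#' @return Named numeric vector of raw variation values per gene.
#' @export
variation_subscore <- function(m, criterion = c("qcv", "iqr", "cv", "sd")) {
  criterion <- match.arg(criterion)
  m <- validate_expression_matrix(m)
  stat <- switch(criterion,
    qcv = function(x) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      (q[3L] - q[1L]) / q[2L]
    },
    iqr = function(x) stats::IQR(x),
    cv = function(x) stats::sd(x) / mean(x),
    sd = stats::sd
  )
  raw <- apply(m, 1L, function(x) {
    pos <- x[x > 0]
    if (!length(pos)) return(NA_real_)       # all-zero: filled in below
    if (length(pos) == 1L) return(0)
    stat(pos)
  })
  if (anyNA(raw)) {
    worst <- if (all(is.na(raw))) 0 else max(raw, na.rm = TRUE)
    raw[is.na(raw)] <- worst
  }
  raw
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`; when all values are equal every output is 0.5
#' (degenerate convention that keeps weights meaningful instead of producing
#' NaN).
#'
#' @param x Numeric vector (length >= 1, finite).
#' @return Numeric vector in \[0, 1\].
#' @export
minmax <- function(x) {
  if (!length(x)) stop("minmax needs at least one value", call. = FALSE)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Score genes for expression ubiquity
#'
#' The package's central fit: computes the three subscores (breadth, level,
#' variation) for every gene of an expression matrix, min-max normalizes the
#' level and variation statistics (the breadth fraction is already in
#' \[0, 1\]), combines them as the weighted sum `w_b * s_b + w_l * s_l +
#' w_v * s_v`, and min-max normalizes the composite so the best gene scores
#' 1 and the worst 0. Ranks are assigned by descending score with gene-ID
#' ascending as deterministic tie-break; the percentile of a gene is
#' `100 * #[genes with score <= its score] / N`.
#'
#' @param m Expression matrix (genes x samples, >= 2 samples).
#' @param config A [scoring_config()]; alternatively pass the individual
#'   criteria/weights.
#' @inheritParams scoring_config
#' @return A `ubiq_scores` data.frame with columns `gene_id`, `breadth`,
#'   `level_raw`, `level`, `variation_raw`, `variation`, `score`, `rank`,
#'   `percentile`, ordered by rank; attributes `config`, `n_samples`, `meta`.
#' @examples
#' sim <- simulate_expression(synthetic_spec(n_samples = 20, n_ubiquitous = 10,
#'   n_specific = 30, n_variable = 5, n_silent = 5, seed = 1))
#' fit <- ubiquity_score(sim$matrix)
#' head(fit)
#' @export
ubiquity_score <- function(m, config = NULL,
                           breadth = "above_p95", level = "median",
                           variation = "qcv", weights = default_weights()) {
  if (is.null(config))
    config <- scoring_config(breadth, level, variation, weights)
  m <- validate_expression_matrix(m, require_samples = 2L)
  sub <- compute_subscores(m, config)
  compose_from_subscores(sub, config, n_samples = ncol(m),
                         meta = attr(m, "meta"))
}

# Subscores depend on the criteria only, never on the weights; sensitivity
# analysis recomputes composites over a weight grid from one subscore set.
compute_subscores <- function(m, config) {
  s_b <- breadth_subscore(m, config$breadth)
  l_raw <- level_subscore(m, config$level)
  v_raw <- variation_subscore(m, config$variation)
  data.frame(gene_id = rownames(m), breadth = s_b,
             level_raw = l_raw, level = minmax(l_raw),
             variation_raw = v_raw, variation = minmax(v_raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

compose_from_subscores <- function(sub, config, n_samples = NA_integer_,
                                   meta = list()) {
  w <- config$weights
  raw <- w[["breadth"]] * sub$breadth + w[["level"]] * sub$level +
    w[["variation"]] * sub$variation
  sub$score <- minmax(raw)
  ord <- order(-sub$score, sub$gene_id)
  sub <- sub[ord, , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  # percentile: fraction of genes scoring <= this gene (ties share a value)
  n <- nrow(sub)
  sub$percentile <- 100 *
    (n + 1 - rank_max_desc(sub$score)) / n
  rownames(sub) <- NULL
  new_score_table(sub, config = config, n_samples = n_samples, meta = meta)
}

# For scores sorted descending: number of genes with score <= s(g) equals
# n + 1 - (max index among equal scores counted from the top); computed via
# rank with ties.method = "min" on descending order.
rank_max_desc <- function(score_desc) {
  rank(-score_desc, ties.method = "min")
}

new_score_table <- function(df, config, n_samples, meta = list()) {
  structure(df, class = c("ubiq_scores", "data.frame"),
            config = config, n_samples = n_samples, meta = meta)
}

#' @export
print.ubiq_scores <- function(x, n = 6L, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Ubiquity scores: %d genes", nrow(x)))
  if (!is.na(attr(x, "n_samples")))
    cat(sprintf(", %d samples", attr(x, "n_samples")))
  cat("\n")
  if (!is.null(cfg) && !is.na(cfg$breadth))
    cat(sprintf("  criteria: breadth=%s, level=%s, variation=%s; weights: %s\n",
                cfg$breadth, cfg$level, cfg$variation,
                paste(sprintf("%+.2f", cfg$weights), collapse = "/")))
  cat("Top genes:\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @export
summary.ubiq_scores <- function(object, top_fraction = 0.05, ...) {
  s <- list(
    n_genes = nrow(object),
    n_samples = attr(object, "n_samples"),
    config = attr(object, "config"),
    score_quantiles = stats::quantile(object$score,
                                      c(0, 0.25, 0.5, 0.75, 0.95, 1)),
    top_fraction = top_fraction,
    n_ubiquitous = floor(top_fraction * nrow(object)),
    top_genes = utils::head(object$gene_id, 10L)
  )
  class(s) <- "summary.ubiq_scores"
  s
}

#' @export
print.summary.ubiq_scores <- function(x, ...) {
  cat(sprintf("Ubiquity scoring of %d genes", x$n_genes))
  if (!is.na(x$n_samples)) cat(sprintf(" across %d samples", x$n_samples))
  cat("\n")
  cat(sprintf("Ubiquitous set (top %.1f%%): %d genes\n",
              100 * x$top_fraction, x$n_ubiquitous))
  cat("Score quantiles:\n")
  print(round(x$score_quantiles, 4))
  cat("Highest-scoring genes:", paste(x$top_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a score distribution
#'
#' Score against rank percentile, the standard view of a ubiquity ranking:
#' most genes score low and the curve rises steeply near the top.
#'
#' @param x A `ubiq_scores` table.
#' @param top_fraction Cutoff fraction marked with a dashed line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ubiq_scores <- function(x, top_fraction = 0.05, ...) {
  pct <- 100 * (nrow(x) - x$rank + 1) / nrow(x)
  graphics::plot(pct, x$score, type = "l", xlab = "rank percentile",
                 ylab = "composite score", ...)
  graphics::abline(v = 100 * (1 - top_fraction), lty = 2)
  invisible(x)
}
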