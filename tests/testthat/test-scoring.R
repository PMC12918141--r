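test_that("per-sample thresholds follow the linear-interpolation quantile", {
  m <- mat_fix(matrix(c(0, 0, 0, 10), 4, 1))
  expect_equal(unname(sample_thresholds(m, "above_zero")), 0)

  m <- mat_fix(matrix(c(1, 2, 3, 4), 4, 1))
  expect_equal(unname(sample_thresholds(m, "above_median")), 2.5)

  m <- mat_fix(matrix(1:100, 100, 1))
  expect_equal(unname(sample_thresholds(m, "above_p95")), 95.05)
})

test_that("breadth subscore honours >= for thresholds and > for above_zero", {
  # gene equal to the sample maximum in every sample
  m <- mat_fix(rbind(c(9, 9), c(1, 2), c(0, 0)))
  expect_equal(unname(breadth_subscore(m, "above_p95")["g01"]), 1)

  # all-zero gene under above_zero vs above_median with sample medians (0, 2)
  m <- mat_fix(rbind(c(0, 0), c(0, 2), c(0, 4)))
  expect_equal(unname(sample_thresholds(m, "above_median")), c(0, 2))
  expect_equal(unname(breadth_subscore(m, "above_zero")["g01"]), 0)
  expect_equal(unname(breadth_subscore(m, "above_median")["g01"]), 0.5)

  # 2 samples, gene above the per-sample p95 in exactly one
  m <- mat_fix(rbind(c(10, 1), c(1, 10), c(5, 5), c(2, 2)))
  expect_equal(unname(breadth_subscore(m, "above_p95")["g01"]), 0.5)
})

test_that("level subscore uses positive values only with zero fallback", {
  m <- mat_fix(rbind(c(0, 4, 6), c(0, 0, 0), c(2, 2, 2)))
  expect_equal(unname(level_subscore(m, "median")), c(5, 0, 2))
  expect_equal(unname(level_subscore(m, "mean")), c(5, 0, 2))
})

test_that("variation subscore matches the quartile and sd formulas", {
  m <- mat_fix(rbind(c(5, 5, 5, 5, 0), c(1, 2, 3, 4, 5), c(1, 3, 0, 0, 0)))
  qcv <- variation_subscore(m, "qcv")
  expect_equal(unname(qcv["g01"]), 0)
  expect_equal(unname(qcv["g02"]), (4 - 2) / 3)
  expect_equal(unname(variation_subscore(m, "sd")["g03"]), sqrt(2))
  expect_equal(unname(variation_subscore(m, "iqr")["g02"]), 2)
  expect_equal(unname(variation_subscore(m, "cv")["g02"]), sd(1:5) / 3)
})

test_that("all-zero genes get the worst observed variation, single-positive genes zero", {
  m <- mat_fix(rbind(c(0, 0, 0), c(1, 5, 9), c(0, 7, 0)))
  v <- variation_subscore(m, "qcv")
  expect_equal(unname(v["g01"]), max(v["g02"]))  # worst case
  expect_equal(unname(v["g03"]), 0)
})

test_that("min-max normalization maps to [0,1] with the 0.5 degenerate convention", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax(c(7, 7)), c(0.5, 0.5))
  expect_equal(minmax(c(0, 1, 3)), c(0, 1 / 3, 1))
})

test_that("composite scores reproduce the hand-computed 3-gene fixture", {
  # subscores (breadth, level, variation): (1,1,0), (0.5,0.5,0.5), (0,0,1)
  # raw composites under defaults: 0.75, 0.25, -0.25 -> scores 1, 0.5, 0
  sub <- data.frame(gene_id = c("gA", "gB", "gC"),
                    breadth = c(1, 0.5, 0), level_raw = NA, level = c(1, 0.5, 0),
                    variation_raw = NA, variation = c(0, 0.5, 1))
  out <- ubiscore:::compose_from_subscores(sub, scoring_config())
  expect_equal(out$score[match(c("gA", "gB", "gC"), out$gene_id)],
               c(1, 0.5, 0))
  expect_equal(out$rank[match(c("gA", "gB", "gC"), out$gene_id)], 1:3)
  expect_equal(out$percentile[out$gene_id == "gA"], 100)
})

test_that("final scores are invariant under positive weight rescaling", {
  for (seed in 1:5) {
    m <- rand_mat(60, 15, seed)
    f1 <- ubiquity_score(m)
    f2 <- ubiquity_score(m, weights = default_weights() * 3.7)
    expect_equal(f1$score, f2$score, tolerance = 1e-12)
    expect_equal(f1$gene_id, f2$gene_id)
  }
})

test_that("a gene's score is monotone in breadth and anti-monotone in variation", {
  set.seed(42)
  base <- data.frame(gene_id = sprintf("g%02d", 1:20),
                     breadth = runif(20), level_raw = NA, level = runif(20),
                     variation_raw = NA, variation = runif(20))
  cfg <- scoring_config()
  raw_score <- function(sub, id) {
    out <- ubiscore:::compose_from_subscores(sub, cfg)
    out$score[out$gene_id == id]
  }
  for (i in c(1, 7, 13)) {
    id <- base$gene_id[i]
    up <- base; up$breadth[i] <- min(1, up$breadth[i] + 0.2)
    expect_gte(raw_score(up, id), raw_score(base, id))
    worse <- base; worse$variation[i] <- min(1, worse$variation[i] + 0.2)
    expect_lte(raw_score(worse, id), raw_score(base, id))
  }
})

test_that("breadth is invariant under per-sample monotone transformations", {
  for (seed in 1:5) {
    m <- rand_mat(50, 8, seed, zero_frac = 0)
    transforms <- list(function(x) x^2, function(x) 3 * x + 1, log1p, sqrt)
    mt <- unclass(m)
    for (j in seq_len(ncol(mt)))
      mt[, j] <- transforms[[1 + (j %% 4)]](mt[, j])
    m2 <- expression_matrix(mt)
    for (crit in c("above_p95", "above_median"))
      expect_equal(breadth_subscore(m, crit), breadth_subscore(m2, crit),
                   info = crit)
  }
})

test_that("qcv/cv are scale-free while iqr/sd scale linearly", {
  m <- rand_mat(40, 10, 99, zero_frac = 0.1)
  m3 <- expression_matrix(unclass(m) * 5)
  expect_equal(variation_subscore(m, "qcv"), variation_subscore(m3, "qcv"))
  expect_equal(variation_subscore(m, "cv"), variation_subscore(m3, "cv"))
  expect_equal(5 * variation_subscore(m, "iqr"), variation_subscore(m3, "iqr"))
  expect_equal(5 * variation_subscore(m, "sd"), variation_subscore(m3, "sd"))
})

test_that("score table invariants hold on random data", {
  for (seed in 1:4) {
    m <- rand_mat(80, 12, seed)
    fit <- ubiquity_score(m)
    expect_equal(min(fit$score), 0)
    expect_equal(max(fit$score), 1)
    expect_setequal(fit$rank, seq_len(nrow(fit)))
    expect_true(all(diff(fit$percentile) <= 0))  # ordered by rank
    expect_true(all(fit$percentile >= 0 & fit$percentile <= 100))
  }
})

test_that("rank ties break deterministically by gene ID", {
  m <- mat_fix(rbind(c(1, 2), c(1, 2), c(5, 9)),
               genes = c("gB", "gA", "gC"))
  fit <- ubiquity_score(m)
  tied <- fit[fit$gene_id %in% c("gA", "gB"), ]
  expect_equal(tied$gene_id[order(tied$rank)], c("gA", "gB"))
})

test_that("configuration validation enforces weight signs", {
  expect_error(scoring_config(weights = c(-0.1, 0.25, -0.25)), ">= 0")
  expect_error(scoring_config(weights = c(0.5, 0.25, 0.25)), "<= 0")
  expect_error(scoring_config(weights = c(0, 0, 0)), "zero")
  expect_error(ubiquity_score(mat_fix(matrix(1:3, 3, 1))), "2 sample")
})
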