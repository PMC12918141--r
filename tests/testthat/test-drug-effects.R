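drug_fix <- function(rows) {
  drug_stats(do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], drug_id = r[[2]], p_value = as.numeric(r[[3]]),
               log_fc = as.numeric(r[[4]]),
               concentration = if (length(r) > 4) r[[5]] else NA_character_,
               stringsAsFactors = FALSE))), strip_versions = FALSE)
}

test_that("significance filter is boundary-inclusive at P <= alpha", {
  tab <- drug_fix(list(list("g1", "d1", 0.05, 1), list("g2", "d1", 0.051, 1),
                       list("g3", "d1", 0.049, 1)))
  kept <- significant_pairs(tab)
  expect_setequal(kept$gene_id, c("g1", "g3"))
  expect_equal(nrow(significant_pairs(tab[0, ])), 0L)
  expect_error(significant_pairs(tab, alpha = 0), "\\(0, 1\\)")
  expect_error(significant_pairs(tab, alpha = 1), "\\(0, 1\\)")
})

test_that("affected proportions and bias ratio follow the count definitions", {
  universe <- sprintf("g%02d", 1:10)
  ubiq <- universe[1:4]
  # d1 affects 2 ubiquitous + 3 non-ubiquitous genes
  tab <- drug_fix(list(list("g01", "d1", 0.01, 1), list("g02", "d1", 0.02, -1),
                       list("g05", "d1", 0.01, 2), list("g06", "d1", 0.03, 1),
                       list("g07", "d1", 0.04, 1)))
  s <- affected_proportions(significant_pairs(tab), ubiq, universe)
  expect_equal(s$prop_ubiq, 0.5)
  expect_equal(s$prop_nonubiq, 0.5)
  expect_equal(s$bias_ratio, 1)

  # drug affecting every ubiquitous gene and nothing else
  tab2 <- drug_fix(lapply(ubiq, function(g) list(g, "d2", 0.01, 1)))
  s2 <- affected_proportions(tab2, ubiq, universe)
  expect_equal(s2$prop_ubiq, 1)
  expect_equal(s2$bias_ratio, 0)

  # drug with no significant records is reported with omitted ratio
  s3 <- affected_proportions(tab2, ubiq, universe, drugs = c("d2", "d9"))
  expect_true(is.na(s3$bias_ratio[s3$drug_id == "d9"]))
  expect_equal(s3$prop_ubiq[s3$drug_id == "d9"], 0)

  expect_error(affected_proportions(tab2, universe, universe), "complement")
  expect_error(affected_proportions(tab2, "outside", universe), "subset")
})

test_that("a gene counts as affected if ANY concentration record is significant", {
  tab <- drug_fix(list(list("g01", "d1", 0.01, 1, "1uM"),
                       list("g01", "d1", 0.90, 1, "10uM"),
                       list("g02", "d1", 0.90, 1, "1uM")))
  s <- affected_proportions(significant_pairs(tab), "g01", c("g01", "g02"))
  expect_equal(s$n_affected_ubiq, 1L)
  expect_equal(s$n_affected_nonubiq, 0L)
})

test_that("bias ranking orders by ratio with Inf on top and ID tie-breaks", {
  summ <- data.frame(drug_id = c("d1", "d2", "d3", "d4", "d5"),
                     bias_ratio = c(0.2, 1.0, 5.0, Inf, NA),
                     stringsAsFactors = FALSE)
  r <- rank_by_bias(summ, top_n = 1L)
  expect_equal(r$ubiquitous_biased$drug_id, "d1")
  expect_equal(r$nonubiquitous_biased$drug_id, "d4")  # Inf above any finite

  ties <- data.frame(drug_id = c("dB", "dA"), bias_ratio = c(1, 1),
                     stringsAsFactors = FALSE)
  rt <- rank_by_bias(ties, top_n = 2L)
  expect_equal(rt$ubiquitous_biased$drug_id, c("dA", "dB"))

  one <- rank_by_bias(summ[1, ], top_n = 10L)
  expect_equal(one$ubiquitous_biased$drug_id, "d1")
  expect_equal(one$nonubiquitous_biased$drug_id, "d1")
})

test_that("group summaries average member-drug proportions", {
  summ <- data.frame(drug_id = c("d1", "d2", "d3"),
                     moa = c("m1", "m1", NA),
                     prop_ubiq = c(0.2, 0.4, 0.9),
                     prop_nonubiq = c(0.1, 0.1, 0.9),
                     mean_abs_lfc = c(1, 3, 5),
                     stringsAsFactors = FALSE)
  g <- group_summaries(summ, c(d1 = "m1", d2 = "m1"))
  expect_equal(g$prop_ubiq, 0.3)
  expect_equal(g$prop_nonubiq, 0.1)
  expect_equal(g$mean_abs_lfc, 2)
  expect_equal(attr(g, "n_unlabeled"), 1L)

  single <- group_summaries(summ, c(d1 = "solo"))
  expect_equal(single$prop_ubiq, summ$prop_ubiq[1])
  expect_error(group_summaries(summ, character()), "empty group map")
})

test_that("three-drug group means match the hand computation", {
  summ <- data.frame(drug_id = c("d1", "d2", "d3"),
                     prop_ubiq = c(0.1, 0.2, 0.6),
                     prop_nonubiq = c(0.3, 0.3, 0.0),
                     mean_abs_lfc = c(1, 2, 6),
                     stringsAsFactors = FALSE)
  g <- group_summaries(summ, c(d1 = "G", d2 = "G", d3 = "G"))
  expect_equal(g$prop_ubiq, 0.3)
  expect_equal(g$prop_nonubiq, 0.2)
  expect_equal(g$bias_ratio, 0.2 / 0.3)
  expect_equal(g$mean_abs_lfc, 3)
})

test_that("weighted mean score weights by the strongest |logFC| per gene", {
  scores <- fake_scores(c("gHi", "gLo"), c(0.9, 0.1))
  pairs <- drug_fix(list(list("gHi", "d1", 0.01, 3), list("gLo", "d1", 0.01, -1)))
  expect_equal(weighted_mean_score(pairs, scores), 0.7)

  equal_w <- drug_fix(list(list("gHi", "d1", 0.01, 2), list("gLo", "d1", 0.01, -2)))
  expect_equal(weighted_mean_score(equal_w, scores), 0.5)

  one <- drug_fix(list(list("gHi", "d1", 0.01, 42)))
  expect_equal(weighted_mean_score(one, scores), 0.9)

  multi <- drug_fix(list(list("gHi", "d1", 0.01, 1, "1uM"),
                         list("gHi", "d1", 0.02, 3, "10uM"),
                         list("gLo", "d1", 0.01, 1, "1uM")))
  expect_equal(weighted_mean_score(multi, scores), 0.7)       # max collapse
  expect_equal(weighted_mean_score(multi, scores, "mean"), (2 * 0.9 + 0.1) / 3)

  zero <- drug_fix(list(list("gHi", "d1", 0.01, 0), list("gLo", "d1", 0.01, 0)))
  expect_warning(wm <- weighted_mean_score(zero, scores), "zero")
  expect_equal(wm, 0.5)
})

test_that("sector effect sizes average |logFC| and report empty sectors as missing", {
  sec <- structure(data.frame(gene_id = c("g1", "g2", "g3"),
                              sector = c("10", "10", "00"),
                              stringsAsFactors = FALSE),
                   class = c("ubiq_sectors", "data.frame"))
  pairs <- drug_fix(list(list("g1", "d1", 0.01, 1), list("g2", "d1", 0.01, -3)))
  out <- sector_effect_sizes(pairs, sec)
  expect_equal(out$mean_abs_lfc[out$sector == "10"], 2)
  expect_true(is.na(out$mean_abs_lfc[out$sector == "00"]))
  expect_equal(out$n_records[out$sector == "00"], 0L)

  grouped <- sector_effect_sizes(pairs, sec, grouping = c(d1 = "L"))
  expect_equal(grouped$mean_abs_lfc[grouped$sector == "10" &
                                      grouped$group == "L"], 2)
})

test_that("filtering before or after per-drug summarizing commutes", {
  sim <- simulate_expression(synthetic_spec(n_samples = 10, n_ubiquitous = 20,
    n_specific = 40, n_variable = 10, n_silent = 5, seed = 8))
  ds <- simulate_drug_stats(sim$labels, n_broad_drugs = 2,
                            n_specific_drugs = 3, seed = 8)
  universe <- names(sim$labels)
  ubiq <- names(sim$labels)[sim$labels == "ubiquitous"]
  direct <- affected_proportions(significant_pairs(ds$stats), ubiq, universe)
  # aggregate per drug first, then drop the non-significant records
  per_drug <- lapply(split(seq_len(nrow(ds$stats)), ds$stats$drug_id),
                     function(ix) significant_pairs(ds$stats[ix, ]))
  refiltered <- affected_proportions(do.call(rbind, per_drug), ubiq, universe)
  expect_equal(direct, refiltered, ignore_attr = TRUE)
})
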