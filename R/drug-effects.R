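#' Filter drug statistics to significant (gene, drug) pairs
#'
#' Keeps records whose t-test p-value is at or below `alpha` (boundary
#' inclusive: a drug significantly influences a gene at P <= alpha).
#'
#' @param stats A `ubiq_drug_stats` table.
#' @param alpha Significance threshold in (0, 1); default 0.05. No
#'   multiple-testing correction is applied at this stage.
#' @return The filtered `ubiq_drug_stats` table.
#' @export
significant_pairs <- function(stats, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  out <- stats[stats$p_value <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-drug affected proportions and ubiquity bias
#'
#' For every drug, compares the proportion of ubiquitous genes it
#' significantly influences with the proportion of non-ubiquitous genes. The
#' universe is the set of genes shared by the scoring dataset and the drug
#' dataset; a gene counts as affected by a drug if ANY of its concentration
#' records for that drug is significant. The bias ratio is
#' `prop_nonubiq / prop_ubiq` (`Inf` when only non-ubiquitous genes are
#' affected; `NA` and flagged omitted when the drug affects no gene): values
#' below 1 mean the drug is biased toward ubiquitous genes.
#'
#' @param pairs Significant (gene, drug) records (see [significant_pairs()]).
#' @param ubiq Character vector: the ubiquitous gene set (subset of
#'   `universe`).
#' @param universe Character vector: all genes eligible for counting.
#' @param drugs Drug IDs to report; defaults to the drugs present in
#'   `pairs`. A listed drug without significant records gets zero
#'   proportions and an omitted (NA) bias ratio.
#' @return A `ubiq_drug_summary` data.frame, one row per drug: `drug_id`,
#'   `moa`, `atc`, `n_affected_ubiq`, `n_affected_nonubiq`, `prop_ubiq`,
#'   `prop_nonubiq`, `bias_ratio`, `mean_abs_lfc`.
#' @export
affected_proportions <- function(pairs, ubiq, universe,
                                 drugs = sort(unique(pairs$drug_id))) {
  ubiq <- unique(as.character(ubiq))
  universe <- unique(as.character(universe))
  if (!all(ubiq %in% universe))
    stop("`ubiq` must be a subset of `universe`", call. = FALSE)
  nonubiq <- setdiff(universe, ubiq)
  if (!length(ubiq) || !length(nonubiq))
    stop("both the ubiquitous set and its complement must be non-empty",
         call. = FALSE)
  pairs <- pairs[pairs$gene_id %in% universe, , drop = FALSE]
  rows <- lapply(drugs, function(d) {
    sub <- pairs[pairs$drug_id == d, , drop = FALSE]
    affected <- unique(sub$gene_id)
    n_u <- sum(affected %in% ubiq)
    n_n <- length(affected) - n_u
    p_u <- n_u / length(ubiq)
    p_n <- n_n / length(nonubiq)
    ratio <- if (n_u == 0 && n_n == 0) NA_real_
             else if (p_u == 0) Inf else p_n / p_u
    data.frame(drug_id = d,
               moa = first_label(sub$moa), atc = first_label(sub$atc),
               n_affected_ubiq = n_u, n_affected_nonubiq = n_n,
               prop_ubiq = p_u, prop_nonubiq = p_n, bias_ratio = ratio,
               mean_abs_lfc = if (nrow(sub)) mean(abs(sub$log_fc)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("ubiq_drug_summary", "data.frame"),
            n_ubiq = length(ubiq), n_nonubiq = length(nonubiq))
}

first_label <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x)) x[1L] else NA_character_
}

#' Rank drugs by ubiquity bias
#'
#' Returns the drugs most biased toward ubiquitous genes (smallest
#' non-ubiquitous:ubiquitous ratio) and most biased toward non-ubiquitous
#' genes (largest ratio; infinite ratios sort above any finite one). Drugs
#' with an omitted (NA) ratio are excluded; ties are broken by drug ID.
#'
#' @param summaries A `ubiq_drug_summary` table (see
#'   [affected_proportions()] or [group_summaries()]).
#' @param top_n Number of entries per list.
#' @return List with `ubiquitous_biased` and `nonubiquitous_biased`
#'   data.frames.
#' @export
rank_by_bias <- function(summaries, top_n = 10L) {
  s <- summaries[!is.na(summaries$bias_ratio), , drop = FALSE]
  id_col <- if ("drug_id" %in% names(s)) "drug_id" else "group"
  asc <- s[order(s$bias_ratio, s[[id_col]]), , drop = FALSE]
  desc <- s[order(-s$bias_ratio, s[[id_col]]), , drop = FALSE]
  list(ubiquitous_biased = utils::head(asc, top_n),
       nonubiquitous_biased = utils::head(desc, top_n))
}

#' Aggregate drug summaries into groups
#'
#' Aggregates per-drug summaries by a flat label (mechanism of action, ATC
#' class, ...). Group proportions are the unweighted mean of the member
#' drugs' proportions (pooled counting across member drugs is available as
#' `method = "pooled"`), and the group effect size is the mean of the member
#' drugs' mean absolute log fold changes. Unlabeled drugs are skipped and
#' counted.
#'
#' @param summaries A `ubiq_drug_summary` table.
#' @param grouping Named character vector drug ID -> label; defaults to the
#'   `moa` column of the summaries.
#' @param method `"mean"` (average member-drug proportions, default) or
#'   `"pooled"` (treat a gene as affected by the group if affected by any
#'   member; requires `pairs`, `ubiq`, `universe`).
#' @param pairs,ubiq,universe Only for `method = "pooled"`: the inputs of
#'   [affected_proportions()].
#' @return A `ubiq_drug_summary`-like data.frame, one row per group, with
#'   `group`, `n_drugs`, proportions, `bias_ratio`, `mean_abs_lfc`;
#'   attribute `n_unlabeled` counts skipped drugs.
#' @export
group_summaries <- function(summaries, grouping = NULL,
                            method = c("mean", "pooled"),
                            pairs = NULL, ubiq = NULL, universe = NULL) {
  method <- match.arg(method)
  if (is.null(grouping)) {
    grouping <- stats::setNames(summaries$moa, summaries$drug_id)
    grouping <- grouping[!is.na(grouping)]
  }
  if (!length(grouping)) stop("empty group map", call. = FALSE)
  lab <- grouping[summaries$drug_id]
  n_unlabeled <- sum(is.na(lab))
  keep <- !is.na(lab)
  s <- summaries[keep, , drop = FALSE]
  lab <- lab[keep]
  groups <- sort(unique(lab))
  rows <- lapply(groups, function(g) {
    member <- s[lab == g, , drop = FALSE]
    if (method == "mean") {
      p_u <- mean(member$prop_ubiq)
      p_n <- mean(member$prop_nonubiq)
    } else {
      if (is.null(pairs) || is.null(ubiq) || is.null(universe))
        stop("pooled grouping needs `pairs`, `ubiq` and `universe`",
             call. = FALSE)
      sub <- pairs[pairs$drug_id %in% member$drug_id &
                     pairs$gene_id %in% universe, , drop = FALSE]
      affected <- unique(sub$gene_id)
      p_u <- sum(affected %in% ubiq) / length(unique(ubiq))
      p_n <- sum(!affected %in% ubiq) / length(setdiff(universe, ubiq))
    }
    ratio <- if (p_u == 0 && p_n == 0) NA_real_
             else if (p_u == 0) Inf else p_n / p_u
    data.frame(group = g, n_drugs = nrow(member),
               prop_ubiq = p_u, prop_nonubiq = p_n, bias_ratio = ratio,
               mean_abs_lfc = mean(member$mean_abs_lfc),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("ubiq_drug_summary", "data.frame"),
            n_unlabeled = n_unlabeled, method = method)
}

#' Log-fold-change-weighted mean score of drug-affected genes
#'
#' Summarizes where a drug's significantly affected genes sit in a ubiquity
#' ranking, weighting each affected gene's composite score by its absolute
#' log fold change (per gene, the maximum |logFC| across the drug's
#' significant records; `lfc_summary = "mean"` averages instead).
#' Up- and down-regulation are not distinguished.
#'
#' @param pairs Significant records for ONE drug.
#' @param scores A `ubiq_scores` table.
#' @param lfc_summary How to collapse multiple records per gene: `"max"`
#'   (default) or `"mean"` of |logFC|.
#' @return Weighted mean score (numeric scalar).
#' @export
weighted_mean_score <- function(pairs, scores, lfc_summary = c("max", "mean")) {
  lfc_summary <- match.arg(lfc_summary)
  if (length(unique(pairs$drug_id)) > 1L)
    stop("`pairs` must contain records of a single drug", call. = FALSE)
  idx <- match(pairs$gene_id, scores$gene_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no affected gene has a score", call. = FALSE)
  pairs <- pairs[keep, , drop = FALSE]
  fun <- if (lfc_summary == "max") max else mean
  w <- tapply(abs(pairs$log_fc), pairs$gene_id, fun)
  sc <- scores$score[match(names(w), scores$gene_id)]
  if (all(w == 0)) {
    warning("all |logFC| are zero; returning unweighted mean score",
            call. = FALSE)
    return(mean(sc))
  }
  sum(w * sc) / sum(w)
}

#' Mean effect sizes per sector
#'
#' Mean absolute log fold change over all significant (gene, drug) records,
#' grouped by the gene's sector of a two-dataset classification and
#' optionally by a drug label (e.g. ATC class). Sectors with no record are
#' reported as missing (`NA`), not zero.
#'
#' @param pairs Significant records (see [significant_pairs()]).
#' @param sectors A `ubiq_sectors` assignment.
#' @param grouping Optional named character vector drug ID -> label.
#' @return data.frame with `sector`, optionally `group`, `n_records`,
#'   `mean_abs_lfc` (NA for empty sector cells).
#' @export
sector_effect_sizes <- function(pairs, sectors, grouping = NULL) {
  sec <- sectors$sector[match(pairs$gene_id, sectors$gene_id)]
  keep <- !is.na(sec)
  pairs <- pairs[keep, , drop = FALSE]
  sec <- sec[keep]
  lv <- c("00", "01", "10", "11")
  if (is.null(grouping)) {
    cells <- expand.grid(sector = lv, stringsAsFactors = FALSE)
    key <- factor(sec, lv)
    mean_lfc <- tapply(abs(pairs$log_fc), key, mean)
    n_rec <- tapply(rep(1L, length(sec)), key, sum)
    cells$n_records <- ifelse(is.na(n_rec[cells$sector]), 0L,
                              n_rec[cells$sector])
    cells$mean_abs_lfc <- as.numeric(mean_lfc[cells$sector])
  } else {
    grp <- grouping[pairs$drug_id]
    keep2 <- !is.na(grp)
    pairs <- pairs[keep2, , drop = FALSE]
    sec <- sec[keep2]; grp <- grp[keep2]
    labels <- sort(unique(grp))
    cells <- expand.grid(sector = lv, group = labels,
                         stringsAsFactors = FALSE)
    key <- paste(sec, grp)
    mean_lfc <- tapply(abs(pairs$log_fc), key, mean)
    n_rec <- table(key)
    ck <- paste(cells$sector, cells$group)
    cells$n_records <- ifelse(ck %in% names(n_rec), as.integer(n_rec[ck]), 0L)
    cells$mean_abs_lfc <- as.numeric(mean_lfc[ck])
  }
  cells
}
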