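#' Ubiquitous gene set from a ranking
#'
#' The ubiquity cutoff is count-based: exactly `k = floor(top_fraction * N)`
#' genes — the k best under the deterministic rank order (score descending,
#' gene ID ascending) — are called ubiquitous. `k = 0` is allowed.
#'
#' @param scores A `ubiq_scores` table.
#' @param top_fraction Fraction of genes considered ubiquitous, in (0, 1\];
#'   default 0.05.
#' @return Character vector of gene IDs.
#' @export
ubiquitous_set <- function(scores, top_fraction = 0.05) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must be in (0, 1]", call. = FALSE)
  k <- floor(top_fraction * nrow(scores))
  scores$gene_id[order(scores$rank)][seq_len(k)]
}

#' Cross-dataset sector classification
#'
#' Classifies the genes shared by two rankings into four sectors by joint
#' ubiquity: `"11"` ubiquitous in both, `"10"` only in A, `"01"` only in B,
#' `"00"` in neither. Each dataset's ubiquitous set is computed on its FULL
#' gene list first; membership is then evaluated on the shared genes, so a
#' dataset's ubiquitous genes missing from the other dataset are simply
#' absent from the assignment.
#'
#' @param a,b `ubiq_scores` tables for the two datasets.
#' @param top_fraction Cutoff fraction passed to [ubiquitous_set()].
#' @return A `ubiq_sectors` data.frame with one row per shared gene:
#'   `gene_id`, `sector`, `score_a`, `percentile_a`, `score_b`,
#'   `percentile_b`; attribute `sector_counts`.
#' @export
classify_sectors <- function(a, b, top_fraction = 0.05) {
  shared <- intersect(a$gene_id, b$gene_id)
  if (!length(shared))
    stop("the two score tables share no genes", call. = FALSE)
  ub_a <- ubiquitous_set(a, top_fraction)
  ub_b <- ubiquitous_set(b, top_fraction)
  ia <- match(shared, a$gene_id)
  ib <- match(shared, b$gene_id)
  in_a <- shared %in% ub_a
  in_b <- shared %in% ub_b
  out <- data.frame(
    gene_id = shared,
    sector = paste0(as.integer(in_a), as.integer(in_b)),
    score_a = a$score[ia], percentile_a = a$percentile[ia],
    score_b = b$score[ib], percentile_b = b$percentile[ib],
    stringsAsFactors = FALSE
  )
  counts <- table(factor(out$sector, levels = c("00", "01", "10", "11")))
  structure(out, class = c("ubiq_sectors", "data.frame"),
            sector_counts = counts, top_fraction = top_fraction)
}

#' @export
print.ubiq_sectors <- function(x, ...) {
  counts <- attr(x, "sector_counts")
  cat(sprintf("Sector assignment over %d shared genes (top fraction %.2f):\n",
              nrow(x), attr(x, "top_fraction")))
  pct <- 100 * counts / sum(counts)
  for (s in names(counts))
    cat(sprintf("  sector %s: %6d (%5.2f%%)\n", s, counts[[s]], pct[[s]]))
  invisible(x)
}

#' Spearman correlation of two rankings
#'
#' Spearman's rank correlation of the composite scores over the genes shared
#' by two tables (average ranks for ties).
#'
#' @param a,b `ubiq_scores` tables.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_scores <- function(a, b) {
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < 3L)
    stop("need at least 3 shared genes for a rank correlation", call. = FALSE)
  stats::cor(a$score[match(shared, a$gene_id)],
             b$score[match(shared, b$gene_id)], method = "spearman")
}

#' Sector profile of a gene list
#'
#' Where do the genes of a list fall among the sectors of a two-dataset
#' classification? Reports per-sector counts, the fractions of the covered
#' list per sector, and the over-representation ratio (fraction of the list
#' in a sector divided by the fraction of all shared genes in that sector).
#' List genes absent from the shared-gene universe are reported as
#' `uncovered`.
#'
#' @param list A `ubiq_gene_list` (or character vector of gene IDs).
#' @param sectors A `ubiq_sectors` assignment.
#' @return data.frame with one row per sector (`sector`, `n`, `fraction`,
#'   `overall_fraction`, `ratio`); attributes `n_covered`, `n_uncovered`.
#' @export
list_sector_profile <- function(list, sectors) {
  ids <- if (inherits(list, "ubiq_gene_list")) list$gene_ids
         else unique(as.character(list))
  covered <- ids[ids %in% sectors$gene_id]
  if (!length(covered))
    stop("gene list has no genes among the shared genes of the assignment",
         call. = FALSE)
  lv <- c("00", "01", "10", "11")
  in_list <- table(factor(sectors$sector[match(covered, sectors$gene_id)], lv))
  overall <- table(factor(sectors$sector, lv))
  out <- data.frame(
    sector = lv,
    n = as.integer(in_list),
    fraction = as.numeric(in_list) / length(covered),
    overall_fraction = as.numeric(overall) / nrow(sectors),
    stringsAsFactors = FALSE
  )
  out$ratio <- ifelse(out$overall_fraction > 0,
                      out$fraction / out$overall_fraction, NA_real_)
  structure(out, n_covered = length(covered),
            n_uncovered = length(ids) - length(covered))
}

#' Per-gene report across datasets
#'
#' Looks up score, rank and percentile of query genes in any number of named
#' score tables (the per-gene view used to vet candidate reference genes).
#' Genes absent from a dataset are reported as missing (`NA`), never as zero.
#' When a sector assignment is supplied, the gene's sector is added.
#'
#' @param gene_ids Character vector of query genes.
#' @param tables Named list of `ubiq_scores` tables.
#' @param sectors Optional `ubiq_sectors` assignment for a designated pair.
#' @return data.frame with one row per (gene, dataset): `gene_id`, `dataset`,
#'   `score`, `rank`, `percentile` and optionally `sector`.
#' @export
gene_report <- function(gene_ids, tables, sectors = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("`tables` must be a named list of score tables", call. = FALSE)
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    idx <- match(gene_ids, tab$gene_id)
    data.frame(gene_id = gene_ids, dataset = nm,
               score = tab$score[idx], rank = tab$rank[idx],
               percentile = tab$percentile[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(sectors))
    out$sector <- sectors$sector[match(out$gene_id, sectors$gene_id)]
  out[order(match(out$gene_id, gene_ids)), , drop = FALSE]
}

#' Intersection pattern counts of multiple gene lists
#'
#' Counts every non-empty membership pattern across two or more gene lists
#' (the machinery behind Venn/upset summaries). A pattern is a string of 0/1
#' flags in list order, e.g. `"101"` for genes in lists 1 and 3 only.
#'
#' @param lists List of `ubiq_gene_list` objects (or character vectors).
#' @return data.frame with columns `pattern` and `n`; counts sum to the size
#'   of the union.
#' @export
multi_list_intersections <- function(lists) {
  if (length(lists) < 2L)
    stop("need at least 2 gene lists", call. = FALSE)
  sets <- lapply(lists, function(l)
    if (inherits(l, "ubiq_gene_list")) l$gene_ids else unique(as.character(l)))
  universe <- unique(unlist(sets))
  flags <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
  pattern <- apply(flags, 1L, function(f) paste(as.integer(f), collapse = ""))
  tab <- table(pattern)
  data.frame(pattern = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
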