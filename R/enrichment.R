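#' Partition a ranking into consecutive buckets
#'
#' Splits a ranking into rank-order slices of `b = ceiling(fraction * N)`
#' genes each; every bucket except possibly the last has exactly `b` genes,
#' and the last (lowest-ranking) bucket may be smaller. The concatenation of
#' the buckets is the full ranking.
#'
#' @param ranking A `ubiq_scores` table (or character vector already in rank
#'   order).
#' @param fraction Bucket size as a fraction of the ranking, in (0, 1\];
#'   default 0.025.
#' @return A `ubiq_buckets`: list of character vectors of gene IDs;
#'   attributes `bucket_size` and `fraction`.
#' @export
bucketize <- function(ranking, fraction = 0.025) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  ids <- if (is.character(ranking)) ranking
         else ranking$gene_id[order(ranking$rank)]
  n <- length(ids)
  b <- ceiling(fraction * n)
  idx <- ceiling(seq_len(n) / b)
  buckets <- split(ids, idx)
  names(buckets) <- NULL
  structure(buckets, class = "ubiq_buckets", bucket_size = b,
            fraction = fraction)
}

#' One-sided hypergeometric over-representation test
#'
#' Tail probability P\[X >= k\] that a uniform draw of `|query|` genes from
#' the background contains at least the observed overlap `k` with the term,
#' where the term is first intersected with the background. The query must
#' be a subset of the background.
#'
#' @param query Character vector of query genes (subset of `background`).
#' @param term Character vector of term member genes.
#' @param background Character vector: the gene universe.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_test <- function(query, term, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- unique(as.character(query))
  if (!all(query %in% background))
    stop("`query` must be a subset of `background`", call. = FALSE)
  term_bg <- intersect(unique(as.character(term)), background)
  k <- length(intersect(query, term_bg))
  # P[X >= k], X ~ Hypergeometric(|bg|, |term in bg|, |query|)
  stats::phyper(k - 1L, length(term_bg), length(background) - length(term_bg),
                length(query), lower.tail = FALSE)
}

#' Over-representation analysis of one gene set
#'
#' Tests every term of a collection against a query set with the
#' hypergeometric tail, adjusts p-values with Benjamini-Hochberg across all
#' tested terms jointly, and counts significant terms per annotation source.
#' Terms disjoint from the background are skipped (reported); query genes
#' outside the background are dropped with a warning. Also reports the
#' number of highly significant terms with `-log10(p_adj) >= 16`.
#'
#' @param query Character vector of query genes.
#' @param collection A `ubiq_collection` (see [read_collection()]).
#' @param background Character vector: the gene universe.
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @return List with `terms` (data.frame: `term_id`, `source`, `overlap`,
#'   `term_size`, `p_value`, `p_adjusted`, `significant`), `n_significant`
#'   per source, `n_highly_significant`, `n_skipped_terms`.
#' @export
enrich_set <- function(query, collection, background, alpha = 0.05) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, background)
  }
  pruned <- lapply(collection, function(t) intersect(t$genes, background))
  keep <- lengths(pruned) > 0L
  n_skipped <- sum(!keep)
  terms <- collection[keep]
  pruned <- pruned[keep]
  if (!length(terms)) {
    return(list(terms = data.frame(term_id = character(), source = character(),
                                   overlap = integer(), term_size = integer(),
                                   p_value = numeric(), p_adjusted = numeric(),
                                   significant = logical()),
                n_significant = integer(0), n_highly_significant = 0L,
                n_skipped_terms = n_skipped))
  }
  overlap <- vapply(pruned, function(g) length(intersect(query, g)), integer(1L))
  term_size <- lengths(pruned)
  p <- stats::phyper(overlap - 1L, term_size,
                     length(background) - term_size, length(query),
                     lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  df <- data.frame(
    term_id = vapply(terms, `[[`, character(1L), "term_id"),
    source = vapply(terms, `[[`, character(1L), "source"),
    overlap = overlap, term_size = term_size,
    p_value = p, p_adjusted = p_adj,
    significant = p_adj <= alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_sig <- tapply(df$significant, df$source, sum)
  list(terms = df,
       n_significant = stats::setNames(as.integer(n_sig), names(n_sig)),
       n_highly_significant = sum(-log10(df$p_adjusted) >= 16),
       n_skipped_terms = n_skipped)
}

#' Sliding over-representation analysis along a ranking
#'
#' Divides a ranking into consecutive buckets (default 2.5% of the genes
#' each) and runs an independent over-representation analysis per bucket.
#' The background is the intersection of the ranked genes with the genes
#' annotated in any term of the collection, shared across all buckets.
#' Returns the number of significant terms per bucket and annotation source
#' — in an informative ranking the counts fall off from the top buckets to
#' the bottom ones.
#'
#' @param ranking A `ubiq_scores` table.
#' @param collection A `ubiq_collection`.
#' @param fraction Bucket fraction (default 0.025).
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @return List with `counts` (matrix bucket x source), `bucket_size`, and
#'   `background_size`.
#' @export
sliding_enrichment <- function(ranking, collection, fraction = 0.025,
                               alpha = 0.05) {
  annotated <- unique(unlist(lapply(collection, `[[`, "genes")))
  ids <- ranking$gene_id[order(ranking$rank)]
  background <- intersect(ids, annotated)
  buckets <- bucketize(ranking, fraction)
  sources <- sort(unique(vapply(collection, `[[`, character(1L), "source")))
  counts <- matrix(0L, nrow = length(buckets), ncol = length(sources),
                   dimnames = list(sprintf("bucket_%02d", seq_along(buckets)),
                                   sources))
  if (length(background) && length(collection)) {
    for (i in seq_along(buckets)) {
      q <- intersect(buckets[[i]], background)
      if (!length(q)) next
      res <- enrich_set(q, collection, background, alpha)
      if (nrow(res$terms))
        counts[i, names(res$n_significant)] <- res$n_significant
    }
  }
  list(counts = counts, bucket_size = attr(buckets, "bucket_size"),
       background_size = length(background))
}
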