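#' Reads-per-kilobase transformation
#'
#' First step of GeTMM: divide each gene's raw count by its transcript length
#' in kilobases. Counts must be raw non-negative integers (pre-normalized
#' input is rejected); genes without a length entry are dropped with a
#' warning.
#'
#' @param counts Expression matrix of raw read counts.
#' @param lengths Named numeric vector gene ID -> length in bp (see
#'   [read_gene_lengths()]).
#' @return Expression matrix of RPK values; `meta$dropped_no_length` records
#'   the number of genes dropped.
#' @export
counts_to_rpk <- function(counts, lengths) {
  counts <- validate_expression_matrix(counts)
  if (any(counts != round(counts)))
    stop("counts_to_rpk expects raw integer counts; non-integer values found",
         call. = FALSE)
  covered <- rownames(counts) %in% names(lengths)
  n_drop <- sum(!covered)
  if (n_drop == nrow(counts))
    stop("no gene in the count matrix has a length entry", call. = FALSE)
  if (n_drop > 0)
    warning(sprintf("%d gene(s) without length entry dropped", n_drop),
            call. = FALSE)
  m <- counts[covered, , drop = FALSE]
  len_kb <- lengths[rownames(m)] / 1000
  if (any(len_kb <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  rpk <- m / len_kb
  meta <- c(attr(counts, "meta"), list(unit = "RPK",
                                       dropped_no_length = n_drop))
  expression_matrix(unclass_matrix(rpk), meta = meta)
}

unclass_matrix <- function(m) {
  attr(m, "meta") <- NULL
  class(m) <- "matrix"
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Per-sample scaling factors by the weighted trimmed mean of M-values
#' against a reference sample. M and A values are computed from the raw
#' per-gene values of the two samples; genes with a zero in either sample are
#' excluded. The default trims 30% of the most extreme M-values and 5% of the
#' most extreme A-values on each side; genes are precision-weighted by the
#' delta-method (binomial) approximation. The reference sample is the one
#' whose upper quartile of positive values is closest to the mean upper
#' quartile across samples. Factors are rescaled so their geometric mean is
#' exactly 1; a factor therefore absorbs both sequencing depth and
#' compositional differences relative to the other samples.
#'
#' @param rpk Expression matrix (typically RPK values).
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(rpk, trim_m = 0.30, trim_a = 0.05) {
  rpk <- validate_expression_matrix(rpk, require_samples = 2L)
  lib <- colSums(rpk)
  zero_lib <- lib <= 0
  if (any(zero_lib))
    stop(sprintf("sample(s) with all-zero values: %s",
                 paste(colnames(rpk)[zero_lib], collapse = ", ")), call. = FALSE)
  uq <- apply(rpk, 2L, function(x) stats::quantile(x[x > 0], 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  log_f <- vapply(seq_len(ncol(rpk)), function(s) {
    if (s == ref) return(0)
    pair_tmm_log2(rpk[, s], rpk[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, numeric(1L))
  f <- 2 ^ log_f
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(rpk))
}

# log2 scaling of sample `obs` relative to `ref`, by the weighted trimmed
# mean of M = log2(obs/ref) over genes positive in both samples. Precision
# weights use the delta-method binomial variance of the library-scaled
# proportions. Trimming follows the rank-window convention:
# keep ranks in [floor(n*trim)+1, n - floor(n*trim)].
pair_tmm_log2 <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  depth <- log2(n_obs) - log2(n_ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(depth)
  # M/A on library-scaled proportions; the depth ratio is added back at the
  # end so the returned factor absorbs sequencing depth. Computing M this way
  # keeps floating-point ties identical to the composition-only formulation.
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  # degenerate: identical composition (all M equal up to noise)
  if (max(abs(m - m[1L])) < 1e-10) return(m[1L] + depth)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m)   # average ranks on ties, keeping tied genes symmetric
  ra_ <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(sel)) sel <- rep(TRUE, n)
  wm <- sum(m[sel] / w[sel]) / sum(1 / w[sel])
  if (!is.finite(wm)) wm <- mean(m[sel])
  wm + depth
}

#' GeTMM normalization
#'
#' Gene-length-corrected TMM normalization of raw read counts, supporting
#' both intra- and inter-sample comparison: counts are converted to RPK,
#' per-sample scaling factors are estimated by TMM on the RPK values, and
#' each sample is scaled to a common per-million effective library size
#' (geometric-mean RPK library size times the sample's factor). For samples
#' of identical composition and depth every column sums to exactly 1e6, and
#' the output is invariant under a global rescaling of all counts.
#'
#' @inheritParams counts_to_rpk
#' @inheritParams tmm_factors
#' @return Expression matrix of normalized values; `meta$normalization` is
#'   set to `"GeTMM"`.
#' @export
getmm_normalize <- function(counts, lengths, trim_m = 0.30, trim_a = 0.05) {
  rpk <- counts_to_rpk(counts, lengths)
  f <- tmm_factors(rpk, trim_m = trim_m, trim_a = trim_a)
  lib <- colSums(rpk)
  eff <- exp(mean(log(lib))) * f  # effective library size per sample
  out <- sweep(unclass_matrix(rpk), 2L, eff, `/`) * 1e6
  meta <- c(attr(rpk, "meta"), list(normalization = "GeTMM"))
  meta$unit <- "GeTMM per-million"
  expression_matrix(out, meta = meta)
}
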