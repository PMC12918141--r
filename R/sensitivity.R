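#' Full factorial weight grid
#'
#' Varies each default weight by a relative amount (default +/-20%) and
#' builds the full Cartesian product of equally spaced per-axis values. With
#' the defaults (+0.50, +0.25, -0.25), 20% relative range and 11 points per
#' axis, the grid holds 11^3 = 1331 triples spanning
#' \[0.40, 0.60\] x \[0.20, 0.30\] x \[-0.30, -0.20\].
#'
#' @param defaults Numeric vector of the three default weights
#'   (breadth, level, variation).
#' @param rel_range Relative half-range per axis (>= 0).
#' @param points_per_axis Number of equally spaced points per axis, endpoints
#'   inclusive (>= 1; 1 yields the single default triple).
#' @return A `ubiq_weight_grid`: data.frame with columns `w_breadth`,
#'   `w_level`, `w_variation` in lexicographic order; attributes record the
#'   per-axis ranges and points per axis.
#' @export
weight_grid <- function(defaults = default_weights(), rel_range = 0.20,
                        points_per_axis = 11L) {
  if (points_per_axis < 1L) stop("`points_per_axis` must be >= 1", call. = FALSE)
  if (rel_range < 0) stop("`rel_range` must be >= 0", call. = FALSE)
  defaults <- validate_weights(defaults)
  axis <- function(d) {
    if (points_per_axis == 1L) return(d)
    sort(seq(d * (1 - rel_range), d * (1 + rel_range),
             length.out = points_per_axis))
  }
  axes <- lapply(defaults, axis)
  # lexicographic order over (breadth, level, variation): last axis fastest
  g <- expand.grid(w_variation = axes[[3L]], w_level = axes[[2L]],
                   w_breadth = axes[[1L]], KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("w_breadth", "w_level", "w_variation")]
  rownames(g) <- NULL
  structure(g, class = c("ubiq_weight_grid", "data.frame"),
            ranges = lapply(axes, range), points_per_axis = points_per_axis,
            defaults = defaults)
}

#' Top-set overlap across a weight grid
#'
#' Measures how stable the ubiquitous set is under weight perturbation.
#' Subscores are computed once (they do not depend on the weights); the
#' composite is recomputed for every weight triple of the grid, and the
#' overlap is the size of the intersection of all resulting top-k sets
#' divided by k, with `k = floor(top_fraction * N)`. When `restrict_to` is
#' given (e.g. the sector-11 genes of a cross-dataset comparison), every top
#' set and the denominator are first intersected with that set; the
#' denominator is the baseline top set (default weights in `config`)
#' intersected with `restrict_to`.
#'
#' @param m Expression matrix.
#' @param config [scoring_config()] providing the criteria and baseline
#'   weights.
#' @param grid A [weight_grid()].
#' @param top_fraction Cutoff fraction (default 0.05).
#' @param restrict_to Optional character vector of gene IDs.
#' @return List with `overlap` (fraction in \[0, 1\]), `k`, `n_grid`, and
#'   `stable_genes` (the intersection set).
#' @export
top_set_overlap <- function(m, config = scoring_config(), grid = weight_grid(),
                            top_fraction = 0.05, restrict_to = NULL) {
  if (!nrow(grid)) stop("weight grid is empty", call. = FALSE)
  m <- validate_expression_matrix(m, require_samples = 2L)
  sub <- compute_subscores(m, config)
  k <- floor(top_fraction * nrow(sub))
  top_for <- function(w) {
    raw <- w[1L] * sub$breadth + w[2L] * sub$level + w[3L] * sub$variation
    # min-max on the composite preserves order; top-k by raw value directly
    ord <- order(-raw, sub$gene_id)
    sub$gene_id[ord][seq_len(k)]
  }
  base_top <- top_for(config$weights)
  tops <- lapply(seq_len(nrow(grid)), function(i) top_for(as.numeric(grid[i, ])))
  common <- Reduce(intersect, tops)
  if (is.null(restrict_to)) {
    denom <- k
    stable <- common
  } else {
    base_r <- intersect(base_top, restrict_to)
    if (!length(base_r))
      stop("`restrict_to` is disjoint from the baseline top set", call. = FALSE)
    stable <- intersect(common, restrict_to)
    denom <- length(base_r)
  }
  list(overlap = length(stable) / denom, k = k, n_grid = nrow(grid),
       stable_genes = stable)
}
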