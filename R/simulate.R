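#' Specification for synthetic expression data
#'
#' Defines a gene-by-sample generator with four planted gene classes chosen
#' to span the behaviours the ubiquity score discriminates:
#' \describe{
#'   \item{ubiquitous}{detected in every sample, high log-normal level,
#'     small spread — the class the score should rank on top.}
#'   \item{specific}{expressed in only a small fraction of samples (default
#'     10%), at a substantial level when expressed — tissue-restricted
#'     genes.}
#'   \item{variable}{detected broadly but with a large log-scale spread —
#'     noisy, condition-dependent genes.}
#'   \item{silent}{near-zero expression with heavy dropout.}
#' }
#' Values are log-normal where detected and exactly zero elsewhere; all
#' randomness is governed by the integer `seed`.
#'
#' @param n_samples Number of samples (default 100).
#' @param n_ubiquitous,n_specific,n_variable,n_silent Class sizes
#'   (defaults 200/600/150/50).
#' @param seed Integer seed (default 1).
#' @param params Per-class generative parameters; override entries of the
#'   default list (each class: `detection`, `meanlog`, `sdlog`; `specific`
#'   uses `detection` as the expressed-sample fraction).
#' @return A `ubiq_sim_spec` list.
#' @export
synthetic_spec <- function(n_samples = 100L, n_ubiquitous = 200L,
                           n_specific = 600L, n_variable = 150L,
                           n_silent = 50L, seed = 1L, params = list()) {
  counts <- c(ubiquitous = n_ubiquitous, specific = n_specific,
              variable = n_variable, silent = n_silent)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(counts > 0) < 2L)
    warning("fewer than 2 non-empty gene classes; ranking-based checks are degenerate",
            call. = FALSE)
  default_params <- list(
    ubiquitous = list(detection = 1.00, meanlog = log(800), sdlog = 0.25),
    specific   = list(detection = 0.10, meanlog = log(200), sdlog = 1.00),
    variable   = list(detection = 0.95, meanlog = log(300), sdlog = 1.30),
    silent     = list(detection = 0.05, meanlog = log(0.5), sdlog = 0.50)
  )
  for (cls in names(params))
    default_params[[cls]] <- utils::modifyList(default_params[[cls]],
                                               params[[cls]])
  structure(list(n_samples = as.integer(n_samples), class_counts = counts,
                 params = default_params, seed = as.integer(seed)),
            class = "ubiq_sim_spec")
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate an expression matrix with planted gene classes
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `labels`
#'   (named character vector gene ID -> class).
#' @examples
#' sim <- simulate_expression(synthetic_spec(n_samples = 10, n_ubiquitous = 5,
#'   n_specific = 10, n_variable = 5, n_silent = 0, seed = 7))
#' table(sim$labels)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "ubiq_sim_spec"))
  with_seed(spec$seed, simulate_expression_impl(spec))
}

simulate_expression_impl <- function(spec) {
  n_genes <- sum(spec$class_counts)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  labels <- rep(names(spec$class_counts), times = spec$class_counts)
  names(labels) <- gene_ids
  m <- matrix(0, n_genes, spec$n_samples,
              dimnames = list(gene_ids,
                              sprintf("S%03d", seq_len(spec$n_samples))))
  for (cls in names(spec$class_counts)) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    p <- spec$params[[cls]]
    for (i in idx) {
      if (cls == "specific") {
        k <- max(1L, round(p$detection * spec$n_samples))
        detected <- sample.int(spec$n_samples, k)
      } else {
        detected <- which(stats::runif(spec$n_samples) < p$detection)
      }
      if (length(detected))
        m[i, detected] <- stats::rlnorm(length(detected), p$meanlog, p$sdlog)
    }
  }
  mat <- expression_matrix(m, meta = list(source = "synthetic",
                                          seed = spec$seed))
  list(matrix = mat, labels = labels)
}

#' Simulate a paired dataset with knocked-down ubiquitous genes
#'
#' Generates dataset A from `spec` and dataset B from the same generative
#' parameters, except that a random fraction of the planted ubiquitous genes
#' is knocked down in B: their detection probability is multiplied by
#' `knock_detection`, their expression level divided by `knock_level`, and
#' their log-scale spread raised to `knock_sdlog` (a perturbed gene is both
#' rarer and noisier). This emulates genes that are ubiquitous under
#' baseline conditions but lose that property under perturbation (sector
#' "10" of a cross-dataset comparison).
#'
#' @param spec A [synthetic_spec()].
#' @param perturb_fraction Fraction of planted ubiquitous genes knocked down
#'   in B (default 0.3).
#' @param seed Integer seed governing the pairing (defaults to `spec$seed`).
#' @param knock_detection,knock_level,knock_sdlog Knockdown severity.
#' @return List with `a`, `b` (expression matrices), `labels`, and
#'   `knocked_down` (gene IDs perturbed in B).
#' @export
simulate_paired_datasets <- function(spec, perturb_fraction = 0.3,
                                     seed = spec$seed, knock_detection = 0.3,
                                     knock_level = 10, knock_sdlog = 1.0) {
  stopifnot(inherits(spec, "ubiq_sim_spec"))
  with_seed(seed, {
    sim_a <- simulate_expression_impl(spec)
    ubiq <- names(sim_a$labels)[sim_a$labels == "ubiquitous"]
    n_knock <- round(perturb_fraction * length(ubiq))
    knocked <- sort(sample(ubiq, n_knock))
    sim_b <- simulate_expression_impl(spec)
    if (n_knock > 0) {
      p <- spec$params$ubiquitous
      kb <- matrix(0, n_knock, spec$n_samples)
      for (j in seq_len(n_knock)) {
        detected <- which(stats::runif(spec$n_samples) <
                            p$detection * knock_detection)
        if (length(detected))
          kb[j, detected] <- stats::rlnorm(length(detected),
                                           p$meanlog - log(knock_level),
                                           knock_sdlog)
      }
      b <- unclass_matrix(sim_b$matrix)
      b[knocked, ] <- kb
      sim_b$matrix <- expression_matrix(b, meta = attr(sim_b$matrix, "meta"))
    }
    list(a = sim_a$matrix, b = sim_b$matrix, labels = sim_a$labels,
         knocked_down = knocked)
  })
}

#' Simulate a drug-statistics table with planted drug classes
#'
#' Generates per (gene, drug) t-test summaries for two planted drug kinds:
#' broad drugs perturb genes of every class with an elevated hit probability
#' for ubiquitous genes (global perturbations preferentially visible on
#' broadly expressed genes), and specific drugs hit a small random subset of
#' non-ubiquitous genes only. Unaffected pairs get p-values uniform on
#' (0.05, 1\] and near-zero log fold changes; affected pairs get p <= 0.05
#' and |logFC| drawn from a gamma model with random sign.
#'
#' @param labels Named character vector gene ID -> class (see
#'   [simulate_expression()]).
#' @param n_broad_drugs,n_specific_drugs Number of drugs per kind
#'   (defaults 5 and 15).
#' @param effect Effect model; override entries of
#'   `list(broad_hit_ubiquitous = 0.40, broad_hit_other = 0.10,
#'   specific_hit = 0.03, lfc_shape = 2, lfc_rate = 1, null_lfc_sd = 0.05,
#'   class_lfc_multiplier = c())` — `class_lfc_multiplier` scales affected
#'   |logFC| per gene class (e.g. to plant larger effects on knocked-down
#'   genes).
#' @param seed Integer seed (default 1).
#' @return List with `stats` (a `ubiq_drug_stats` table covering every
#'   (gene, drug) pair) and `drug_classes` (named vector drug ID ->
#'   "broad"/"specific").
#' @export
simulate_drug_stats <- function(labels, n_broad_drugs = 5L,
                                n_specific_drugs = 15L, effect = list(),
                                seed = 1L) {
  eff <- utils::modifyList(list(
    broad_hit_ubiquitous = 0.40, broad_hit_other = 0.10, specific_hit = 0.03,
    lfc_shape = 2, lfc_rate = 1, null_lfc_sd = 0.05,
    class_lfc_multiplier = c()
  ), effect)
  genes <- names(labels)
  drugs <- c(if (n_broad_drugs > 0) sprintf("broadD%02d", seq_len(n_broad_drugs)),
             if (n_specific_drugs > 0) sprintf("specD%02d", seq_len(n_specific_drugs)))
  kinds <- c(rep("broad", n_broad_drugs), rep("specific", n_specific_drugs))
  names(kinds) <- drugs
  if (!length(drugs)) stop("need at least one drug", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_along(drugs), function(di) {
      kind <- kinds[[di]]
      if (kind == "broad") {
        p_hit <- ifelse(labels == "ubiquitous", eff$broad_hit_ubiquitous,
                        eff$broad_hit_other)
        moa <- "broad_perturbagen"
        atc <- "L"
      } else {
        p_hit <- ifelse(labels == "ubiquitous", 0, eff$specific_hit)
        moa <- "targeted_agent"
        atc <- "N"
      }
      hit <- stats::runif(length(genes)) < p_hit
      p <- ifelse(hit, stats::runif(length(genes), 0, 0.05),
                  stats::runif(length(genes), 0.05, 1))
      mult <- rep(1, length(genes))
      if (length(eff$class_lfc_multiplier)) {
        for (cls in names(eff$class_lfc_multiplier))
          mult[labels == cls] <- eff$class_lfc_multiplier[[cls]]
      }
      lfc <- ifelse(hit,
                    sample(c(-1, 1), length(genes), replace = TRUE) * mult *
                      stats::rgamma(length(genes), eff$lfc_shape, eff$lfc_rate),
                    stats::rnorm(length(genes), 0, eff$null_lfc_sd))
      data.frame(gene_id = genes, drug_id = drugs[di], p_value = p,
                 log_fc = lfc, concentration = "10uM", moa = moa, atc = atc,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    list(stats = drug_stats(tab, strip_versions = FALSE,
                            context = "simulated drug stats"),
         drug_classes = kinds)
  })
}
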