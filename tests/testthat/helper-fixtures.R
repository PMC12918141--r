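# Shared fixture builders and independent oracles.

mat_fix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_mat <- function(n_genes, n_samples, seed, zero_frac = 0.2) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, log(50), 1), n_genes, n_samples)
  m[runif(length(m)) < zero_frac] <- 0
  mat_fix(m)
}

# Minimal independent score-table builder for fixtures: rank by score
# descending (gene ID tie-break), percentile by the <=-fraction convention.
fake_scores <- function(gene_id, score) {
  ord <- order(-score, gene_id)
  df <- data.frame(gene_id = gene_id[ord], score = score[ord],
                   stringsAsFactors = FALSE)
  df$breadth <- df$level_raw <- df$level <- df$variation_raw <-
    df$variation <- 0
  df$rank <- seq_len(nrow(df))
  df$percentile <- vapply(df$score,
                          function(s) 100 * sum(df$score <= s) / nrow(df),
                          numeric(1))
  df <- df[c("gene_id", "breadth", "level_raw", "level", "variation_raw",
             "variation", "score", "rank", "percentile")]
  structure(df, class = c("ubiq_scores", "data.frame"),
            config = list(breadth = "above_p95", level = "median",
                          variation = "qcv", weights = default_weights()),
            n_samples = NA_integer_, meta = list())
}

write_gct_fixture <- function(path, m) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(NAME = rownames(m), Description = "na",
                   as.data.frame(unclass(m)), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Brute-force hypergeometric tail: enumerate every possible query draw of the
# observed size from the background and count draws whose overlap with the
# term is at least the observed one.
hyper_oracle <- function(query, term, background) {
  background <- unique(background)
  term <- intersect(unique(term), background)
  k_obs <- length(intersect(query, term))
  draws <- combn(length(background), length(query))
  is_term <- background %in% term
  hits <- apply(draws, 2, function(ix) sum(is_term[ix]) >= k_obs)
  mean(hits)
}
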