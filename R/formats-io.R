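#' Read a GCT 1.2 expression matrix
#'
#' GCT 1.2 files carry two header lines (`#1.2`, then
#' `<n_genes>TAB<n_samples>`) followed by a table with `NAME` and
#' `Description` columns. The description column is discarded into the
#' matrix's `meta`. Duplicate gene IDs (after optional version stripping) are
#' resolved by keeping the first occurrence, with a warning.
#'
#' @param path Path to a GCT 1.2 file.
#' @param strip_versions Strip Ensembl-style ".N" version suffixes from gene
#'   IDs before deduplication (default `TRUE`).
#' @return An [expression_matrix()].
#' @export
read_gct <- function(path, strip_versions = TRUE) {
  head <- readLines(path, n = 2L, warn = FALSE)
  if (length(head) < 2L)
    stop(sprintf("malformed GCT '%s': fewer than two header lines", path),
         call. = FALSE)
  if (trimws(head[1L]) != "#1.2")
    stop(sprintf("malformed GCT '%s': first line is '%s', expected '#1.2'",
                 path, head[1L]), call. = FALSE)
  dims <- strsplit(head[2L], "\t", fixed = TRUE)[[1L]]
  ndim <- suppressWarnings(as.integer(dims))
  if (length(ndim) < 2L || anyNA(ndim[1:2]))
    stop(sprintf("malformed GCT '%s': dimensions line is '%s'", path, head[2L]),
         call. = FALSE)
  n_genes <- ndim[1L]; n_samples <- ndim[2L]
  tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != n_samples + 2L)
    stop(sprintf("GCT dimension mismatch in '%s': declared %d samples, found %d data columns",
                 path, n_samples, ncol(tab) - 2L), call. = FALSE)
  if (nrow(tab) != n_genes)
    stop(sprintf("GCT dimension mismatch in '%s': declared %d genes, found %d data rows",
                 path, n_genes, nrow(tab)), call. = FALSE)
  ids <- tab[[1L]]
  desc <- tab[[2L]]
  if (strip_versions) ids <- strip_gene_versions(ids)
  keep <- dedupe_first(ids, context = path)
  vals <- parse_numeric_columns(tab[keep, -(1:2), drop = FALSE], path,
                                row_offset = 3L, col_offset = 2L)
  rownames(vals) <- ids[keep]
  expression_matrix(vals, meta = list(
    source = path, format = "GCT 1.2",
    description = stats::setNames(desc[keep], ids[keep])
  ))
}

#' Read a plain TSV expression matrix
#'
#' First column holds gene IDs, remaining columns one numeric sample each.
#' Score tables written by [write_scores()] are rejected (different schema).
#'
#' @inheritParams read_gct
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, strip_versions = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 2L)
    stop(sprintf("'%s': expected a gene-ID column plus >= 1 sample column", path),
         call. = FALSE)
  score_cols <- c("score", "rank", "percentile")
  if (all(score_cols %in% names(tab)))
    stop(sprintf("'%s' looks like a score table (has %s columns), not an expression matrix",
                 path, paste(score_cols, collapse = "/")), call. = FALSE)
  ids <- tab[[1L]]
  if (strip_versions) ids <- strip_gene_versions(ids)
  keep <- dedupe_first(ids, context = path)
  vals <- parse_numeric_columns(tab[keep, -1L, drop = FALSE], path,
                                row_offset = 1L, col_offset = 1L)
  rownames(vals) <- ids[keep]
  expression_matrix(vals, meta = list(source = path, format = "TSV"))
}

# Strict numeric parsing for character data frames; reports the first
# offending cell in file coordinates (header + skipped lines accounted for by
# the offsets).
parse_numeric_columns <- function(df, path, row_offset, col_offset) {
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- is.na(x)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("'%s': non-numeric value '%s' at data row %d, column %d ('%s')",
                   path, df[[j]][i], i + row_offset, j + col_offset,
                   names(df)[j]), call. = FALSE)
    }
    vals[, j] <- x
  }
  vals
}

#' Read a gene list (one ID per line)
#'
#' Lines starting with `#` are comments; blank lines ignored; duplicates
#' removed.
#'
#' @param path Path to the list file.
#' @param name Label for the list; defaults to the file name without extension.
#' @param strip_versions Strip ".N" version suffixes (default `TRUE`).
#' @return A `ubiq_gene_list`: list with elements `name` and `gene_ids`.
#' @export
read_gene_list <- function(path, name = NULL, strip_versions = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (strip_versions) lines <- strip_gene_versions(lines)
  gene_list(unique(lines), name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a gene list
#' @param gene_ids Character vector of gene IDs (deduplicated).
#' @param name Label.
#' @return A `ubiq_gene_list`.
#' @export
gene_list <- function(gene_ids, name = "gene_list") {
  structure(list(name = name, gene_ids = unique(as.character(gene_ids))),
            class = "ubiq_gene_list")
}

#' Read a gene-length table
#'
#' TSV with a gene-ID column and a length column (base pairs, positive).
#'
#' @inheritParams read_gene_list
#' @return Named numeric vector gene ID -> length in bp.
#' @export
read_gene_lengths <- function(path, strip_versions = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L)
    stop(sprintf("'%s': expected gene-ID and length columns", path), call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (strip_versions) ids <- strip_gene_versions(ids)
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len) || any(len <= 0))
    stop(sprintf("'%s': gene lengths must be positive numbers", path), call. = FALSE)
  keep <- dedupe_first(ids, context = path)
  stats::setNames(len[keep], ids[keep])
}

#' Read a drug-statistics table
#'
#' TSV with per (gene, drug) differential-expression summaries: columns
#' `gene_id`, `drug_id`, `p_value`, `log_fc` and optional `concentration`,
#' `moa`, `atc`. Validates that p-values lie in \[0, 1\], log fold changes are
#' finite, and (gene, drug, concentration) combinations are unique.
#'
#' @inheritParams read_gene_list
#' @return A `ubiq_drug_stats` data.frame.
#' @export
read_drug_stats <- function(path, strip_versions = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  drug_stats(tab, strip_versions = strip_versions, context = path)
}

#' Construct/validate a drug-statistics table
#'
#' @param df data.frame with columns `gene_id`, `drug_id`, `p_value`,
#'   `log_fc`; optional `concentration`, `moa`, `atc`.
#' @param strip_versions Strip ".N" suffixes from gene IDs.
#' @param context Label used in error messages.
#' @return The validated data.frame with class `ubiq_drug_stats`.
#' @export
drug_stats <- function(df, strip_versions = TRUE, context = "drug stats") {
  need <- c("gene_id", "drug_id", "p_value", "log_fc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$gene_id <- as.character(df$gene_id)
  if (strip_versions) df$gene_id <- strip_gene_versions(df$gene_id)
  df$drug_id <- as.character(df$drug_id)
  df$p_value <- as.numeric(df$p_value)
  df$log_fc <- as.numeric(df$log_fc)
  for (opt in c("concentration", "moa", "atc"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  bad_p <- which(!is.finite(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad_p))
    stop(sprintf("%s: p_value outside [0,1] at row(s) %s", context,
                 paste(utils::head(bad_p, 10L), collapse = ", ")), call. = FALSE)
  if (any(!is.finite(df$log_fc)))
    stop(sprintf("%s: non-finite log_fc values", context), call. = FALSE)
  key <- paste(df$gene_id, df$drug_id, df$concentration, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("%s: duplicate (gene, drug, concentration) at row(s) %s",
                 context, paste(utils::head(dup, 10L), collapse = ", ")),
         call. = FALSE)
  df <- df[c(need, "concentration", "moa", "atc")]
  class(df) <- c("ubiq_drug_stats", "data.frame")
  df
}

#' Write / read score tables
#'
#' `write_scores()` serializes a [ubiquity_score()] result to TSV with a
#' commented header describing the columns; `read_scores()` restores it
#' losslessly (gene IDs, raw and normalized subscores, composite score, rank,
#' percentile).
#'
#' @param scores A `ubiq_scores` table.
#' @param path Output/input path.
#' @return `read_scores()` returns a `ubiq_scores` data.frame.
#' @export
write_scores <- function(scores, path) {
  cfg <- attr(scores, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ubiquity score table",
    sprintf("# config: breadth=%s level=%s variation=%s weights=%s",
            cfg$breadth, cfg$level, cfg$variation,
            paste(format(cfg$weights, trim = TRUE), collapse = ",")),
    "# columns: gene_id, breadth (fraction of samples above threshold),",
    "#   level_raw/level (raw and min-max level), variation_raw/variation,",
    "#   score (composite, min-max), rank (1 = best), percentile [0,100]"
  ), con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  header <- readLines(path, warn = FALSE)
  cfg_line <- grep("^# config:", header, value = TRUE)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "breadth", "level_raw", "level", "variation_raw",
            "variation", "score", "rank", "percentile")
  if (!all(need %in% names(tab)))
    stop(sprintf("'%s' is not a score table: missing column(s) %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")), call. = FALSE)
  tab <- tab[need]
  if (nrow(tab)) {
    if (any(tab$percentile < 0 | tab$percentile > 100))
      stop(sprintf("'%s': percentile values outside [0,100]", path), call. = FALSE)
    if (!setequal(tab$rank, seq_len(nrow(tab))))
      stop(sprintf("'%s': ranks are not a permutation of 1..N", path), call. = FALSE)
  }
  cfg <- list(breadth = NA_character_, level = NA_character_,
              variation = NA_character_, weights = default_weights())
  if (length(cfg_line)) {
    f <- function(k) sub(sprintf(".*%s=(\\S+).*", k), "\\1", cfg_line[1L])
    cfg$breadth <- f("breadth"); cfg$level <- f("level")
    cfg$variation <- f("variation")
    w <- suppressWarnings(as.numeric(strsplit(f("weights"), ",")[[1L]]))
    if (length(w) == 3L && !anyNA(w))
      cfg$weights <- stats::setNames(w, c("breadth", "level", "variation"))
  }
  new_score_table(tab, config = cfg, n_samples = NA_integer_,
                  meta = list(source = path))
}

#' Read a gene-set collection (GMT-style TSV)
#'
#' Each line: term ID, source label, then tab-separated member gene IDs.
#' Terms with no members are rejected; term IDs must be unique.
#'
#' @inheritParams read_gene_list
#' @return A `ubiq_collection`: list of terms, each with `term_id`, `source`,
#'   `genes`.
#' @export
read_collection <- function(path, strip_versions = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  terms <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("'%s': collection line with no member genes: '%s'",
                   path, substr(l, 1, 60)), call. = FALSE)
    genes <- parts[-(1:2)]
    if (strip_versions) genes <- strip_gene_versions(genes)
    list(term_id = parts[1L], source = parts[2L], genes = unique(genes))
  })
  gene_set_collection(terms)
}

#' Construct a gene-set collection
#' @param terms List of `list(term_id=, source=, genes=)` entries.
#' @return A `ubiq_collection`.
#' @export
gene_set_collection <- function(terms) {
  ids <- vapply(terms, `[[`, character(1L), "term_id")
  if (anyDuplicated(ids))
    stop("duplicate term IDs in collection", call. = FALSE)
  if (any(vapply(terms, function(t) length(t$genes) == 0L, logical(1L))))
    stop("collection terms must have non-empty member sets", call. = FALSE)
  structure(stats::setNames(terms, ids), class = "ubiq_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
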