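#' Construct an expression matrix
#'
#' An expression matrix is the unit every scoring criterion consumes: a
#' non-negative numeric gene-by-sample matrix with unique gene identifiers as
#' row names, unique sample identifiers as column names, and a free-form
#' `meta` attribute recording provenance (source name, normalization applied).
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   dimnames set. All values must be finite and >= 0.
#' @param meta Named list of free-text provenance entries.
#' @return The matrix with class `"ubiq_matrix"` prepended and a `meta`
#'   attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' @export
expression_matrix <- function(values, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as rownames and sample IDs as colnames",
         call. = FALSE)
  storage.mode(values) <- "double"
  x <- structure(values, meta = as.list(meta))
  class(x) <- c("ubiq_matrix", class(values))
  validate_expression_matrix(x)
}

# Shared validator: dimnames unique, values finite and non-negative.
validate_expression_matrix <- function(x, require_samples = 1L) {
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene IDs in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  if (nrow(x) < 1L)
    stop("expression matrix must contain at least one gene", call. = FALSE)
  if (ncol(x) < require_samples)
    stop(sprintf("expression matrix must contain at least %d sample(s)",
                 require_samples), call. = FALSE)
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("expression values must be finite and >= 0; first offender: gene '%s', sample '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]), call. = FALSE)
  }
  x
}

#' @export
print.ubiq_matrix <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Expression matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  if (length(meta))
    cat(paste0("  ", names(meta), ": ", unlist(meta), collapse = "\n"), "\n")
  invisible(x)
}

# Strip Ensembl-style ".N" version suffixes from gene IDs; cross-dataset joins
# operate on unversioned IDs.
strip_gene_versions <- function(ids) sub("\\.[0-9]+$", "", ids)

# Deduplication policy: keep the first occurrence of each gene ID, warn with a
# count. Returns the row subset to keep.
dedupe_first <- function(ids, context = "input") {
  dup <- duplicated(ids)
  if (any(dup))
    warning(sprintf("%d duplicate gene ID(s) in %s; keeping first occurrence",
                    sum(dup), context), call. = FALSE)
  !dup
}
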