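#' Principal component analysis of samples
#'
#' PCA of the samples of an expression matrix: probe-set rows are centered
#' across samples (no variance scaling by default, the common choice for
#' expression data), the centered matrix is decomposed by SVD, and samples
#' are projected onto the components ("super genes" — linear combinations of
#' probe-set expression values capturing maximal variance). Rows with
#' missing values are dropped and counted. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param expr Expression matrix (probe sets x samples, log2), >= 2 samples.
#' @param n_components Components to keep (default all; clipped with a
#'   warning if too large).
#' @param scale_rows Also scale rows to unit variance (default FALSE);
#'   zero-variance rows are dropped when scaling.
#' @return An object of class `pca_result`: `scores` (samples x
#'   components), `variance_explained` (per component, fractions summing to
#'   <= 1), `loadings` (probe sets x components), `n_dropped_rows`.
#' @export
pca_samples <- function(expr, n_components = NULL, scale_rows = FALSE) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop("need >= 2 samples for PCA", call. = FALSE)
  keep <- rowSums(is.na(expr)) == 0L
  if (scale_rows) keep <- keep & apply(expr, 1, stats::sd, na.rm = TRUE) > 0
  x <- expr[keep, , drop = FALSE]
  n_dropped <- sum(!keep)

  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale_rows)
  k_max <- length(pc$sdev)
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) {
    warning("n_components clipped to ", k_max, call. = FALSE)
    n_components <- k_max
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = scores,
         variance_explained = ve[seq_len(n_components)],
         loadings = loadings,
         center = pc$center,
         n_dropped_rows = n_dropped),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
            collapse = ", "),
      if (length(x$variance_explained) > 5) "...", "\n")
  invisible(x)
}

#' Tidy PCA scores for plotting
#'
#' @param pca A `pca_result`.
#' @param sheet Optional sample sheet to merge group labels from.
#' @param n_components Components to include (default 2).
#' @return Data frame with `sample_id`, `PC1..PCk`, `variance_explained`
#'   columns plus sheet annotations if supplied.
#' @export
pca_plot_data <- function(pca, sheet = NULL, n_components = 2L) {
  k <- min(n_components, ncol(pca$scores))
  df <- data.frame(sample_id = rownames(pca$scores),
                   pca$scores[, seq_len(k), drop = FALSE],
                   stringsAsFactors = FALSE)
  if (!is.null(sheet)) df <- merge(df, sheet, by = "sample_id", sort = FALSE)
  attr(df, "variance_explained") <- pca$variance_explained[seq_len(k)]
  df
}
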