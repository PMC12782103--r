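#' Principal component analysis of one omics dataset
#'
#' Columns are always mean-centered and optionally scaled to unit variance;
#' the decomposition is computed from singular values (via [stats::prcomp()])
#' and the proportion of variance explained by component i is
#' `sigma_i^2 / sum(sigma^2)` over the full decomposition. A deterministic
#' sign convention is applied: within each loading column the
#' largest-magnitude entry is made positive (scores flipped to match), so
#' outputs are reproducible across platforms.
#'
#' @param dataset an `omx_matrix` (or plain numeric matrix).
#' @param k number of components to retain (1..5, and at most
#'   `min(n - 1, p)`).
#' @param scale scale columns to unit variance (default FALSE; an error is
#'   raised for constant columns when TRUE).
#' @return an `omx_pca`: `dataset_name`, `k`, `scores` (n x k), `loadings`
#'   (p x k), `var_explained` (length k), `sdev_all` (all singular values /
#'   sqrt(n-1)).
#' @export
run_pca <- function(dataset, k = 2L, scale = FALSE) {
  x <- if (inherits(dataset, "omx_matrix")) dataset$values else as.matrix(dataset)
  nm <- if (inherits(dataset, "omx_matrix")) dataset$name else "dataset"
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (k > 5L) stopf("at most 5 components may be retained")
  if (k < 1L || k > kmax)
    stopf("k = %d out of range (max %d for %d samples x %d features)", k, kmax, n, p)
  if (scale) {
    const <- which(apply(x, 2L, stats::var) == 0)
    if (length(const))
      stopf("constant column(s) cannot be unit-scaled: %s",
            paste(colnames(x)[const], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  ve <- ev / sum(ev)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(dataset_name = nm, k = k, scores = scores, loadings = loadings,
                 var_explained = ve[seq_len(k)], sdev_all = pc$sdev,
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL),
            class = "omx_pca")
}

#' @export
print.omx_pca <- function(x, ...) {
  cat(sprintf("PCA of '%s': %d components retained\n", x$dataset_name, x$k))
  cat("Variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(x$k), 100 * x$var_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Associate principal-component scores with metadata variables
#'
#' For every (metadata variable, component) pair, the PC score vector is
#' regressed on the variable (categorical variables enter as indicator
#' codes); the cell value is the overall ANOVA F-test p-value of that model.
#' Benjamini-Hochberg adjustment, when requested, is applied jointly across
#' the whole variable-by-component grid. Zero-variance variables yield `NA`
#' cells.
#'
#' @param pca an `omx_pca`.
#' @param metadata an `omx_metadata` aligned to the PCA scores.
#' @param apply_fdr compute BH-adjusted p-values (default FALSE).
#' @return an `omx_pc_assoc`: `raw_p` (variables x components), `adj_p` (or
#'   NULL), `method` = "anova_f".
#' @export
pc_metadata_association <- function(pca, metadata, apply_fdr = FALSE) {
  stopifnot(inherits(pca, "omx_pca"), inherits(metadata, "omx_metadata"))
  if (nrow(metadata$table) != nrow(pca$scores))
    stopf("metadata rows (%d) do not match PCA scores (%d)",
          nrow(metadata$table), nrow(pca$scores))
  vars <- names(metadata$table)
  raw <- matrix(NA_real_, length(vars), pca$k,
                dimnames = list(vars, colnames(pca$scores)))
  for (v in vars) {
    xv <- metadata$table[[v]]
    if (metadata$var_kind[[v]] == "categorical") xv <- as.factor(xv)
    if (length(unique(xv)) < 2L) next  # zero-variance: not applicable
    for (j in seq_len(pca$k)) {
      fit <- stats::lm(pca$scores[, j] ~ xv)
      an <- stats::anova(fit)
      raw[v, j] <- an[["Pr(>F)"]][1L]
    }
  }
  adj <- NULL
  if (apply_fdr) {
    flat <- as.vector(raw)
    ok <- !is.na(flat)
    flat[ok] <- bh_adjust(flat[ok])
    adj <- matrix(flat, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  }
  structure(list(raw_p = raw, adj_p = adj, method = "anova_f"),
            class = "omx_pc_assoc")
}

#' @export
print.omx_pc_assoc <- function(x, ...) {
  cat("PC-metadata association p-values (ANOVA F)\n")
  print(signif(x$raw_p, 3))
  invisible(x)
}

#' Long-format data behind the PCA score scatter-plot matrix
#'
#' One block of n rows per component pair (i < j <= k), carrying both score
#' coordinates and the sample's response level for colouring.
#'
#' @param pca an `omx_pca`.
#' @param response an `omx_response`.
#' @param metadata an `omx_metadata` aligned to the scores.
#' @return data frame with columns sample, pc_i, pc_j, score_i, score_j,
#'   response.
#' @export
score_plot_data <- function(pca, response, metadata) {
  y <- as.character(metadata$table[[response$name]])
  n <- nrow(pca$scores)
  pairs <- utils::combn(pca$k, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    data.frame(sample = seq_len(n), pc_i = i, pc_j = j,
               score_i = pca$scores[, i], score_j = pca$scores[, j],
               response = y, stringsAsFactors = FALSE)
  }))
}

#' Plot the association heatmap for an `omx_pc_assoc`
#'
#' Cells show -log10 p (raw or adjusted).
#' @param x an `omx_pc_assoc`.
#' @param adjusted use adjusted p-values when available.
#' @param ... passed to [graphics::image()].
#' @export
plot.omx_pc_assoc <- function(x, adjusted = FALSE, ...) {
  m <- if (adjusted && !is.null(x$adj_p)) x$adj_p else x$raw_p
  z <- -log10(t(m))
  z[!is.finite(z)] <- NA
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, axes = FALSE,
                  xlab = "", ylab = "", main = "PC-metadata associations (-log10 p)",
                  ...)
  graphics::axis(1, at = seq_len(nrow(z)), labels = rownames(z))
  graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 2)
  graphics::box()
  invisible(x)
}
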