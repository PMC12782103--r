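#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `adj_i = min over {j : p_(j) >= p_(i)} of min(1, m * p_(j) / j)` with
#' step-up monotonicity enforced. This single implementation is shared by
#' every stage that reports an FDR (differential expression, PC-metadata
#' associations, enrichment).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stopf("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m * p[o] / (m:1)))
  adj[order(o)]
}

## contrast vector for 'a vs b' on the coefficients of model.matrix(~ y)
contrast_vector <- function(levels_all, a, b) {
  if (!a %in% levels_all || !b %in% levels_all)
    stopf("contrast levels must be response levels (got '%s' vs '%s')", a, b)
  if (a == b) stopf("contrast levels must differ")
  cv <- numeric(length(levels_all))
  names(cv) <- levels_all
  cv[a] <- 1
  cv[b] <- cv[b] - 1
  cv[1L] <- 0  # reference level is absorbed by the intercept
  ## coefficient vector is (intercept, level2..levelg); intercept never enters
  c(0, cv[-1L])
}

de_table <- function(feature, log2fc, t_stat, df, p, method, fdr) {
  adj <- bh_adjust(p)
  out <- data.frame(feature = feature, log2fc = log2fc, t = t_stat, df = df,
                    p = p, adj_p = adj, significant = adj < fdr,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "fdr") <- fdr
  class(out) <- c("omx_detable", "data.frame")
  out
}

## shared per-feature OLS machinery: full model on all response levels,
## pairwise contrast extracted from the fitted coefficients
ols_feature_fits <- function(values, y, contrast) {
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- length(y)
  if (any(table(y) < 2L)) stopf("every response level needs >= 2 samples")
  df_res <- n - g
  if (df_res < 1L) stopf("zero residual degrees of freedom")
  X <- stats::model.matrix(~y)
  cv <- contrast_vector(levels(y), contrast[1L], contrast[2L])
  fit <- stats::lm.fit(X, values)
  coefs <- fit$coefficients               # g x p
  res <- as.matrix(values - X %*% coefs)
  s_sq <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(chol(crossprod(X)))
  v_c <- drop(t(cv) %*% xtx_inv %*% cv)   # unscaled contrast variance factor
  effect <- drop(cv %*% coefs)
  list(effect = effect, s_sq = s_sq, df = df_res, v_c = v_c, X = X, cv = cv,
       residuals = res)
}

#' Differential expression by ordinary least squares
#'
#' Per feature, a linear model on all response levels (indicator coding);
#' the effect is the difference of level means `a - b`, interpreted as a
#' log2 fold-change under the assumption that the input values are already
#' on the log2 scale (this is not checked — supply log-transformed data).
#' The t-statistic uses the residual df of the full model (`n - g`) and
#' p-values are BH-adjusted within the table.
#'
#' @param dataset an `omx_matrix` (values assumed log2 scale).
#' @param y response factor aligned to the dataset rows (reference level
#'   first).
#' @param contrast character vector `c(a, b)` of two response levels
#'   (`b` is typically the reference level).
#' @param fdr significance threshold on the adjusted p-values.
#' @return an `omx_detable` data frame: feature, log2fc, t, df, p, adj_p,
#'   significant.
#' @export
de_ols <- function(dataset, y, contrast, fdr = 0.05) {
  f <- ols_feature_fits(dataset$values, y, contrast)
  se <- sqrt(f$s_sq * f$v_c)
  t_stat <- ifelse(se == 0, 0, f$effect / se)
  p <- 2 * stats::pt(-abs(t_stat), df = f$df)
  de_table(dataset$feature_ids, f$effect, t_stat, rep(f$df, length(t_stat)),
           p, "ols", fdr)
}

#' Estimate the empirical-Bayes variance moderation prior
#'
#' Method of moments on `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`: the
#' prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = max(var(e) - trigamma(d/2), 0)`, inverted by Newton
#' iteration (when the max clamps to zero, `d0 = Inf`), and the prior
#' variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`, reducing
#' to `exp(mean(e))` in the `d0 = Inf` limit (the geometric mean of the
#' bias-corrected log variances). With equal sample variances this limit
#' differs from the common value by the chi-square log-scale bias factor
#' `exp(log(d/2) - digamma(d/2))`; the bias-corrected form is what keeps the
#' moderated t calibrated.
#'
#' @param s_sq per-feature residual variances (length >= 10, all > 0).
#' @param d residual degrees of freedom of each variance (>= 1).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_moderation_prior <- function(s_sq, d) {
  if (length(s_sq) < 10L) stopf("need >= 10 features to fit the prior")
  if (any(s_sq <= 0)) stopf("residual variances must be positive")
  if (d < 1) stopf("residual df must be >= 1")
  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  excess <- stats::var(e) - trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  x <- trigamma_inverse(excess)
  d0 <- 2 * x
  s0_sq <- exp(mean(e) + digamma(x) - log(x))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Invert the trigamma function by Newton iteration
#'
#' Solves `trigamma(x) = target` for `x > 0`. Newton steps on
#' `1/trigamma` (which is nearly linear) for stability, to 1e-10.
#'
#' @param target positive value.
#' @return x with `trigamma(x) = target`.
#' @export
trigamma_inverse <- function(target) {
  if (target <= 0) return(Inf)
  x <- 0.5 + 1 / target
  for (i in 1:60) {
    tg <- trigamma(x)
    delta <- tg * (1 - tg / target) / psigamma(x, 2L)
    x <- x + delta
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

## moderated statistics given per-feature effects/variances and a prior
moderated_stats <- function(effect, s_sq, d, v_c, prior) {
  d0 <- prior$d0
  s_tilde_sq <- if (is.infinite(d0)) rep(prior$s0_sq, length(s_sq)) else
    (d0 * prior$s0_sq + d * s_sq) / (d0 + d)
  se <- sqrt(s_tilde_sq * v_c)
  t_stat <- ifelse(se == 0, 0, effect / se)
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat)) else
    2 * stats::pt(-abs(t_stat), df = df_total)
  list(t = t_stat, df = df_total, p = p, s_tilde_sq = s_tilde_sq)
}

#' Differential expression with empirical-Bayes moderated t-statistics
#'
#' As [de_ols()] but each feature's residual variance is shrunk toward the
#' prior variance `s0^2` with prior df `d0` (estimated from all features by
#' [fit_moderation_prior()]); the moderated t has `d0 + d` degrees of
#' freedom (normal when `d0 = Inf`).
#'
#' @inheritParams de_ols
#' @return an `omx_detable`.
#' @export
de_moderated <- function(dataset, y, contrast, fdr = 0.05) {
  f <- ols_feature_fits(dataset$values, y, contrast)
  prior <- fit_moderation_prior(f$s_sq, f$df)
  m <- moderated_stats(f$effect, f$s_sq, f$df, f$v_c, prior)
  out <- de_table(dataset$feature_ids, f$effect, m$t,
                  rep(m$df, length(m$t)), m$p, "moderated", fdr)
  attr(out, "prior") <- prior
  out
}

#' Precision weights for count data (mean-variance trend)
#'
#' Counts are converted to log2 counts-per-million
#' `y = log2((count + 0.5) / (L_i + 1) * 1e6)` with `L_i` the library size
#' of sample i. Per-feature OLS residual standard deviations are square-root
#' transformed and regressed on the mean log2 count
#' `mean(y_g) + mean(log2(L + 1)) - log2(1e6)` by locally-weighted
#' regression (span 0.5). Each observation's predicted log2 count is mapped
#' through the fitted trend by piecewise-linear interpolation (flat beyond
#' the range) and the weight is the interpolated value to the power -4,
#' capped so the max/min weight ratio is at most 1e6.
#'
#' @param counts an `omx_matrix` with `is_count = TRUE`.
#' @param y response factor defining the design.
#' @return list with `logcpm` (n x p), `weights` (n x p, strictly positive
#'   and finite), `trend` (x, y of the fitted curve), `lib_size`.
#' @export
voom_weights <- function(counts, y) {
  if (!counts$is_count) stopf("dataset '%s' is not count data", counts$name)
  x <- counts$values
  if (ncol(x) < 10L) stopf("need >= 10 features to fit the mean-variance trend")
  L <- rowSums(x)
  if (any(L == 0)) stopf("sample(s) with all-zero counts: %s",
                         paste(which(L == 0), collapse = ", "))
  y <- droplevels(as.factor(y))
  logcpm <- log2(sweep(x + 0.5, 1L, L + 1, "/") * 1e6)
  X <- stats::model.matrix(~y)
  fit <- stats::lm.fit(X, logcpm)
  g <- nlevels(y)
  res <- as.matrix(logcpm - X %*% fit$coefficients)
  sdev <- sqrt(colSums(res^2) / (nrow(x) - g))
  mean_logcount <- colMeans(logcpm) + mean(log2(L + 1)) - log2(1e6)
  lo <- stats::lowess(mean_logcount, sqrt(sdev), f = 0.5)
  ## per-observation predicted log2 count from the feature's fitted log-cpm
  fitted_logcount <- X %*% fit$coefficients +
    matrix(log2(L + 1) - log2(1e6), nrow(x), ncol(x))
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_logcount),
                        rule = 2, ties = "ordered")$y
  w <- matrix(pred^-4, nrow(x), ncol(x))
  floor_w <- max(w) / 1e6
  w[w < floor_w] <- floor_w
  colnames(logcpm) <- colnames(w) <- counts$feature_ids
  list(logcpm = logcpm, weights = w, trend = list(x = lo$x, y = lo$y),
       lib_size = L)
}

#' Differential expression for counts via precision-weighted least squares
#'
#' Computes [voom_weights()], fits each feature by weighted least squares,
#' then applies the same variance moderation as [de_moderated()].
#'
#' @inheritParams de_ols
#' @param counts an `omx_matrix` of counts.
#' @return an `omx_detable` (effects are log2 fold-changes of CPM).
#' @export
de_voom <- function(counts, y, contrast, fdr = 0.05) {
  vw <- voom_weights(counts, y)
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- length(y)
  df_res <- n - g
  if (df_res < 1L) stopf("zero residual degrees of freedom")
  X <- stats::model.matrix(~y)
  cv <- contrast_vector(levels(y), contrast[1L], contrast[2L])
  p_feat <- ncol(vw$logcpm)
  effect <- s_sq <- v_c <- numeric(p_feat)
  for (j in seq_len(p_feat)) {
    w <- vw$weights[, j]
    fj <- stats::lm.wfit(X, vw$logcpm[, j], w)
    effect[j] <- sum(cv * fj$coefficients)
    s_sq[j] <- sum(w * fj$residuals^2) / df_res
    xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    v_c[j] <- drop(t(cv) %*% xtwx_inv %*% cv)
  }
  prior <- fit_moderation_prior(s_sq, df_res)
  m <- moderated_stats(effect, s_sq, df_res, v_c, prior)
  out <- de_table(counts$feature_ids, effect, m$t, rep(m$df, p_feat), m$p,
                  "voom", fdr)
  attr(out, "prior") <- prior
  attr(out, "voom") <- vw["trend"]
  out
}

#' Volcano table at a user-chosen FDR threshold
#'
#' Re-flags significance at `fdr` from the stored adjusted p-values without
#' refitting anything.
#'
#' @param de an `omx_detable`.
#' @param fdr threshold in (0, 1\] (0 and 1 accepted as degenerate bounds).
#' @return data frame: feature, log2fc, neg_log10_p, significant.
#' @export
volcano_table <- function(de, fdr = 0.05) {
  if (fdr < 0 || fdr > 1) stopf("fdr must lie in [0, 1]")
  data.frame(feature = de$feature, log2fc = de$log2fc,
             neg_log10_p = -log10(de$p), significant = de$adj_p < fdr,
             stringsAsFactors = FALSE)
}

#' Volcano plot of a differential-expression table
#' @param x an `omx_detable`.
#' @param fdr significance threshold.
#' @param ... passed to plot.
#' @export
plot.omx_detable <- function(x, fdr = attr(x, "fdr"), ...) {
  vt <- volcano_table(x, fdr)
  graphics::plot(vt$log2fc, vt$neg_log10_p,
                 col = ifelse(vt$significant, "red", "grey40"), pch = 16,
                 cex = 0.6, xlab = "log2 fold-change", ylab = "-log10 p",
                 main = sprintf("Volcano (%s, FDR %.2g)", attr(x, "method"), fdr),
                 ...)
  invisible(x)
}
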