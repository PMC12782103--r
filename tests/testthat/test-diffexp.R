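make_dataset <- function(x, name = "d") {
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  omics_from_df(x, name)
}

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj), order(adj[order(p)][rank(p)]))  # rank-monotone
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("OLS differential expression matches the pooled t-test", {
  ## orientation: effect is mean(a) - mean(b)
  x <- matrix(c(0, 0, 0, 1, 1, 1.1), 6, 1)
  y <- factor(rep(c("control", "case"), each = 3),
              levels = c("control", "case"))
  de <- de_ols(make_dataset(x), y, c("case", "control"))
  expect_equal(de$log2fc, mean(c(1, 1, 1.1)), tolerance = 1e-12)
  de_rev <- de_ols(make_dataset(x), y, c("control", "case"))
  expect_equal(de_rev$log2fc, -de$log2fc, tolerance = 1e-12)

  ## identical group means give t = 0, p = 1
  x0 <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1)
  de0 <- de_ols(make_dataset(x0), y, c("case", "control"))
  expect_equal(de0$t, 0)
  expect_equal(de0$p, 1)

  set.seed(8)
  xr <- matrix(rnorm(20 * 30), 20, 30)
  yr <- factor(rep(c("g0", "g1"), each = 10), levels = c("g0", "g1"))
  der <- de_ols(make_dataset(xr), yr, c("g1", "g0"))
  for (j in 1:30) {
    tt <- t.test(xr[11:20, j], xr[1:10, j], var.equal = TRUE)
    expect_equal(der$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(der$p[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("multi-level responses use the full-model residual df", {
  set.seed(13)
  x <- matrix(rnorm(18 * 12), 18, 12)
  y <- factor(rep(c("ctl", "mild", "severe"), each = 6),
              levels = c("ctl", "mild", "severe"))
  de <- de_moderated(make_dataset(x), y, c("severe", "ctl"))
  prior <- attr(de, "prior")
  expect_equal(unique(de$df), prior$d0 + (18 - 3))
  expect_error(de_ols(make_dataset(x), y, c("severe", "absent")),
               "response levels")
  expect_error(de_ols(make_dataset(x), y, c("ctl", "ctl")), "must differ")
})

test_that("trigamma inversion agrees with a bisection oracle", {
  bisect <- function(target) {
    lo <- 1e-8; hi <- 1e8
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > target) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  for (target in c(0.001, 0.05, 0.3, 1.5, 10, 200)) {
    expect_equal(trigamma_inverse(target), bisect(target), tolerance = 1e-8)
  }
})

test_that("moderation prior handles zero excess spread", {
  pr <- fit_moderation_prior(rep(2, 100), d = 6)
  expect_identical(pr$d0, Inf)
  ## the d0 = Inf limit is the geometric mean of the bias-corrected
  ## log variances: exp(mean(log s^2) - digamma(d/2) + log(d/2))
  expect_equal(pr$s0_sq, 2 * exp(log(3) - digamma(3)), tolerance = 1e-12)
  expect_error(fit_moderation_prior(c(rep(1, 9)), 4), ">= 10 features")
  expect_error(fit_moderation_prior(c(rep(1, 99), -1), 4), "positive")
})

test_that("posterior variance interpolates prior and sample variances", {
  ms <- omicspanel:::moderated_stats(effect = 1, s_sq = 2, d = 4,
                                     v_c = 1, prior = list(d0 = 4, s0_sq = 1))
  expect_equal(ms$s_tilde_sq, (4 * 1 + 4 * 2) / 8)  # = 1.5
  expect_equal(ms$df, 8)

  ## d0 -> 0+ recovers the ordinary t; d0 -> Inf the z with s0
  eff <- 0.7; s2 <- 2.3; d <- 6; vc <- 0.4
  t_ord <- eff / sqrt(s2 * vc)
  ms0 <- omicspanel:::moderated_stats(eff, s2, d, vc,
                                      list(d0 = 1e-10, s0_sq = 9))
  expect_equal(ms0$t, t_ord, tolerance = 1e-6)
  msI <- omicspanel:::moderated_stats(eff, s2, d, vc,
                                      list(d0 = Inf, s0_sq = 9))
  expect_equal(msI$t, eff / sqrt(9 * vc), tolerance = 1e-12)
  expect_equal(msI$p, 2 * pnorm(-abs(msI$t)), tolerance = 1e-12)
})

test_that("moderated statistics agree with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  n <- 10; p <- 400
  x <- matrix(rnorm(n * p, sd = rep(sqrt(rchisq(p, 5) / 5), each = n)), n, p)
  y <- factor(rep(c("a", "b"), each = n / 2), levels = c("a", "b"))
  de <- de_moderated(make_dataset(x), y, c("b", "a"))
  design <- model.matrix(~y)
  ebf <- limma::eBayes(limma::lmFit(t(x), design))
  expect_equal(attr(de, "prior")$d0, ebf$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$s0_sq, ebf$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(ebf$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(ebf$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t is calibrated on fully null data", {
  set.seed(55)
  x <- matrix(rnorm(10 * 2000), 10, 2000)
  y <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b"))
  de <- de_moderated(make_dataset(x), y, c("b", "a"))
  expect_gte(mean(de$p < 0.05), 0.035)
  expect_lte(mean(de$p < 0.05), 0.065)
})

test_that("count precision weights are positive, finite and trend-driven", {
  sim <- simulate_study(n = 12, p = 500, q = 0, delta = 0,
                        noise = "negative_binomial", seed = 17)
  counts <- sim$study$datasets[[1]]
  y <- sim$study$metadata$table$group
  vw <- voom_weights(counts, y)
  expect_true(all(is.finite(vw$weights)))
  expect_true(all(vw$weights > 0))
  expect_lte(max(vw$weights) / min(vw$weights), 1e6)

  ## two features with identical counts get identical weights
  c2 <- counts
  c2$values[, 2] <- c2$values[, 1]
  vw2 <- voom_weights(c2, y)
  expect_equal(vw2$weights[, 1], vw2$weights[, 2], tolerance = 1e-12)

  ## counts mean-variance: low-count features are down-weighted
  mean_count <- colMeans(counts$values)
  dec <- cut(mean_count, quantile(mean_count, 0:10 / 10), include.lowest = TRUE,
             labels = FALSE)
  expect_lt(mean(vw$weights[, dec == 1]), mean(vw$weights[, dec == 10]))

  bad <- counts
  bad$values[3, ] <- 0
  expect_error(voom_weights(bad, y), "all-zero")
})

test_that("count pipeline agrees with the established precision-weight fit", {
  skip_if_not_installed("limma")
  sim <- simulate_study(n = 12, p = 300, q = 20, delta = 1.5,
                        noise = "negative_binomial", seed = 23)
  counts <- sim$study$datasets[[1]]
  y <- sim$study$metadata$table$group
  vw <- voom_weights(counts, y)
  design <- model.matrix(~y)
  v <- limma::voom(t(counts$values), design, lib.size = rowSums(counts$values),
                   span = 0.5)
  expect_equal(vw$logcpm, t(v$E), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(vw$weights, t(v$weights), tolerance = 1e-6, ignore_attr = TRUE)

  de <- de_voom(counts, y, c("case", "control"))
  ebf <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(de$t, unname(ebf$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(ebf$p.value[, 2]), tolerance = 1e-6)
})

test_that("volcano tables re-threshold without refitting", {
  set.seed(3)
  x <- matrix(rnorm(12 * 50), 12, 50)
  x[7:12, 1:5] <- x[7:12, 1:5] + 3
  y <- factor(rep(c("a", "b"), each = 6), levels = c("a", "b"))
  de <- de_ols(make_dataset(x), y, c("b", "a"))
  v_all <- volcano_table(de, 1.0)
  expect_identical(v_all$significant, de$adj_p < 1)
  v_none <- volcano_table(de, 0)
  expect_false(any(v_none$significant))
  ## lowering the threshold never adds significant features
  fdrs <- c(0.2, 0.1, 0.05, 0.01)
  counts_sig <- vapply(fdrs, function(f) sum(volcano_table(de, f)$significant),
                       integer(1))
  expect_true(all(diff(counts_sig) <= 0))
  expect_equal(v_all$neg_log10_p, -log10(de$p))
})
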