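## hand one-way ANOVA oracle: between/within sums of squares
anova_oracle <- function(x, g) {
  g <- as.factor(g)
  grand <- mean(x)
  ss_b <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(g) - 1
  df_w <- length(x) - nlevels(g)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

## direct Kruskal-Wallis formula with tie correction
kw_oracle <- function(x, g) {
  g <- as.factor(g)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, function(ri)
    sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

test_that("continuous regression matches the hand ANOVA oracle", {
  x <- c(0, 0, 1, 1, 10, 10, 11, 11)
  g <- rep(c("a", "b"), each = 4)
  orc <- anova_oracle(x, g)
  expect_equal(orc$f, 600)  # between SS 200 on 1 df, within SS 2 on 6 df
  res <- test_continuous_regression(x, g)
  expect_equal(res$row$statistic, orc$f, tolerance = 1e-12)
  expect_equal(res$row$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$row$per_group_summary["a", "mean"], 0.5)
  expect_equal(res$row$per_group_summary["b", "sd"], sd(c(10, 10, 11, 11)))

  set.seed(11)
  for (i in 1:20) {
    g3 <- sample(c("a", "b", "c"), 30, replace = TRUE, prob = c(.4, .3, .3))
    while (min(table(g3)) < 2) g3 <- sample(c("a", "b", "c"), 30, replace = TRUE)
    xr <- rnorm(30)
    orc <- anova_oracle(xr, g3)
    res <- test_continuous_regression(xr, g3)
    expect_equal(res$row$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("continuous regression handles degenerate inputs", {
  expect_error(test_continuous_regression(rep(1, 8), rep(c("a", "b"), 4)),
               "zero variance")
  expect_error(test_continuous_regression(1:5, c("a", "a", "b", "b", "c")),
               ">= 2 observations")
  res <- test_continuous_regression(c(1, 2, 3, 1, 2, 3),
                                    rep(c("a", "b"), each = 3))
  expect_equal(res$row$statistic, 0)
  expect_equal(res$row$p_value, 1)
})

test_that("Kruskal-Wallis matches rank arithmetic", {
  row <- test_continuous_kw(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(row$statistic, 2.4, tolerance = 1e-12)  # R1=3, R2=7, N=4
  expect_equal(row$p_value, pchisq(2.4, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(row$per_group_summary["a", "median"], 1.5)

  ## identical group value-multisets give H ~ 0
  row0 <- test_continuous_kw(c(5, 7, 9, 5, 7, 9), rep(c("a", "b"), each = 3))
  expect_lt(row0$statistic, 1e-10)

  set.seed(21)
  for (i in 1:50) {
    g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    while (min(table(g)) < 1 || length(unique(g)) < 3)
      g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    x <- rnorm(24)
    row <- test_continuous_kw(x, g)
    expect_equal(row$statistic, kw_oracle(x, g), tolerance = 1e-10)
  }
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank-sum", {
  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    x <- rnorm(n1 + n2)   # continuous: no ties
    g <- rep(c("a", "b"), c(n1, n2))
    w <- sum(rank(x)[g == "a"])
    N <- n1 + n2
    z <- (w - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(test_continuous_kw(x, g)$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("categorical chi-square matches direct cell arithmetic", {
  x <- rep(c("m", "f"), each = 20)
  g <- c(rep("a", 10), rep("b", 10), rep("a", 10), rep("b", 10))
  row <- test_categorical(x, g)
  expect_equal(row$statistic, 0)
  expect_equal(row$p_value, 1)

  ## [[20,5],[5,20]]: all expected counts 12.5, X^2 = 4 * 7.5^2/12.5 = 18
  x2 <- rep(c("m", "f"), c(25, 25))
  g2 <- c(rep("a", 20), rep("b", 5), rep("a", 5), rep("b", 20))
  row2 <- test_categorical(x2, g2, yates = FALSE)
  expect_equal(row2$statistic, 18, tolerance = 1e-12)
  expect_equal(row2$p_value, pchisq(18, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  ## invariance to swapping rows with columns
  row2t <- test_categorical(g2, x2, yates = FALSE)
  expect_equal(row2$statistic, row2t$statistic, tolerance = 1e-12)

  ## 2x3 tables use df = 2 and never the continuity correction
  x3 <- rep(c("m", "f"), 15)
  g3 <- rep(c("a", "b", "c"), each = 10)
  row3 <- test_categorical(x3, g3)
  expect_equal(row3$df, 2)
  expect_identical(row3$test_name, "chi-square")

  expect_error(test_categorical(rep("m", 10), rep(c("a", "b"), 5)), "2x2")
})

test_that("column percentages sum to 100 within each group", {
  set.seed(5)
  x <- sample(c("m", "f", "x"), 60, replace = TRUE)
  g <- rep(c("a", "b"), 30)
  row <- test_categorical(x, g)
  pct <- row$per_group_summary[, c("a_pct", "b_pct")]
  expect_equal(unname(colSums(pct)), c(100, 100), tolerance = 0.01)
})

test_that("assumption validation decomposes into four chi-square components", {
  ## symmetric alternating residuals: odd moments vanish, skewness = 0
  r <- rep(c(-1, 1), 50)
  rep_ <- global_validate(r, fitted = rnorm(100))
  expect_lt(rep_$components[["skewness"]], 1e-20)
  expect_equal(rep_$global_stat, sum(rep_$components), tolerance = 1e-12)
  expect_equal(rep_$global_df, 4)

  ## well-behaved normal residuals: no rejection at extreme levels
  set.seed(101)
  x <- rnorm(500); yv <- rnorm(500)
  fit <- lm(yv ~ x)
  rep2 <- global_validate(residuals(fit), fitted(fit))
  expect_gt(rep2$global_p, 0.001)

  ## residuals tracking fitted^2: the link component must fire
  set.seed(102)
  f <- rnorm(300)
  r3 <- f^2 - mean(f^2) + rnorm(300, sd = 0.1)
  rep3 <- global_validate(r3, f)
  expect_lt(rep3$component_p[["link_function"]], 0.01)
  expect_identical(rep3$verdict, "violated")

  ## constant fitted values: link/heteroscedasticity not applicable
  rep4 <- global_validate(rnorm(50), rep(2, 50))
  expect_true(is.na(rep4$components[["link_function"]]))
  expect_equal(rep4$global_df, 2)
  expect_error(global_validate(rnorm(5), rnorm(5)), "at least 8")
})

test_that("global assumption test holds its type-I error under the null", {
  set.seed(2024)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(200); yv <- rnorm(200)
    fit <- stats::lm.fit(cbind(1, x), yv)
    global_validate(fit$residuals, yv - fit$residuals)$global_p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("build_table1 covers every non-response variable", {
  md <- data.frame(group = rep(c("a", "b"), each = 20),
                   age = rnorm(40, 50),
                   sex = sample(rep(c("m", "f"), 20)),
                   stringsAsFactors = FALSE)
  lm <- metadata_from_df(md, "group", "a")
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  st <- assemble_study(lm$metadata, lm$response, list(omics_from_df(x, "d")))
  t1 <- build_table1(st)
  expect_length(t1, 2)
  expect_setequal(vapply(t1, `[[`, character(1), "variable"), c("age", "sex"))
  expect_s3_class(t1[[1]]$assumptions, "omx_assumptions")

  t1k <- build_table1(st, mode = "nonparametric")
  age_row <- t1k[[which(vapply(t1k, `[[`, character(1), "variable") == "age")]]
  expect_identical(age_row$test_name, "Kruskal-Wallis")

  ## all-categorical metadata: every row is a chi-square test
  md2 <- data.frame(group = rep(c("a", "b"), each = 20),
                    sex = sample(rep(c("m", "f"), 20)),
                    site = sample(rep(c("s1", "s2"), 20)),
                    stringsAsFactors = FALSE)
  lm2 <- metadata_from_df(md2, "group", "a")
  st2 <- assemble_study(lm2$metadata, lm2$response, list(omics_from_df(x, "d")))
  t2 <- build_table1(st2)
  expect_true(all(grepl("chi-square", vapply(t2, `[[`, character(1),
                                             "test_name"))))
})

test_that("a planted group shift is detected while null variables stay quiet", {
  set.seed(77)
  n <- 100
  g <- rep(c("a", "b"), each = n / 2)
  md <- data.frame(group = g,
                   shifted = rnorm(n) + ifelse(g == "b", 2, 0),
                   null1 = rnorm(n), null2 = rnorm(n), null3 = rnorm(n),
                   stringsAsFactors = FALSE)
  lm <- metadata_from_df(md, "group", "a")
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  st <- assemble_study(lm$metadata, lm$response, list(omics_from_df(x, "d")))
  df <- as.data.frame(build_table1(st))
  expect_lt(df$p_value[df$variable == "shifted"], 0.001)
  expect_gt(mean(df$p_value[df$variable != "shifted"]), 0.01)
})

test_that("markdown rendering of Table 1 yields a pipe table", {
  st <- tiny_study()
  md_lines <- table1_markdown(build_table1(st))
  expect_match(md_lines[1], "^\\| variable")
  expect_match(md_lines[2], "^\\|---")
  expect_length(md_lines, 2 + 1)  # header, separator, one row (age)
})
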