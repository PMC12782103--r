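#' Global validation of linear-regression assumptions
#'
#' Four directional chi-square(1) components computed on the residuals of a
#' fitted linear model, plus their sum as a global chi-square(4) statistic:
#'
#' * skewness: `n * g1^2 / 6` with `g1 = m3 / m2^(3/2)` (moments about the
#'   residual mean, maximum-likelihood scale);
#' * kurtosis: `n * (g2 - 3)^2 / 24` with `g2 = m4 / m2^2`;
#' * link function: score test `n * R^2` from regressing the residuals on the
#'   squared fitted values;
#' * heteroscedasticity: Breusch-Pagan `n * R^2` from regressing the squared
#'   scaled residuals `r^2 / m2` on the fitted values.
#'
#' When the fitted values are constant the link and heteroscedasticity
#' components are undefined; they are reported as `NA` and the global degrees
#' of freedom reduce accordingly. The verdict is `"violated"` iff the global
#' p-value is below `alpha`.
#'
#' @param residuals residual vector (length >= 8).
#' @param fitted fitted values, same length.
#' @param alpha verdict threshold (default 0.05).
#' @return an `omx_assumptions` list: per-component statistic/p-value,
#'   `global_stat`, `global_df`, `global_p`, `verdict`.
#' @export
global_validate <- function(residuals, fitted, alpha = 0.05) {
  n <- length(residuals)
  if (n < 8L) stopf("need at least 8 residuals to validate assumptions")
  if (length(fitted) != n) stopf("residuals and fitted must have equal length")
  r <- residuals - mean(residuals)
  m2 <- mean(r^2)
  if (m2 == 0) stopf("residuals have zero variance")
  g1 <- mean(r^3) / m2^1.5
  g2 <- mean(r^4) / m2^2
  skew <- n * g1^2 / 6
  kurt <- n * (g2 - 3)^2 / 24

  nR2 <- function(yy, xx) {
    fit <- stats::lm.fit(cbind(1, xx), yy)
    tss <- sum((yy - mean(yy))^2)
    if (tss == 0) return(0)
    n * (1 - sum(fit$residuals^2) / tss)
  }
  const_fit <- stats::var(fitted) == 0
  link <- if (const_fit) NA_real_ else nR2(r, fitted^2)
  het <- if (const_fit) NA_real_ else nR2(r^2 / m2, fitted)

  comp <- c(skewness = skew, kurtosis = kurt, link_function = link,
            heteroscedasticity = het)
  comp_p <- stats::pchisq(comp, df = 1, lower.tail = FALSE)
  global_df <- sum(!is.na(comp))
  global_stat <- sum(comp, na.rm = TRUE)
  global_p <- stats::pchisq(global_stat, df = global_df, lower.tail = FALSE)
  structure(list(components = comp, component_p = comp_p,
                 global_stat = global_stat, global_df = global_df,
                 global_p = global_p,
                 verdict = if (global_p < alpha) "violated" else "assumptions_ok"),
            class = "omx_assumptions")
}

#' @export
print.omx_assumptions <- function(x, ...) {
  cat("Regression assumption validation (chi-square decomposition)\n")
  df <- data.frame(statistic = x$components, p_value = x$component_p)
  print(round(df, 5))
  cat(sprintf("Global: stat = %.4f on %d df, p = %.5g -> %s\n",
              x$global_stat, x$global_df, x$global_p, x$verdict))
  invisible(x)
}

table1_row <- function(variable, kind, summary, test_name, statistic, df,
                       p_value, assumptions = NULL, error = NULL) {
  structure(list(variable = variable, kind = kind, per_group_summary = summary,
                 test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, assumptions = assumptions, error = error),
            class = "omx_table1_row")
}

#' Test a continuous variable against the response by linear regression
#'
#' One-way OLS of `x` on the group indicators; the reported statistic is the
#' overall F against the intercept-only model, with per-group means and
#' standard deviations, and an assumption report from [global_validate()] on
#' the residuals.
#'
#' @param x numeric vector.
#' @param response factor of group labels (>= 2 groups, each >= 2
#'   observations).
#' @return list with `row` (a Table-1 row) and `assumptions`.
#' @export
test_continuous_regression <- function(x, response) {
  response <- droplevels(as.factor(response))
  if (nlevels(response) < 2L) stopf("need at least 2 groups")
  if (any(table(response) < 2L)) stopf("every group needs >= 2 observations")
  if (stats::var(x) == 0) stopf("variable has zero variance")
  fit <- stats::lm(x ~ response)
  an <- stats::anova(fit)
  f <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  dfs <- an[["Df"]]
  summ <- do.call(rbind, lapply(split(x, response), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v))))
  assum <- tryCatch(global_validate(stats::residuals(fit), stats::fitted(fit)),
                    error = function(e) NULL)
  row <- table1_row(NA_character_, "numerical", summ, "linear regression (F)",
                    f, dfs, p, assumptions = assum)
  list(row = row, assumptions = assum)
}

#' Test a continuous variable against the response by Kruskal-Wallis
#'
#' Tie-corrected Kruskal-Wallis rank-sum test with the chi-square
#' approximation on `g - 1` degrees of freedom; summaries are per-group
#' minimum, median and maximum.
#'
#' @inheritParams test_continuous_regression
#' @return a Table-1 row.
#' @export
test_continuous_kw <- function(x, response) {
  response <- droplevels(as.factor(response))
  if (nlevels(response) < 2L) stopf("need at least 2 groups")
  if (length(x) < 3L) stopf("need at least 3 observations in total")
  if (stats::var(x) == 0) stopf("all values are tied across all samples")
  kw <- stats::kruskal.test(x, response)
  summ <- do.call(rbind, lapply(split(x, response), function(v)
    data.frame(min = min(v), median = stats::median(v), max = max(v))))
  table1_row(NA_character_, "numerical", summ, "Kruskal-Wallis",
             unname(kw$statistic), unname(kw$parameter), kw$p.value)
}

#' Test a categorical variable against the response by Pearson chi-square
#'
#' Counts and column percentages per response group; Yates continuity
#' correction is applied iff the contingency table is 2x2 (configurable).
#'
#' @param x categorical vector.
#' @param response factor of group labels.
#' @param yates apply continuity correction to 2x2 tables (default TRUE).
#' @return a Table-1 row.
#' @export
test_categorical <- function(x, response, yates = TRUE) {
  response <- droplevels(as.factor(response))
  tab <- table(x, response)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("contingency table must be at least 2x2 (got %dx%d)",
          nrow(tab), ncol(tab))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has a zero margin")
  correct <- yates && nrow(tab) == 2L && ncol(tab) == 2L
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  pct <- sweep(tab, 2L, colSums(tab), "/") * 100
  summ <- data.frame(as.data.frame.matrix(tab), check.names = FALSE)
  for (g in colnames(pct)) summ[[paste0(g, "_pct")]] <- pct[, g]
  table1_row(NA_character_, "categorical",
             summ,
             if (correct) "chi-square (Yates)" else "chi-square",
             unname(ct$statistic), unname(ct$parameter), ct$p.value)
}

#' Build the cohort characteristics table ("Table 1")
#'
#' One row per metadata variable (excluding the response): numerical
#' variables are analysed by linear regression or the Kruskal-Wallis test,
#' categorical variables by chi-square. Per-variable failures are captured in
#' the row's `error` field rather than aborting the table.
#'
#' @param study an `omx_study`.
#' @param mode `"regression"` or `"nonparametric"`, either a single value or
#'   a named vector per numerical variable.
#' @param yates see [test_categorical()].
#' @return an `omx_table1` (list of rows).
#' @export
build_table1 <- function(study, mode = "regression", yates = TRUE) {
  stopifnot(inherits(study, "omx_study"))
  y <- study_response_factor(study)
  vars <- setdiff(names(study$metadata$table), study$response$name)
  rows <- lapply(vars, function(v) {
    kind <- study$metadata$var_kind[[v]]
    m <- if (length(mode) > 1L && v %in% names(mode)) mode[[v]] else mode[[1L]]
    res <- tryCatch({
      if (kind == "numerical") {
        if (m == "regression") test_continuous_regression(study$metadata$table[[v]], y)$row
        else test_continuous_kw(study$metadata$table[[v]], y)
      } else {
        test_categorical(study$metadata$table[[v]], y, yates = yates)
      }
    }, error = function(e)
      table1_row(v, kind, NULL, NA_character_, NA_real_, NA_real_, NA_real_,
                 error = conditionMessage(e)))
    res$variable <- v
    res
  })
  structure(rows, class = "omx_table1")
}

#' Flatten a Table 1 into a data frame of test results
#' @param x an `omx_table1`.
#' @param ... unused.
#' @return data frame with variable, kind, test, statistic, df, p-value,
#'   assumption verdict and error columns.
#' @export
as.data.frame.omx_table1 <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    variable = r$variable, kind = r$kind, test = r$test_name,
    statistic = r$statistic, df = paste(round(r$df, 2), collapse = ";"),
    p_value = r$p_value,
    assumptions = if (is.null(r$assumptions)) NA_character_ else r$assumptions$verdict,
    error = if (is.null(r$error)) NA_character_ else r$error,
    stringsAsFactors = FALSE)))
}

#' @export
print.omx_table1 <- function(x, ...) {
  cat("Cohort characteristics (Table 1)\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Render a Table 1 as a markdown pipe table
#' @param x an `omx_table1`.
#' @return character vector of markdown lines.
#' @export
table1_markdown <- function(x) {
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 4)
  markdown_table(df)
}

## generic data-frame -> markdown pipe table
markdown_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
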