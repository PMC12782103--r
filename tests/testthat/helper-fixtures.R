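## Shared test fixtures, all built in code.

write_tmp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

## minimal metadata + single-dataset study built in memory
tiny_study <- function(n = 12, p = 6, seed = 42) {
  set.seed(seed)
  md <- data.frame(group = rep(c("healthy", "sick"), each = n / 2),
                   age = round(rnorm(n, 50, 8), 1),
                   stringsAsFactors = FALSE)
  lm <- metadata_from_df(md, "group", "healthy")
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  assemble_study(lm$metadata, lm$response, list(omics_from_df(x, "omics1")))
}

## a stub panel object for method-level tests that don't need a real fit
stub_panel <- function(coefs, name = "stub", oof = NULL,
                       levels = c("control", "case")) {
  structure(list(dataset_name = name,
                 coefficients = coefs,
                 selected_features = names(coefs)[coefs != 0],
                 oof_mean = oof,
                 oof_scores = if (is.null(oof)) NULL else cbind(oof),
                 levels = levels,
                 alpha = 0.5, lambda = 0.1, cv_metric = NA,
                 cv = cv_config(seed = 1)),
            class = "omx_panel")
}

## exact hypergeometric upper tail from integer choose() products
hyper_upper_oracle <- function(k, K, N, n_q) {
  i <- max(0L, k):min(K, n_q)
  num <- sum(choose(K, i) * choose(N - K, n_q - i))
  num / choose(N, n_q)
}

## brute-force BH oracle: the step-up definition applied literally
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(seq_along(p), function(i) {
    js <- which(ps >= p[i])
    min(1, min(m * ps[js] / js))
  }, numeric(1))
}

## rank-based concordance AUC (ties counted one half)
auc_concordance <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  u <- sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}
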