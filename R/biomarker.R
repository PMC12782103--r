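#' Cross-validation configuration
#'
#' @param folds folds per repeat (>= 2; must not exceed the smallest class
#'   count).
#' @param repeats repeats (>= 1).
#' @param seed integer seed; splits are a pure function of it.
#' @param metric `"auc"` or `"accuracy"`.
#' @param family `"gaussian_on_indicator"` (0/1-coded response under squared
#'   loss, predictions clipped to \[0, 1\]) or `"binomial"`.
#' @return an `omx_cvconfig` list.
#' @export
cv_config <- function(folds = 5L, repeats = 5L, seed = 1L,
                      metric = c("auc", "accuracy"),
                      family = c("gaussian_on_indicator", "binomial")) {
  if (folds < 2L) stopf("folds must be >= 2")
  if (repeats < 1L) stopf("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), metric = match.arg(metric),
                 family = match.arg(family)),
            class = "omx_cvconfig")
}

#' Hyperparameter grid
#' @param alphas mixing values in \[0, 1\] (default 0, 0.1, ..., 1).
#' @param lambdas `"auto"` (per-alpha log-spaced path from `lambda_max` down
#'   to `1e-3 * lambda_max`, 50 values) or an explicit positive vector.
#' @param n_lambda grid size when `lambdas = "auto"`.
#' @export
hyper_grid <- function(alphas = seq(0, 1, by = 0.1), lambdas = "auto",
                       n_lambda = 50L) {
  if (!length(alphas)) stopf("alphas must be non-empty")
  if (any(alphas < 0 | alphas > 1)) stopf("alphas must lie in [0, 1]")
  if (!identical(lambdas, "auto") && any(lambdas <= 0))
    stopf("lambdas must be positive")
  structure(list(alphas = sort(alphas), lambdas = lambdas,
                 n_lambda = as.integer(n_lambda)), class = "omx_hypergrid")
}

## deterministic stratified fold assignment: within each class, shuffle and
## deal fold labels round-robin
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < folds)
      stopf("class '%s' has %d samples; cannot stratify into %d folds",
            lev, length(idx), folds)
    assign[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  }
  assign
}

## population-sd standardization fit on training rows only
std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  scl[scl == 0] <- 1   # zero-variance: column becomes all-zero after centering
  list(center = ctr, scale = scl)
}
std_apply <- function(X, st) sweep(sweep(X, 2L, st$center), 2L, st$scale, "/")

cv_metric <- function(scores, y01, metric) {
  if (metric == "auc") roc_curve(scores, y01)$auc
  else mean((scores > 0.5) == (y01 == 1))
}

#' Fit one dataset's biomarker panel by repeated cross-validated elastic net
#'
#' Stratified folds are drawn deterministically from the seed;
#' standardization is fit on the training folds only and applied to the
#' held-out fold; the hyperparameter pair maximizing the mean out-of-fold
#' metric across folds x repeats is selected (ties broken toward the largest
#' lambda, i.e. the sparsest model, then the largest alpha), and the final
#' model is refit on all samples at the selected pair. Out-of-fold predicted
#' probabilities at the selected pair are retained per repeat.
#'
#' @param dataset an `omx_matrix` (or numeric matrix with column names).
#' @param y binary response factor (reference level first).
#' @param grid an [hyper_grid()].
#' @param cv an [cv_config()].
#' @param name dataset label override.
#' @return an `omx_panel` with elements `dataset_name`, `alpha`, `lambda`,
#'   `intercept`, `coefficients` (standardized scale), `selected_features`,
#'   `oof_scores` (n x repeats), `oof_mean`, `cv_metric_table`, `std`
#'   (full-data centering/scaling), `levels`, `cv`, `grid`.
#' @export
fit_panel <- function(dataset, y, grid = hyper_grid(), cv = cv_config(),
                      name = NULL) {
  X <- if (inherits(dataset, "omx_matrix")) dataset$values else as.matrix(dataset)
  nm <- if (!is.null(name)) name else
    if (inherits(dataset, "omx_matrix")) dataset$name else "dataset"
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("response must be binary for biomarker discovery")
  if (cv$folds > min(table(y)))
    stopf("folds (%d) exceed the smallest class count (%d)", cv$folds,
          min(table(y)))
  y01 <- as.numeric(y) - 1
  n <- nrow(X)
  family <- if (cv$family == "binomial") "binomial" else "gaussian"

  ## fixed per-alpha lambda grids from the full (standardized) data
  st_full <- std_fit(X)
  Xs_full <- std_apply(X, st_full)
  lam_grids <- lapply(grid$alphas, function(a) {
    if (identical(grid$lambdas, "auto"))
      auto_lambda_grid(Xs_full, y01, a, n_lambda = grid$n_lambda)
    else sort(grid$lambdas, decreasing = TRUE)
  })
  n_lam <- lengths(lam_grids)

  set.seed(cv$seed)
  ## oof score accumulator: samples x (alpha x lambda) per repeat;
  ## per-fold metric: (alpha x lambda) x (fold x repeat)
  oof <- lapply(seq_len(cv$repeats), function(r)
    lapply(seq_along(grid$alphas), function(a) matrix(NA_real_, n, n_lam[a])))
  met <- lapply(seq_along(grid$alphas), function(a)
    matrix(NA_real_, n_lam[a], cv$folds * cv$repeats))
  for (r in seq_len(cv$repeats)) {
    fold_id <- stratified_folds(y, cv$folds)
    for (f in seq_len(cv$folds)) {
      tr <- fold_id != f
      st <- std_fit(X[tr, , drop = FALSE])
      Xtr <- std_apply(X[tr, , drop = FALSE], st)
      Xte <- std_apply(X[!tr, , drop = FALSE], st)
      for (a in seq_along(grid$alphas)) {
        fit <- suppressWarnings(elastic_net_path(
          Xtr, y01[tr], grid$alphas[a], lam_grids[[a]], family = family))
        for (l in seq_len(n_lam[a])) {
          sc <- enet_predict_score(fit$intercept[l], fit$beta[, l], Xte, family)
          oof[[r]][[a]][!tr, l] <- sc
          met[[a]][l, (r - 1L) * cv$folds + f] <-
            cv_metric(sc, y01[!tr], cv$metric)
        }
      }
    }
  }
  cv_table <- do.call(rbind, lapply(seq_along(grid$alphas), function(a)
    data.frame(alpha = grid$alphas[a], lambda = lam_grids[[a]],
               mean_metric = rowMeans(met[[a]]),
               sd_metric = apply(met[[a]], 1L, stats::sd),
               a_idx = a, l_idx = seq_len(n_lam[a]))))
  ## selection: max mean metric; ties -> largest lambda, then largest alpha
  ord <- order(-cv_table$mean_metric, -cv_table$lambda, -cv_table$alpha)
  best <- cv_table[ord[1L], ]

  final <- suppressWarnings(elastic_net_path(
    Xs_full, y01, best$alpha, lam_grids[[best$a_idx]], family = family))
  beta <- final$beta[, best$l_idx]
  intercept <- final$intercept[best$l_idx]
  selected <- colnames(X)[beta != 0]

  oof_sel <- vapply(seq_len(cv$repeats),
                    function(r) oof[[r]][[best$a_idx]][, best$l_idx],
                    numeric(n))
  structure(list(dataset_name = nm, alpha = best$alpha, lambda = best$lambda,
                 cv_metric = best$mean_metric, intercept = intercept,
                 coefficients = stats::setNames(beta, colnames(X)),
                 selected_features = selected,
                 oof_scores = oof_sel, oof_mean = rowMeans(oof_sel),
                 cv_metric_table = cv_table[order(cv_table$alpha,
                                                  -cv_table$lambda),
                                            c("alpha", "lambda", "mean_metric",
                                              "sd_metric")],
                 std = st_full, levels = levels(y), y = y, cv = cv,
                 grid = grid),
            class = "omx_panel")
}

#' @export
print.omx_panel <- function(x, ...) {
  cat(sprintf("Elastic-net biomarker panel '%s'\n", x$dataset_name))
  cat(sprintf("  alpha = %.2f, lambda = %.4g (mean CV %s = %.3f)\n", x$alpha,
              x$lambda, x$cv$metric, x$cv_metric))
  cat(sprintf("  %d of %d features selected\n", length(x$selected_features),
              length(x$coefficients)))
  invisible(x)
}

#' @export
coef.omx_panel <- function(object, all = FALSE, ...) {
  if (all) object$coefficients
  else object$coefficients[object$coefficients != 0]
}

#' @export
summary.omx_panel <- function(object, ...) {
  print(object)
  cat("\nTop selected features by |standardized coefficient|:\n")
  print(utils::head(importance(object), 10), row.names = FALSE)
  invisible(object)
}

#' Predict panel scores for new samples
#' @param object an `omx_panel`.
#' @param newdata matrix with the panel's feature columns (raw scale; the
#'   stored full-data standardization is applied).
#' @param ... unused.
#' @return predicted probabilities in \[0, 1\].
#' @export
predict.omx_panel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  Xs <- std_apply(X, object$std)
  fam <- if (object$cv$family == "binomial") "binomial" else "gaussian"
  enet_predict_score(object$intercept, object$coefficients, Xs, fam)
}

#' @export
plot.omx_panel <- function(x, top = 20L, ...) {
  imp <- utils::head(importance(x), top)
  if (!nrow(imp)) { graphics::plot.new(); return(invisible(x)) }
  imp <- imp[nrow(imp):1, ]
  op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(imp$coefficient, seq_len(nrow(imp)), pch = 16, yaxt = "n",
                 xlab = "standardized coefficient", ylab = "",
                 main = sprintf("Panel importance: %s", x$dataset_name), ...)
  graphics::abline(v = 0, lty = 2, col = "grey60")
  graphics::axis(2, at = seq_len(nrow(imp)), labels = imp$feature, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Biomarker importance ranking
#'
#' Nonzero-coefficient features ranked by decreasing absolute standardized
#' coefficient, signed values retained, ties broken alphabetically. An empty
#' panel yields an empty table.
#'
#' @param model an `omx_panel`.
#' @return data frame: feature, coefficient, rank.
#' @export
importance <- function(model) {
  cf <- model$coefficients[model$coefficients != 0]
  if (!length(cf))
    return(data.frame(feature = character(), coefficient = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  ord <- order(-abs(cf), names(cf))
  data.frame(feature = names(cf)[ord], coefficient = unname(cf[ord]),
             rank = seq_along(cf), stringsAsFactors = FALSE)
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds are the unique scores in descending order plus a sentinel;
#' tied scores are grouped into one step. The AUC is the trapezoidal area,
#' which equals the rank concordance statistic `U / (n1 * n0)` with ties
#' counted one half.
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels 0/1 vector, logical, or two-level factor (second level =
#'   positive).
#' @return an `omx_roc`: thresholds, fpr, tpr, auc.
#' @export
roc_curve <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L) stopf("labels must have exactly 2 levels")
    labels <- as.numeric(labels) - 1
  }
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(l == 1, grp, sum)
  fp_steps <- tapply(l == 0, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / n1)
  fpr <- c(0, cumsum(fp_steps) / n0)
  thresholds <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = unname(fpr),
                 tpr = unname(tpr), auc = auc), class = "omx_roc")
}

#' @export
print.omx_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Late-integration ensemble of per-dataset biomarker panels
#'
#' Fits one elastic-net panel per omics dataset ([fit_panel()], all on the
#' same seeded folds) and aggregates them by averaging the predicted
#' probabilities: the ensemble's out-of-fold score for a sample is the
#' arithmetic mean of the member panels' out-of-fold scores. Multi-level
#' responses are dichotomized as `level` vs the reference level; other
#' samples are dropped for this stage.
#'
#' @param study an `omx_study`.
#' @param grid an [hyper_grid()].
#' @param cv an [cv_config()].
#' @param level response level to contrast against the reference (default:
#'   first non-reference level).
#' @return an `omx_ensemble`: `models` (list of `omx_panel`),
#'   `ensemble_oof`, `labels`, `rocs` (per panel + `"ensemble"`),
#'   `intersections`.
#' @export
fit_ensemble <- function(study, grid = hyper_grid(), cv = cv_config(),
                         level = NULL) {
  stopifnot(inherits(study, "omx_study"))
  ref <- study$response$reference_level
  if (is.null(level)) level <- setdiff(study$response$levels, ref)[1L]
  y_full <- study_response_factor(study)
  keep <- y_full %in% c(ref, level)
  y <- factor(as.character(y_full[keep]), levels = c(ref, level))
  models <- lapply(study$datasets, function(d) {
    sub <- d
    sub$values <- d$values[keep, , drop = FALSE]
    fit_panel(sub, y, grid = grid, cv = cv)
  })
  ensemble_from_models(models, y)
}

#' Assemble an ensemble from already-fitted panels
#' @param models list of `omx_panel` sharing sample order and labels.
#' @param labels binary response factor.
#' @export
ensemble_from_models <- function(models, labels) {
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  for (m in models) {
    if (length(m$oof_mean) != n) stopf("sample-order mismatch across panels")
    if (!identical(m$levels, levels(labels)))
      stopf("panel '%s' was fit on different labels", m$dataset_name)
  }
  oof_members <- vapply(models, function(m) m$oof_mean, numeric(n))
  ensemble_oof <- rowMeans(oof_members)
  rocs <- c(lapply(models, function(m) roc_curve(m$oof_mean, labels)),
            list(ensemble = roc_curve(ensemble_oof, labels)))
  names(rocs) <- c(vapply(models, function(m) m$dataset_name, character(1)),
                   "ensemble")
  inter <- if (length(models) >= 2L) panel_intersections(models) else NULL
  structure(list(models = models, ensemble_oof = ensemble_oof,
                 member_oof = oof_members, labels = labels, rocs = rocs,
                 intersections = inter),
            class = "omx_ensemble")
}

#' @export
print.omx_ensemble <- function(x, ...) {
  cat(sprintf("Late-integration ensemble of %d panel(s)\n", length(x$models)))
  for (nm in names(x$rocs))
    cat(sprintf("  %-12s oof AUC = %.3f\n", nm, x$rocs[[nm]]$auc))
  invisible(x)
}

#' @export
summary.omx_ensemble <- function(object, ...) {
  print(object)
  cat("\nPanel sizes:\n")
  for (m in object$models)
    cat(sprintf("  %s: %d features\n", m$dataset_name,
                length(m$selected_features)))
  if (!is.null(object$intersections)) {
    cat("\nPanel intersections:\n")
    print(object$intersections, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.omx_ensemble <- function(object, ...) {
  lapply(object$models, coef)
}

#' Predict ensemble probabilities for new samples
#' @param object an `omx_ensemble`.
#' @param newdata named list of matrices, one per member dataset.
#' @param ... unused.
#' @export
predict.omx_ensemble <- function(object, newdata, ...) {
  scores <- vapply(object$models, function(m)
    predict(m, newdata[[m$dataset_name]]),
    numeric(nrow(newdata[[object$models[[1L]]$dataset_name]])))
  rowMeans(scores)
}

#' @export
plot.omx_ensemble <- function(x, ...) {
  cols <- c(grDevices::hcl.colors(length(x$models), "Dark 2"), "black")
  graphics::plot(0:1, 0:1, type = "n", xlab = "False positive rate",
                 ylab = "True positive rate", main = "ROC (out-of-fold)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey70")
  for (i in seq_along(x$rocs)) {
    r <- x$rocs[[i]]
    graphics::lines(r$fpr, r$tpr, col = cols[i],
                    lwd = if (names(x$rocs)[i] == "ensemble") 2.5 else 1.5)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", names(x$rocs),
                                    vapply(x$rocs, `[[`, numeric(1), "auc")),
                   col = cols, lwd = 2, cex = 0.8, bty = "n")
  invisible(x)
}

#' Exact-subset intersection counts of biomarker panels
#'
#' For every non-empty subset S of panels, counts the features (compared by
#' name across datasets) selected by exactly the panels in S, in decreasing
#' count order (UpSet-style tabulation).
#'
#' @param models list of >= 2 `omx_panel` objects.
#' @return data frame: subset (names joined by "+"), n_panels, count.
#' @export
panel_intersections <- function(models) {
  if (length(models) < 2L) stopf("need at least 2 panels")
  panels <- lapply(models, function(m) m$selected_features)
  names(panels) <- vapply(models, function(m) m$dataset_name, character(1))
  all_feats <- unique(unlist(panels))
  membership <- vapply(panels, function(p) all_feats %in% p,
                       logical(length(all_feats)))
  if (length(all_feats) == 1L) membership <- matrix(membership, nrow = 1L,
                                                    dimnames = list(NULL, names(panels)))
  J <- length(panels)
  subsets <- lapply(seq_len(2^J - 1L), function(code)
    which(bitwAnd(code, 2^(seq_len(J) - 1L)) > 0))
  rows <- lapply(subsets, function(s) {
    in_exact <- if (length(all_feats)) {
      rowSums(membership[, s, drop = FALSE]) == length(s) &
        rowSums(membership[, -s, drop = FALSE]) == 0
    } else logical(0)
    data.frame(subset = paste(names(panels)[s], collapse = "+"),
               n_panels = length(s), count = sum(in_exact),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$count, out$subset), , drop = FALSE]
}

#' Project samples onto the selected-biomarker space
#'
#' Restricts each dataset to its selected features, runs PCA per dataset
#' (and on the combined selected-feature matrix, since samples align across
#' datasets), and builds a standardized expression matrix with rows and
#' columns ordered by average-linkage hierarchical clustering on Euclidean
#' distance.
#'
#' @param study an `omx_study`.
#' @param union_features character vector of selected feature names; every
#'   feature must be present in one of the study's datasets.
#' @param k components for the combined PCA (capped by dimensions).
#' @return list: `pca` (combined `omx_pca`), `per_dataset` (PCA per dataset
#'   with >= 1 selected feature), `heatmap` (standardized matrix, clustered
#'   order), `row_order`, `col_order`.
#' @export
panel_projection <- function(study, union_features, k = 2L) {
  if (!length(union_features)) stopf("union_features is empty")
  found <- unlist(lapply(study$datasets, function(d)
    intersect(union_features, d$feature_ids)))
  missing <- setdiff(union_features, found)
  if (length(missing))
    stopf("feature(s) absent from every dataset: %s",
          paste(missing, collapse = ", "))
  mats <- lapply(study$datasets, function(d) {
    sel <- intersect(d$feature_ids, union_features)
    d$values[, sel, drop = FALSE]
  })
  combined <- do.call(cbind, mats[vapply(mats, ncol, integer(1)) > 0])
  kk <- min(k, nrow(combined) - 1L, ncol(combined))
  pca <- run_pca(combined, k = kk)
  per_dataset <- lapply(study$datasets, function(d) {
    sel <- intersect(d$feature_ids, union_features)
    if (!length(sel)) return(NULL)
    kd <- min(k, nrow(d$values) - 1L, length(sel))
    run_pca(d$values[, sel, drop = FALSE], k = kd)
  })
  z <- scale(combined)
  z[, attr(z, "scaled:scale") == 0] <- 0
  row_order <- if (nrow(z) > 2L)
    stats::hclust(stats::dist(z), method = "average")$order else seq_len(nrow(z))
  col_order <- if (ncol(z) > 2L)
    stats::hclust(stats::dist(t(z)), method = "average")$order else seq_len(ncol(z))
  list(pca = pca, per_dataset = Filter(Negate(is.null), per_dataset),
       heatmap = z[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order)
}

#' Pathway-biomarker network of the ensemble panel
#'
#' Nodes are the ensemble-panel biomarkers plus every gene set with
#' `adj_p < fdr` in the enrichment result. A biomarker-pathway edge is drawn
#' iff the biomarker is among the set's overlap genes; a biomarker-biomarker
#' edge iff the absolute Pearson correlation of the pair's standardized
#' values across all samples reaches `r_cutoff` (cross-dataset pairs
#' included, since samples align). Zero-variance biomarkers keep their node
#' but enter no correlation edge.
#'
#' @param study an `omx_study`.
#' @param panel_features character vector of ensemble-panel feature names.
#' @param enrichment an `omx_enrichment` (or NULL for correlation edges
#'   only).
#' @param fdr significance threshold on enrichment adjusted p-values.
#' @param r_cutoff absolute Pearson correlation threshold in (0, 1\].
#' @return list: `nodes` (name, type), `edges` (source, target, edge_type,
#'   weight).
#' @export
panel_network <- function(study, panel_features, enrichment = NULL,
                          fdr = 0.05, r_cutoff = 0.7) {
  if (r_cutoff <= 0 || r_cutoff > 1) stopf("r_cutoff must lie in (0, 1]")
  if (fdr <= 0 || fdr >= 1) stopf("fdr must lie in (0, 1)")
  mats <- lapply(study$datasets, function(d) {
    sel <- intersect(d$feature_ids, panel_features)
    d$values[, sel, drop = FALSE]
  })
  x <- do.call(cbind, mats)
  feats <- colnames(x)
  sds <- apply(x, 2L, stats::sd)
  edges <- list()
  usable <- which(sds > 0)
  if (length(usable) >= 2L) {
    cm <- stats::cor(x[, usable, drop = FALSE])
    idx <- which(abs(cm) >= r_cutoff & upper.tri(cm), arr.ind = TRUE)
    if (nrow(idx))
      edges[[length(edges) + 1L]] <- data.frame(
        source = rownames(cm)[idx[, 1L]], target = colnames(cm)[idx[, 2L]],
        edge_type = "correlation", weight = cm[idx],
        stringsAsFactors = FALSE)
  }
  sig_sets <- character()
  if (!is.null(enrichment)) {
    sig <- enrichment[enrichment$adj_p < fdr, , drop = FALSE]
    sig_sets <- sig$set
    for (i in seq_len(nrow(sig))) {
      genes <- strsplit(sig$genes[i], ";", fixed = TRUE)[[1L]]
      hit <- feats[toupper(feats) %in% genes]
      if (length(hit))
        edges[[length(edges) + 1L]] <- data.frame(
          source = hit, target = sig$set[i], edge_type = "membership",
          weight = 1, stringsAsFactors = FALSE)
    }
  }
  nodes <- rbind(
    data.frame(name = feats, type = "biomarker", stringsAsFactors = FALSE),
    if (length(sig_sets))
      data.frame(name = sig_sets, type = "pathway", stringsAsFactors = FALSE))
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               edge_type = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
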