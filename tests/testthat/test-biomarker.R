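small_grid <- hyper_grid(alphas = c(0.2, 0.8), n_lambda = 8)
small_cv <- function(seed = 11) cv_config(folds = 3, repeats = 2, seed = seed)

test_that("repeated CV tuning is a pure function of the seed", {
  sim <- simulate_study(n = 36, p = 40, q = 4, delta = 1.5, seed = 21)
  d <- sim$study$datasets[[1]]
  y <- study_response_factor(sim$study)
  p1 <- fit_panel(d, y, small_grid, small_cv())
  p2 <- fit_panel(d, y, small_grid, small_cv())
  expect_identical(p1$alpha, p2$alpha)
  expect_identical(p1$lambda, p2$lambda)
  expect_identical(p1$oof_scores, p2$oof_scores)
  expect_identical(p1$coefficients, p2$coefficients)
  p3 <- fit_panel(d, y, small_grid, small_cv(seed = 99))
  expect_false(identical(p1$oof_scores, p3$oof_scores))
})

test_that("stratification constraints are enforced", {
  sim <- simulate_study(n = 20, prop = c(control = 0.8, case = 0.2),
                        p = 15, q = 0, delta = 0, seed = 3)
  y <- study_response_factor(sim$study)
  expect_error(fit_panel(sim$study$datasets[[1]], y, small_grid,
                         cv_config(folds = 5, repeats = 1, seed = 1)),
               "smallest class")
  expect_error(cv_config(folds = 1), "folds")
  expect_error(hyper_grid(alphas = numeric(0)), "non-empty")
})

test_that("standardization hygiene: affine feature rescaling changes nothing", {
  sim <- simulate_study(n = 30, p = 25, q = 3, delta = 1.5, seed = 31)
  d <- sim$study$datasets[[1]]
  y <- study_response_factor(sim$study)
  base <- fit_panel(d, y, small_grid, small_cv())
  d2 <- d
  d2$values[, 1] <- d2$values[, 1] * 250 - 7
  d2$values[, 2] <- d2$values[, 2] / 1000 + 42
  scaled <- fit_panel(d2, y, small_grid, small_cv())
  expect_identical(base$selected_features, scaled$selected_features)
  expect_equal(base$oof_scores, scaled$oof_scores, tolerance = 1e-8)
  expect_equal(base$coefficients, scaled$coefficients, tolerance = 1e-6)
})

test_that("pure noise gives chance-level CV performance", {
  sim <- simulate_study(n = 60, p = 200, q = 0, delta = 0, seed = 41)
  panel <- fit_panel(sim$study$datasets[[1]], study_response_factor(sim$study),
                     hyper_grid(alphas = c(0.1, 0.9), n_lambda = 10),
                     cv_config(folds = 5, repeats = 2, seed = 7))
  expect_gte(panel$cv_metric, 0.35)
  expect_lte(panel$cv_metric, 0.65)
})

test_that("panel importance ranks by absolute coefficient with name ties", {
  p <- stub_panel(c(up = 2, down = -3, none = 0))
  imp <- importance(p)
  expect_identical(imp$feature, c("down", "up"))
  expect_identical(imp$coefficient, c(-3, 2))

  p2 <- stub_panel(c(b = 1, a = -1, c = 0.5))
  expect_identical(importance(p2)$feature, c("a", "b", "c"))

  expect_identical(nrow(importance(stub_panel(c(x = 0)))), 0L)
})

test_that("ensemble averaging and ROC bookkeeping are exact", {
  labels <- factor(rep(c("control", "case"), each = 5),
                   levels = c("control", "case"))
  sep <- c(rep(0.2, 5), rep(0.8, 5))
  m1 <- stub_panel(c(f1 = 1), "d1", oof = rep(c(0.2, 0.8), each = 5))
  m2 <- stub_panel(c(f2 = 1), "d2", oof = rep(c(0.8, 0.2), each = 5))
  ens <- ensemble_from_models(list(m1, m2), labels)
  expect_equal(ens$ensemble_oof, rep(0.5, 10))

  ## identical members: ensemble ROC equals the member ROC
  m3 <- stub_panel(c(f1 = 1), "d1", oof = sep)
  m4 <- stub_panel(c(f1 = 1), "d2", oof = sep)
  ens2 <- ensemble_from_models(list(m3, m4), labels)
  expect_identical(ens2$rocs$ensemble$auc, ens2$rocs$d1$auc)
  expect_equal(ens2$rocs$ensemble$auc, 1)

  m5 <- stub_panel(c(f1 = 1), "d3", oof = sep[1:8])
  expect_error(ensemble_from_models(list(m3, m5), labels), "mismatch")
})

test_that("panel intersections partition the union of panels", {
  a <- stub_panel(c(x = 1, y = 2), "A")
  b <- stub_panel(c(z = 3), "B")
  tab <- panel_intersections(list(a, b))
  expect_equal(tab$count[tab$subset == "A"], 2)
  expect_equal(tab$count[tab$subset == "B"], 1)
  expect_equal(tab$count[tab$subset == "A+B"], 0)

  same <- panel_intersections(list(stub_panel(c(x = 1, y = 1), "A"),
                                   stub_panel(c(x = 2, y = -1), "B")))
  expect_equal(same$count[same$subset == "A+B"], 2)
  expect_true(all(same$count[same$subset != "A+B"] == 0))

  set.seed(9)
  feats <- paste0("f", 1:30)
  ms <- lapply(1:3, function(i) {
    cf <- setNames(rbinom(30, 1, 0.4) * rnorm(30), feats)
    stub_panel(cf, paste0("P", i))
  })
  tab3 <- panel_intersections(ms)
  expect_equal(sum(tab3$count),
               length(unique(unlist(lapply(ms, `[[`, "selected_features")))))
})

test_that("panel projection clusters samples on the selected features", {
  sim <- simulate_study(n = 40, p = c(30, 20), q = c(4, 0), delta = 3,
                        seed = 51)
  st <- sim$study
  proj <- panel_projection(st, sim$truth$planted$ds1)
  expect_s3_class(proj$pca, "omx_pca")
  expect_equal(ncol(proj$heatmap), 4)
  ## planted separation shows up through the association machinery
  assoc <- pc_metadata_association(proj$pca, st$metadata)
  expect_lt(assoc$raw_p["group", 1], 0.01)
  ## determinism of the clustered ordering
  proj2 <- panel_projection(st, sim$truth$planted$ds1)
  expect_identical(proj$row_order, proj2$row_order)
  expect_identical(proj$col_order, proj2$col_order)

  one <- panel_projection(st, sim$truth$planted$ds1[1], k = 3)
  expect_equal(ncol(one$heatmap), 1)
  expect_equal(one$pca$k, 1)

  expect_error(panel_projection(st, "not_a_feature"), "absent")
})

test_that("panel networks respect correlation and membership rules", {
  sim <- simulate_study(n = 30, p = c(10, 10), q = c(0, 0), delta = 0,
                        seed = 61)
  st <- sim$study
  ## duplicate one feature across datasets: r = 1 edge at any cutoff
  st$datasets[[2]]$values[, 1] <- st$datasets[[1]]$values[, 1]
  feats <- c("ds1_f0001", "ds2_f0001", "ds1_f0002")
  net <- panel_network(st, feats, enrichment = NULL, r_cutoff = 1)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1, tolerance = 1e-12)
  expect_identical(sort(c(net$edges$source, net$edges$target)),
                   c("ds1_f0001", "ds2_f0001"))
  expect_equal(nrow(net$nodes), 3)

  ## enrichment membership edges appear only under the FDR gate
  universe <- toupper(paste0("GENE", 1:40))
  coll <- genesets_from_list(list(path1 = universe[1:10],
                                  path2 = universe[30:40]))
  enr <- ora(universe[1:10], universe, coll)
  st2 <- sim$study
  colnames(st2$datasets[[1]]$values) <- universe[1:10]
  st2$datasets[[1]]$feature_ids <- universe[1:10]
  net2 <- panel_network(st2, universe[1:4], enrichment = enr,
                        fdr = 0.05, r_cutoff = 0.999)
  memb <- net2$edges[net2$edges$edge_type == "membership", ]
  expect_equal(nrow(memb), 4)
  expect_true(all(memb$target == "path1"))
  expect_true("path1" %in% net2$nodes$name[net2$nodes$type == "pathway"])

  expect_error(panel_network(st, feats, r_cutoff = 0), "r_cutoff")
})

test_that("late-integration ensemble fits end to end on a small study", {
  sim <- simulate_study(n = 40, p = c(60, 60), q = c(6, 6), delta = 2,
                        seed = 71)
  ens <- fit_ensemble(sim$study, small_grid, small_cv())
  expect_s3_class(ens, "omx_ensemble")
  expect_length(ens$models, 2)
  expect_gte(ens$rocs$ensemble$auc, 0.9)
  expect_true(all(ens$ensemble_oof >= 0 & ens$ensemble_oof <= 1))
  expect_equal(ens$ensemble_oof, rowMeans(ens$member_oof))
  ## predict() on the training matrices yields in-range scores
  pr <- predict(ens, lapply(sim$study$datasets, `[[`, "values"))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(roc_curve(pr, study_response_factor(sim$study))$auc, 0.9)
})

test_that("multi-level responses are dichotomized against the reference", {
  sim <- simulate_study(n = 45, prop = c(ctl = 1/3, mild = 1/3, severe = 1/3),
                        p = 30, q = 3, delta = 2, seed = 81)
  ens <- fit_ensemble(sim$study, small_grid, small_cv(), level = "severe")
  expect_length(ens$labels, 30)  # mild samples dropped
  expect_setequal(levels(ens$labels), c("ctl", "severe"))
})
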