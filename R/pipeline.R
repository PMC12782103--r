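#' Validate a pipeline run configuration
#'
#' Checks the parsed config against the published schema
#' (`inst/schema/config-schema.json`): required blocks, field types and
#' value ranges. Returns the config with defaults filled in; any violation
#' is an error naming the offending field.
#'
#' @param config named list (parsed YAML) or a path to a YAML file.
#' @return validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  req_chr <- function(x, field) {
    if (is.null(x) || !is.character(x) || length(x) != 1L)
      stopf("config field '%s' must be a single string", field)
    x
  }
  if (is.null(config$study_dir) && is.null(config$simulate)) {
    req_chr(config$metadata, "metadata")
    if (is.null(config$datasets) || !length(config$datasets))
      stopf("config field 'datasets' must list at least one dataset")
    for (d in config$datasets) {
      req_chr(d$name, "datasets[].name"); req_chr(d$path, "datasets[].path")
    }
    req_chr(config$response$name, "response.name")
    req_chr(config$response$reference, "response.reference")
  }
  req_chr(config$out_dir, "out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed)) stopf("config field 'seed' must be an integer")
  defaults <- list(
    pca = list(k = 2L, scale = FALSE, fdr = TRUE),
    de = list(method = "auto", fdr = 0.05),
    enrich = list(fdr = 0.05, collections = list()),
    biomarker = list(folds = 5L, repeats = 5L, alphas = seq(0, 1, 0.1),
                     n_lambda = 20L, metric = "auc",
                     family = "gaussian_on_indicator", r_cutoff = 0.7,
                     network_fdr = 0.05),
    metadata_stats = list(mode = "regression"),
    report = list(title = "Multi-omics analysis report"),
    figures = TRUE
  )
  for (nm in names(defaults)) {
    if (nm == "figures") {
      if (is.null(config$figures)) config$figures <- defaults$figures
      next
    }
    block <- if (is.null(config[[nm]])) list() else config[[nm]]
    miss <- setdiff(names(defaults[[nm]]), names(block))
    block[miss] <- defaults[[nm]][miss]
    config[[nm]] <- block
  }
  if (!config$pca$k %in% 1:5) stopf("config field 'pca.k' must be 1..5")
  if (!config$de$method %in% c("auto", "ols", "moderated", "voom"))
    stopf("config field 'de.method' must be auto/ols/moderated/voom")
  for (f in c("de.fdr" = config$de$fdr, "enrich.fdr" = config$enrich$fdr))
    if (!is.numeric(f) || f <= 0 || f >= 1)
      stopf("FDR thresholds must lie in (0, 1)")
  config
}

pipeline_log <- function(out_dir, stage, params, status) {
  line <- jsonlite::toJSON(list(stage = stage, params_hash = object_md5(params),
                                status = status,
                                time = format(Sys.time(), tz = "UTC")),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run_log.jsonl"),
      append = TRUE)
}

pipeline_study <- function(config) {
  if (!is.null(config$study_dir)) return(read_study(config$study_dir))
  lm <- load_metadata(config$metadata, config$response$name,
                      config$response$reference)
  datasets <- lapply(config$datasets, function(d) load_omics(d$path, d$name))
  assemble_study(lm$metadata, lm$response, datasets)
}

## open a png device if the build supports it; returns TRUE when plotting
open_fig <- function(path, enabled, width = 900, height = 700) {
  if (!enabled || !capabilities("png")) return(FALSE)
  grDevices::png(path, width = width, height = height)
  TRUE
}

de_for_dataset <- function(dataset, y, config) {
  method <- config$de$method
  if (method == "auto") method <- if (dataset$is_count) "voom" else "moderated"
  contrast <- config$de$contrast
  if (is.null(contrast)) {
    lev <- levels(y)
    contrast <- c(lev[2L], lev[1L])
  }
  fn <- switch(method, ols = de_ols, moderated = de_moderated, voom = de_voom)
  fn(dataset, y, unlist(contrast), fdr = config$de$fdr)
}

#' Run pipeline stages from a configuration
#'
#' Executes one stage (or `"all"`, in dependency order) of the analysis
#' pipeline described by a YAML config; outputs are written under
#' `out_dir/<stage>/` and a machine-readable JSON-lines run log is appended
#' at `out_dir/run_log.jsonl`. Stages never mutate another stage's outputs,
#' so re-running a single stage is safe. With a fixed config and seed, two
#' runs produce identical output trees (the log's timestamps aside).
#'
#' @param config list or YAML path (see [validate_config()]).
#' @param stage one of validate, simulate, metadata, eda, de, enrich,
#'   biomarker, report, all.
#' @param out_dir optional override of the config's output directory.
#' @param seed optional override of the config's seed.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, stage = "all", out_dir = NULL, seed = NULL) {
  stages_all <- c("simulate", "validate", "metadata", "eda", "de", "enrich",
                  "biomarker", "report")
  stage <- match.arg(stage, c(stages_all, "all"))
  config <- validate_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  todo <- if (stage == "all") {
    if (is.null(config$simulate)) setdiff(stages_all, "simulate") else stages_all
  } else stage
  ## 'all' with a simulate block: later stages read the simulated study
  for (st in todo) {
    sdir <- file.path(out, st)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({
      run_stage_impl(st, config, sdir)
      TRUE
    }, error = function(e) {
      pipeline_log(out, st, config[[st]], paste("error:", conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    if (ok) pipeline_log(out, st, config[[st]], "ok")
    if (st == "simulate") config$study_dir <- file.path(sdir, "study")
  }
  invisible(out)
}

run_stage_impl <- function(st, config, sdir) {
  figs <- isTRUE(config$figures)
  if (st == "simulate") {
    sim <- do.call(simulate_study, c(config$simulate, list(seed = config$seed)))
    write_study(sim$study, file.path(sdir, "study"))
    jsonlite::write_json(sim$truth, file.path(sdir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible())
  }
  study <- pipeline_study(config)
  y <- study_response_factor(study)

  if (st == "validate") {
    info <- list(n = nrow(study$metadata$table),
                 datasets = lapply(study$datasets, function(d)
                   list(name = d$name, p = ncol(d$values),
                        is_count = d$is_count)),
                 response = unclass(study$response),
                 var_kind = as.list(study$metadata$var_kind))
    jsonlite::write_json(info, file.path(sdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  } else if (st == "metadata") {
    t1 <- build_table1(study, mode = config$metadata_stats$mode)
    utils::write.csv(as.data.frame(t1), file.path(sdir, "table1.csv"),
                     row.names = FALSE)
    writeLines(table1_markdown(t1), file.path(sdir, "table1.md"))

  } else if (st == "eda") {
    for (d in study$datasets) {
      k <- min(config$pca$k, nrow(d$values) - 1L, ncol(d$values))
      pca <- run_pca(d, k = k, scale = isTRUE(config$pca$scale))
      pref <- file.path(sdir, d$name)
      utils::write.csv(pca$scores, paste0(pref, "_scores.csv"), row.names = FALSE)
      utils::write.csv(pca$loadings, paste0(pref, "_loadings.csv"))
      utils::write.csv(data.frame(component = seq_len(k),
                                  var_explained = pca$var_explained),
                       paste0(pref, "_var_explained.csv"), row.names = FALSE)
      assoc <- pc_metadata_association(pca, study$metadata,
                                       apply_fdr = isTRUE(config$pca$fdr))
      utils::write.csv(assoc$raw_p, paste0(pref, "_assoc_raw_p.csv"))
      if (!is.null(assoc$adj_p))
        utils::write.csv(assoc$adj_p, paste0(pref, "_assoc_adj_p.csv"))
      utils::write.csv(score_plot_data(pca, study$response, study$metadata),
                       paste0(pref, "_score_plot.csv"), row.names = FALSE)
      if (open_fig(paste0(pref, "_assoc_heatmap.png"), figs)) {
        plot(assoc); grDevices::dev.off()
      }
    }

  } else if (st == "de") {
    for (d in study$datasets) {
      de <- de_for_dataset(d, y, config)
      utils::write.csv(as.data.frame(de)[, c("feature", "log2fc", "t", "df",
                                             "p", "adj_p", "significant")],
                       file.path(sdir, paste0(d$name, "_de.csv")),
                       row.names = FALSE)
      utils::write.csv(volcano_table(de, config$de$fdr),
                       file.path(sdir, paste0(d$name, "_volcano.csv")),
                       row.names = FALSE)
      if (open_fig(file.path(sdir, paste0(d$name, "_volcano.png")), figs)) {
        plot(de, fdr = config$de$fdr); grDevices::dev.off()
      }
    }

  } else if (st == "enrich") {
    colls <- lapply(config$enrich$collections, function(cc) {
      if (!file.exists(cc$path)) stopf("GMT path not found: %s", cc$path)
      read_gmt(cc$path, name = cc$name)
    })
    if (!length(colls)) {
      writeLines("no gene-set collections configured",
                 file.path(sdir, "SKIPPED.txt"))
      return(invisible())
    }
    for (d in study$datasets) {
      if (!detect_gene_symbols(d$feature_ids)) next
      de <- de_for_dataset(d, y, config)
      sig <- de$feature[de$significant]
      if (!length(sig)) next
      universe <- de$feature
      for (cc in colls) {
        enr <- ora(sig, universe, cc)
        utils::write.csv(as.data.frame(enr),
                         file.path(sdir, sprintf("%s_%s_ora.csv", d$name,
                                                 cc$name)),
                         row.names = FALSE)
      }
      if (!is.null(config$enrich$pert_up) && !is.null(config$enrich$pert_down)) {
        up <- de$feature[de$significant & de$log2fc > 0]
        down <- de$feature[de$significant & de$log2fc < 0]
        if (length(up) || length(down)) {
          rev <- drug_reversal(up, down,
                               read_gmt(config$enrich$pert_up, "pert_up"),
                               read_gmt(config$enrich$pert_down, "pert_down"),
                               universe)
          utils::write.csv(rev, file.path(sdir, paste0(d$name, "_reversal.csv")),
                           row.names = FALSE)
        }
      }
    }

  } else if (st == "biomarker") {
    bm <- config$biomarker
    grid <- hyper_grid(alphas = unlist(bm$alphas), n_lambda = bm$n_lambda)
    cvc <- cv_config(folds = bm$folds, repeats = bm$repeats,
                     seed = config$seed, metric = bm$metric,
                     family = bm$family)
    ens <- fit_ensemble(study, grid = grid, cv = cvc, level = bm$level)
    for (m in ens$models) {
      utils::write.csv(importance(m),
                       file.path(sdir, paste0(m$dataset_name, "_panel.csv")),
                       row.names = FALSE)
      utils::write.csv(m$cv_metric_table,
                       file.path(sdir, paste0(m$dataset_name, "_cv_grid.csv")),
                       row.names = FALSE)
    }
    oof <- data.frame(sample = seq_along(ens$ensemble_oof),
                      label = as.character(ens$labels), ens$member_oof,
                      ensemble = ens$ensemble_oof, check.names = FALSE)
    utils::write.csv(oof, file.path(sdir, "oof_scores.csv"), row.names = FALSE)
    roc_pts <- do.call(rbind, lapply(names(ens$rocs), function(nm)
      data.frame(model = nm, fpr = ens$rocs[[nm]]$fpr,
                 tpr = ens$rocs[[nm]]$tpr, auc = ens$rocs[[nm]]$auc)))
    utils::write.csv(roc_pts, file.path(sdir, "roc_points.csv"),
                     row.names = FALSE)
    if (!is.null(ens$intersections))
      utils::write.csv(ens$intersections, file.path(sdir, "intersections.csv"),
                       row.names = FALSE)
    union_feats <- unique(unlist(lapply(ens$models,
                                        function(m) m$selected_features)))
    if (length(union_feats)) {
      keep <- study_response_factor(study) %in% ens$models[[1L]]$levels
      sub <- study
      sub$metadata$table <- sub$metadata$table[keep, , drop = FALSE]
      sub$datasets <- lapply(sub$datasets, function(d) {
        d$values <- d$values[keep, , drop = FALSE]; d
      })
      net <- panel_network(sub, union_feats, enrichment = NULL,
                           r_cutoff = bm$r_cutoff, fdr = bm$network_fdr)
      utils::write.csv(net$edges, file.path(sdir, "network_edges.csv"),
                       row.names = FALSE)
      proj <- panel_projection(sub, union_feats)
      utils::write.csv(proj$pca$scores, file.path(sdir, "panel_pca_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(proj$heatmap, file.path(sdir, "panel_heatmap.csv"))
    }
    if (open_fig(file.path(sdir, "roc.png"), figs)) {
      plot(ens); grDevices::dev.off()
    }

  } else if (st == "report") {
    rep <- report_new(config$report$title, config = config, seed = config$seed)
    t1_md <- file.path(config$out_dir, "metadata", "table1.md")
    if (file.exists(t1_md)) {
      rep <- add_element(rep, "heading", "Cohort characteristics")
      rep <- add_element(rep, "text", paste(readLines(t1_md), collapse = "\n"))
    }
    figs_found <- list.files(config$out_dir, pattern = "\\.png$",
                             recursive = TRUE, full.names = TRUE)
    if (length(figs_found)) {
      rep <- add_element(rep, "heading", "Figures")
      for (f in sort(figs_found)) rep <- add_element(rep, "figure", f)
    }
    render_report(rep, file.path(sdir, "report.md"))
  }
  invisible()
}
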