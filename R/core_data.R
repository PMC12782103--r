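#' Classify metadata columns as numerical or categorical
#'
#' A column is categorical if it is non-numeric, or numeric with at most
#' `max_levels` distinct values (this captures 0/1-coded clinical flags);
#' otherwise it is numerical.
#'
#' @param df data frame of metadata columns.
#' @param max_levels distinct-value threshold below which a numeric column is
#'   treated as categorical (default 5).
#' @return named character vector, one of `"numerical"` / `"categorical"` per
#'   column.
#' @export
classify_variables <- function(df, max_levels = 5L) {
  vapply(df, function(col) {
    if (!is.numeric(col)) return("categorical")
    if (length(unique(col)) <= max_levels) "categorical" else "numerical"
  }, character(1))
}

#' Load a metadata table and its response specification
#'
#' Reads a delimited text file (delimiter sniffed from comma/tab/semicolon),
#' classifies every column as numerical or categorical, and coerces the
#' response column to a factor with the reference level first.
#'
#' Missing values anywhere in the table are a hard error: no imputation is
#' performed because silent imputation corrupts downstream cross-validation.
#'
#' @param path path to a delimited text file with a header row.
#' @param response_name name of the categorical response column.
#' @param reference_level reference category of the response.
#' @param max_levels see [classify_variables()].
#' @return list with elements `metadata` (an `omx_metadata`) and `response`
#'   (an `omx_response` with fields `name`, `reference_level`, `levels`).
#' @export
load_metadata <- function(path, response_name, reference_level, max_levels = 5L) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(df) == 0L) stopf("metadata table is empty: %s", path)
  metadata_from_df(df, response_name, reference_level, max_levels)
}

#' Build a metadata table from an in-memory data frame
#'
#' Same validation as [load_metadata()] without file I/O.
#' @inheritParams load_metadata
#' @param df data frame, samples in rows.
#' @export
metadata_from_df <- function(df, response_name, reference_level, max_levels = 5L) {
  if (!response_name %in% names(df))
    stopf("response column '%s' not found in metadata", response_name)
  na_cells <- which(vapply(df, anyNA, logical(1)))
  if (length(na_cells))
    stopf("metadata contains missing values in column(s): %s",
          paste(names(df)[na_cells], collapse = ", "))
  resp_raw <- as.character(df[[response_name]])
  lev <- unique(resp_raw)
  if (!reference_level %in% lev)
    stopf("reference level '%s' not among observed response values (%s)",
          reference_level, paste(lev, collapse = ", "))
  if (length(lev) < 2L)
    stopf("response '%s' has a single level; need at least 2", response_name)
  levels_ordered <- c(reference_level, sort(setdiff(lev, reference_level)))
  df[[response_name]] <- factor(resp_raw, levels = levels_ordered)

  ## a leading non-numeric unique column is treated as sample ids
  sample_ids <- NULL
  first <- df[[1L]]
  if (names(df)[1L] != response_name && !is.numeric(first) &&
      !anyDuplicated(first)) {
    sample_ids <- as.character(first)
    df <- df[, -1L, drop = FALSE]
  }

  var_kind <- classify_variables(df, max_levels)
  var_kind[response_name] <- "categorical"
  md <- structure(list(table = df, sample_ids = sample_ids, var_kind = var_kind),
                  class = "omx_metadata")
  resp <- structure(list(name = response_name, reference_level = reference_level,
                         levels = levels_ordered), class = "omx_response")
  list(metadata = md, response = resp)
}

#' Load an omics matrix (samples x features)
#'
#' Header row gives feature names; every non-header cell must parse as a
#' number (missing or non-numeric cells are a hard error naming the cell).
#' A leading non-numeric unique column, if present, is consumed as sample ids.
#'
#' @param path delimited text file.
#' @param name dataset label.
#' @return an `omx_matrix`: list with `name`, `values` (n x p numeric matrix),
#'   `feature_ids`, `sample_ids` (or NULL), and `is_count` (TRUE iff all
#'   values are non-negative integers, which makes the dataset eligible for
#'   the count-based precision-weight pipeline).
#' @export
load_omics <- function(path, name) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) == 0L) stopf("omics table '%s' is empty", name)
  sample_ids <- NULL
  first_num <- suppressWarnings(as.numeric(df[[1L]]))
  if (any(is.na(first_num)) && !anyDuplicated(df[[1L]])) {
    sample_ids <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  omics_from_df(df, name, sample_ids = sample_ids)
}

#' Build an omics matrix from an in-memory data frame or matrix
#' @inheritParams load_omics
#' @param df data frame or matrix of values, samples in rows.
#' @param sample_ids optional sample identifiers.
#' @export
omics_from_df <- function(df, name, sample_ids = NULL) {
  if (is.matrix(df)) df <- as.data.frame(df, stringsAsFactors = FALSE,
                                         optional = TRUE)
  feature_ids <- colnames(df)
  if (is.null(feature_ids)) stopf("omics table '%s' lacks feature names", name)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stopf("duplicate feature names in dataset '%s': %s", name,
          paste(unique(dup), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(NULL, feature_ids))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num))
      if (length(bad))
        stopf("dataset '%s': non-numeric value '%s' at row %d, column '%s'",
              name, col[bad[1L]], bad[1L], feature_ids[j])
      vals[, j] <- num
    } else {
      if (anyNA(col))
        stopf("dataset '%s': missing value at row %d, column '%s'",
              name, which(is.na(col))[1L], feature_ids[j])
      vals[, j] <- as.numeric(col)
    }
  }
  is_count <- all(vals >= 0) && all(vals == floor(vals))
  structure(list(name = name, values = vals, feature_ids = feature_ids,
                 sample_ids = sample_ids, is_count = is_count),
            class = "omx_matrix")
}

#' Assemble metadata and omics datasets into an aligned study
#'
#' Alignment is positional: every dataset must have exactly as many rows as
#' the metadata, in the same sample order. When sample-id columns were
#' detected in both files they are used as a cross-check: the first
#' positionally mismatching id is reported as an error.
#'
#' @param metadata an `omx_metadata` from [load_metadata()].
#' @param response an `omx_response`.
#' @param datasets list of `omx_matrix` objects.
#' @return an `omx_study`.
#' @export
assemble_study <- function(metadata, response, datasets) {
  stopifnot(inherits(metadata, "omx_metadata"), inherits(response, "omx_response"))
  if (length(datasets) < 1L) stopf("at least one omics dataset is required")
  if (inherits(datasets, "omx_matrix")) datasets <- list(datasets)
  n <- nrow(metadata$table)
  nms <- vapply(datasets, function(d) d$name, character(1))
  names(datasets) <- nms
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (!inherits(d, "omx_matrix")) stopf("dataset %d is not an omx_matrix", i)
    if (nrow(d$values) != n)
      stopf("dataset %d ('%s') has %d rows but metadata has %d samples",
            i, d$name, nrow(d$values), n)
    if (!is.null(metadata$sample_ids) && !is.null(d$sample_ids)) {
      mism <- which(metadata$sample_ids != d$sample_ids)
      if (length(mism))
        stopf("dataset '%s': sample id mismatch at position %d ('%s' vs '%s')",
              d$name, mism[1L], metadata$sample_ids[mism[1L]],
              d$sample_ids[mism[1L]])
    }
  }
  structure(list(metadata = metadata, datasets = datasets, response = response),
            class = "omx_study")
}

#' @export
print.omx_study <- function(x, ...) {
  n <- nrow(x$metadata$table)
  cat(sprintf("Multi-omics study: %d samples, %d dataset(s)\n", n,
              length(x$datasets)))
  for (d in x$datasets)
    cat(sprintf("  %s: %d features%s\n", d$name, ncol(d$values),
                if (d$is_count) " (counts)" else ""))
  cat(sprintf("Response: %s (reference '%s'; levels: %s)\n", x$response$name,
              x$response$reference_level, paste(x$response$levels, collapse = ", ")))
  kinds <- table(x$metadata$var_kind)
  cat(sprintf("Metadata: %d variables (%s)\n", length(x$metadata$var_kind),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", ")))
  invisible(x)
}

#' Response factor aligned to the study rows
#' @param study an `omx_study`.
#' @return factor with the reference level first.
#' @export
study_response_factor <- function(study) {
  study$metadata$table[[study$response$name]]
}

#' Serialize a study to a directory of canonical CSVs plus a JSON manifest
#'
#' @param study an `omx_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- study$metadata$table
  if (!is.null(study$metadata$sample_ids))
    md <- cbind(sample_id = study$metadata$sample_ids, md)
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  ## 17 significant digits so numeric values round-trip bit-exactly
  for (d in study$datasets) {
    df <- as.data.frame(d$values)
    df[] <- lapply(df, function(col) sprintf("%.17g", col))
    utils::write.csv(df, file.path(dir, paste0(d$name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    datasets = unname(vapply(study$datasets, function(d) d$name, character(1))),
    response = unclass(study$response),
    n = nrow(md),
    p = lapply(study$datasets, function(d) ncol(d$values)),
    var_kind = as.list(study$metadata$var_kind)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a study previously written by [write_study()]
#' @param dir study directory containing `manifest.json`.
#' @return an `omx_study`.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lm <- load_metadata(file.path(dir, "metadata.csv"),
                      manifest$response$name, manifest$response$reference_level)
  datasets <- lapply(manifest$datasets, function(nm)
    load_omics(file.path(dir, paste0(nm, ".csv")), nm))
  assemble_study(lm$metadata, lm$response, datasets)
}
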