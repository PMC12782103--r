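#' Read a gene-set collection from a GMT file
#'
#' One set per tab-delimited line: set name, description, then members.
#' Member symbols are upper-cased and deduplicated within each set.
#'
#' @param path GMT file.
#' @param name collection label (defaults to the file name).
#' @return an `omx_genesets`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stopf("GMT file '%s', line %d: expected >= 3 tab-separated fields, got %d",
            path, i, length(fields))
    nms[i] <- fields[1L]
    sets[[i]] <- unique(toupper(fields[-(1:2)]))
  }
  names(sets) <- nms
  genesets_from_list(sets, name)
}

#' Build a gene-set collection from a named list
#' @param sets named list of character vectors (gene symbols).
#' @param name collection label.
#' @export
genesets_from_list <- function(sets, name = "collection") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("set names must be present and unique")
  sets <- lapply(sets, function(s) unique(toupper(s)))
  structure(list(name = name, sets = sets), class = "omx_genesets")
}

#' Write a gene-set collection to GMT
#' @param collection an `omx_genesets`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.omx_genesets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("Gene-set collection '%s': %d sets (sizes %d..%d)\n", x$name,
              length(x$sets), min(sizes), max(sizes)))
  invisible(x)
}

#' Detect whether feature ids look like human gene symbols
#'
#' A dataset qualifies for enrichment when at least `min_frac` of its feature
#' ids match uppercase alphanumeric symbols of length 1-10 beginning with a
#' letter (after upper-casing).
#'
#' @param feature_ids character vector.
#' @param min_frac qualifying fraction (default 0.5).
#' @return logical scalar.
#' @export
detect_gene_symbols <- function(feature_ids, min_frac = 0.5) {
  frac <- mean(grepl("^[A-Z][A-Z0-9]{0,9}$", toupper(feature_ids)))
  frac >= min_frac
}

#' Over-representation analysis with an explicit background universe
#'
#' For each set: `K = |set intersect universe|`, `k = |set intersect query|`,
#' and the p-value is the hypergeometric upper tail `P(X >= k)` with
#' parameters (N = |universe|, K, n_q = |query|). Sets that are empty after
#' intersection with the universe are dropped (their count is reported).
#' The query is intersected with the universe first; BH adjustment is
#' applied across all tested sets.
#'
#' @param query character vector of gene symbols (e.g. significant features).
#' @param universe background gene list: the features actually tested
#'   upstream, which corrects the sampling bias of testing only measured
#'   genes.
#' @param collection an `omx_genesets`.
#' @return an `omx_enrichment`: data frame (set, overlap k, set_size K,
#'   query_size, universe_size, gene_ratio, p, adj_p, genes) plus a
#'   `dropped` attribute (sets with no universe member) and
#'   `query_dropped` (query genes outside the universe).
#' @export
ora <- function(query, universe, collection) {
  universe <- unique(toupper(universe))
  if (length(universe) < 2L) stopf("universe must contain at least 2 genes")
  query <- unique(toupper(query))
  query_dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  if (!length(query)) stopf("query is empty after intersection with the universe")
  N <- length(universe)
  n_q <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set_u <- intersect(collection$sets[[nm]], universe)
    K <- length(set_u)
    if (K == 0L) return(NULL)
    hits <- intersect(set_u, query)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, query_size = n_q, universe_size = N,
               gene_ratio = k / n_q, p = p,
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) stopf("no set overlaps the universe")
  out$adj_p <- bh_adjust(out$p)
  out <- out[, c("set", "k", "K", "query_size", "universe_size", "gene_ratio",
                 "p", "adj_p", "genes")]
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "query_dropped") <- query_dropped
  class(out) <- c("omx_enrichment", "data.frame")
  out
}

#' Drug-reversal scoring against up/down perturbation signatures
#'
#' Runs [ora()] of the differentially up-regulated genes against each
#' perturbation's down-set and of the down-regulated genes against each
#' up-set; a perturbation that reverses the signature scores high on both.
#' `combined_score = -log10(adj_p_up_vs_down) + -log10(adj_p_down_vs_up)`.
#' Perturbations present in only one collection get p = 1 for the missing
#' side. Sorted by descending score with deterministic ties broken by
#' perturbation name.
#'
#' @param up_genes,down_genes character vectors (either may be empty, not
#'   both).
#' @param pert_up,pert_down `omx_genesets` of perturbation-induced up/down
#'   sets, sharing perturbation names.
#' @param universe background gene list.
#' @return data frame: perturbation, p_up_vs_down, p_down_vs_up (BH
#'   adjusted), combined_score.
#' @export
drug_reversal <- function(up_genes, down_genes, pert_up, pert_down, universe) {
  if (!length(up_genes) && !length(down_genes))
    stopf("both query gene lists are empty")
  perts <- sort(union(names(pert_up$sets), names(pert_down$sets)))
  side_p <- function(query, collection) {
    p <- rep(1, length(perts)); names(p) <- perts
    if (!length(query)) return(p)
    enr <- ora(query, universe, collection)
    p[enr$set] <- enr$adj_p
    p
  }
  p_uvd <- side_p(up_genes, pert_down)
  p_dvu <- side_p(down_genes, pert_up)
  score <- -log10(p_uvd) + -log10(p_dvu)
  out <- data.frame(perturbation = perts, p_up_vs_down = p_uvd,
                    p_down_vs_up = p_dvu, combined_score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$combined_score, out$perturbation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-plot of an enrichment result
#' @param x an `omx_enrichment`.
#' @param top number of sets to show.
#' @param ... passed to plot.
#' @export
plot.omx_enrichment <- function(x, top = 15L, ...) {
  d <- utils::head(x[order(x$p), ], top)
  d <- d[nrow(d):1, ]
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(d$gene_ratio, seq_len(nrow(d)), cex = sqrt(d$k) / 2 + 0.5,
                 pch = 16, col = grDevices::hcl.colors(nrow(d), "viridis")[
                   rank(d$adj_p, ties.method = "first")],
                 yaxt = "n", xlab = "gene ratio", ylab = "",
                 main = "Over-representation", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$set, las = 2, cex.axis = 0.7)
  invisible(x)
}
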