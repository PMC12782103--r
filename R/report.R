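#' Create an empty analysis report
#'
#' A report is an ordered list of elements (headings, markdown text, figure
#' paths, tables) plus a provenance block (config hash, seed, package
#' version) that is always rendered, so the document is a pure function of
#' its elements and provenance inputs.
#'
#' @param title document title.
#' @param config any list describing the run (hashed into the provenance
#'   block).
#' @param seed the seed used for the analyses.
#' @return an `omx_report`.
#' @export
report_new <- function(title, config = list(), seed = NA) {
  structure(list(title = title, elements = list(),
                 provenance = list(
                   config_hash = object_md5(config), seed = seed,
                   tool = paste0("omicspanel ",
                                 as.character(utils::packageVersion("omicspanel"))))),
            class = "omx_report")
}

#' Append an element to a report
#'
#' @param report an `omx_report`.
#' @param kind one of `"heading"`, `"text"`, `"figure"`, `"table"`.
#' @param content markdown text (heading/text), a file path (figure), or a
#'   data frame (table).
#' @return the updated report.
#' @export
add_element <- function(report, kind = c("heading", "text", "figure", "table"),
                        content) {
  kind <- match.arg(kind)
  report$elements[[length(report$elements) + 1L]] <-
    list(kind = kind, content = content,
         position = length(report$elements) + 1L)
  report
}

#' Reorder report elements by an explicit permutation
#'
#' @param report an `omx_report`.
#' @param permutation integer vector: a bijection on 1..n elements; element i
#'   of the result is the old element `permutation[i]`.
#' @export
reorder_report <- function(report, permutation) {
  n <- length(report$elements)
  if (!setequal(permutation, seq_len(n)) || length(permutation) != n)
    stopf("permutation must be a bijection on 1..%d", n)
  report$elements <- report$elements[permutation]
  for (i in seq_len(n)) report$elements[[i]]$position <- i
  report
}

#' Render a report to a self-contained markdown document
#'
#' Figures are embedded as relative image links; tables are inlined as
#' markdown pipe tables. Every referenced figure path must exist at render
#' time. When `docx` is requested and a `pandoc` executable is on the PATH,
#' the markdown is additionally converted to a word-processor document;
#' conversion failure downgrades to markdown-only with a warning. Rendering
#' contains no timestamps, so it is idempotent: rendering twice yields
#' identical bytes.
#'
#' @param report an `omx_report`.
#' @param out_path output markdown file.
#' @param docx also attempt word-processor conversion (default FALSE).
#' @return `out_path`, invisibly.
#' @export
render_report <- function(report, out_path, docx = FALSE) {
  lines <- c(paste("#", report$title), "")
  for (el in report$elements) {
    lines <- c(lines, switch(
      el$kind,
      heading = c(paste("##", el$content), ""),
      text = c(el$content, ""),
      figure = {
        if (!file.exists(el$content))
          stopf("figure path does not exist: %s", el$content)
        c(sprintf("![](%s)", rel_path(el$content, dirname(out_path))), "")
      },
      table = c(markdown_table(as.data.frame(el$content)), "")))
  }
  pv <- report$provenance
  lines <- c(lines, "---", "## Provenance", "",
             sprintf("- config hash: `%s`", pv$config_hash),
             sprintf("- seed: %s", pv$seed),
             sprintf("- tool: %s", pv$tool), "")
  writeLines(lines, out_path)
  if (docx) {
    pandoc <- Sys.which("pandoc")
    if (!nzchar(pandoc)) {
      warnf("pandoc not found on PATH; markdown only")
    } else {
      docx_path <- sub("\\.md$", ".docx", out_path)
      status <- system2(pandoc, c(shQuote(out_path), "-o", shQuote(docx_path)))
      if (status != 0) warnf("pandoc conversion failed; markdown only")
    }
  }
  invisible(out_path)
}

## express target relative to base so rendered documents are portable
rel_path <- function(target, base) {
  t_parts <- strsplit(normalizePath(target, winslash = "/"), "/")[[1L]]
  b_parts <- strsplit(normalizePath(base, winslash = "/"), "/")[[1L]]
  i <- 0L
  while (i < min(length(t_parts), length(b_parts)) &&
         t_parts[i + 1L] == b_parts[i + 1L]) i <- i + 1L
  if (i == 0L) return(target)  # different roots: keep as given
  up <- rep("..", length(b_parts) - i)
  paste(c(up, t_parts[(i + 1L):length(t_parts)]), collapse = "/")
}

#' @export
print.omx_report <- function(x, ...) {
  cat(sprintf("Report '%s': %d element(s)\n", x$title, length(x$elements)))
  for (el in x$elements)
    cat(sprintf("  %2d. [%s] %s\n", el$position, el$kind,
                if (is.character(el$content)) substr(el$content[1L], 1, 50)
                else paste0("<", class(el$content)[1L], ">")))
  invisible(x)
}
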