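#' Render a genotype-comparison summary as markdown
#'
#' Produces the compact wildtype-versus-mutant table used by the analysis
#' drivers: one row per derived property (estimate +/- SE where available),
#' rounded for reading; machine-readable output should use the JSON
#' emitters instead.
#'
#' @param rows A data frame with columns `property`, `units`, `wildtype`,
#'   `mutant` (values preformatted as character, or numeric). May be empty.
#' @param path Optional output file.
#' @param title Report title.
#' @return Character vector of markdown lines (invisibly when written).
#' @export
report_markdown <- function(rows, path = NULL,
                            title = "Genotype comparison") {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 3, format = "fg") else as.character(x)
  }
  lines <- c(paste("#", title), "")
  if (is.null(rows) || nrow(rows) == 0) {
    lines <- c(lines, "_No results._")
  } else {
    lines <- c(lines,
               "| Property | Units | Wildtype | Mutant |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %s | %s |",
                       fmt(rows$property), fmt(rows$units),
                       fmt(rows$wildtype), fmt(rows$mutant)))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
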