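#' Write tabular and graphical result files
#'
#' Emits the three result artifacts into `out_dir`:
#' \describe{
#'   \item{qualitative.tsv}{genes x hypotheses, cells `+1`/`-1`/`0`, empty
#'     for undefined, `+1/-1` for unresolved-conflict display (edited cells
#'     show their edited value).}
#'   \item{quantitative.tsv}{QT values with three trailing summary rows
#'     `Sum of Pro`, `Sum of Anti`, `Net`.}
#'   \item{net_effects.svg}{horizontal bar chart of the net effect per
#'     hypothesis term, positive bars green and negative bars red, the same
#'     colour convention as the tables.}
#' }
#' Output is plain deterministic text: identical inputs give byte-identical
#' files.
#'
#' @param ql a `ql_matrix`.
#' @param qs a `quant_summary` for the same matrix.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the paths written.
#' @export
write_outputs <- function(ql, qs, out_dir) {
  stopifnot(inherits(ql, "ql_matrix"), inherits(qs, "quant_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(qualitative = file.path(out_dir, "qualitative.tsv"),
             quantitative = file.path(out_dir, "quantitative.tsv"),
             chart = file.path(out_dir, "net_effects.svg"))

  header <- paste(c("gene", ql$hypotheses), collapse = "\t")
  qual_rows <- vapply(seq_along(ql$genes), function(i) {
    cells <- vapply(seq_along(ql$hypotheses), function(j)
      .render_ql_cell(ql, i, j), character(1))
    paste(c(ql$genes[[i]], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, qual_rows), paths[["qualitative"]])

  quant_rows <- vapply(seq_along(ql$genes), function(i) {
    cells <- vapply(seq_along(ql$hypotheses), function(j) {
      v <- qs$qt[i, j]
      if (is.na(v)) "" else .num(v)
    }, character(1))
    paste(c(ql$genes[[i]], cells), collapse = "\t")
  }, character(1))
  summary_rows <- c(
    paste(c("Sum of Pro", vapply(qs$pro, .num, character(1))),
          collapse = "\t"),
    paste(c("Sum of Anti", vapply(qs$anti, .num, character(1))),
          collapse = "\t"),
    paste(c("Net", vapply(qs$net, .num, character(1))), collapse = "\t"))
  writeLines(c(header, quant_rows, summary_rows), paths[["quantitative"]])

  writeLines(svg_barchart(qs$net, ql$hypotheses), paths[["chart"]])
  invisible(paths)
}

.render_ql_cell <- function(ql, i, j) {
  v <- ql$ql[i, j]
  if (is.na(v)) return("")
  if (ql$conflict[i, j] && !ql$edited[i, j]) return("+1/-1")
  if (v > 0) "+1" else if (v < 0) "-1" else "0"
}

.num <- function(x) {
  if (x == round(x)) return(as.character(as.integer(round(x))))
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Horizontal bar chart of net effects as SVG text
#'
#' A minimal, dependency-free SVG writer: one horizontal bar per hypothesis
#' term, green for net-positive, red for net-negative, drawn about a zero
#' axis. Written by hand (rather than through a graphics device) so the
#' bytes are a pure function of the data.
#'
#' @param net named numeric vector of net effects.
#' @param labels bar labels (defaults to `names(net)`).
#' @return character vector of SVG lines.
#' @export
svg_barchart <- function(net, labels = names(net)) {
  n <- length(net)
  bar_h <- 22; gap <- 8; left <- 170; plot_w <- 420; top <- 30
  height <- top + n * (bar_h + gap) + 30
  width <- left + plot_w + 60
  maxabs <- max(abs(net), 1e-12)
  sc <- (plot_w / 2) / maxabs
  x0 <- left + plot_w / 2
  out <- c(
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" ",
                   "font-family=\"sans-serif\" font-size=\"13\">"),
            as.integer(width), as.integer(height)),
    sprintf(paste0("<line x1=\"%.2f\" y1=\"%d\" x2=\"%.2f\" y2=\"%d\" ",
                   "stroke=\"#444444\" stroke-width=\"1\"/>"),
            x0, as.integer(top - 10), x0,
            as.integer(top + n * (bar_h + gap))))
  for (k in seq_len(n)) {
    y <- top + (k - 1) * (bar_h + gap)
    w <- abs(net[[k]]) * sc
    x <- if (net[[k]] >= 0) x0 else x0 - w
    col <- if (net[[k]] > 0) "#2ca02c" else if (net[[k]] < 0) "#d62728"
           else "#aaaaaa"
    out <- c(out,
      sprintf(paste0("<rect x=\"%.2f\" y=\"%.2f\" width=\"%.2f\" ",
                     "height=\"%d\" fill=\"%s\"/>"),
              x, y, w, as.integer(bar_h), col),
      sprintf(paste0("<text x=\"%d\" y=\"%.2f\" ",
                     "text-anchor=\"end\">%s</text>"),
              as.integer(left - 8), y + bar_h - 6,
              .xml_escape(labels[[k]])),
      sprintf("<text x=\"%.2f\" y=\"%.2f\">%s</text>",
              if (net[[k]] >= 0) x0 + w + 6 else x - 6 -
                7.2 * nchar(.num(net[[k]])),
              y + bar_h - 6, .num(net[[k]])))
  }
  c(out, "</svg>")
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}
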