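#' Read gene-to-GO annotations
#'
#' Loads an annotation set from either a GAF 2.x file (tab-separated, `!`
#' comment lines; column 3 = object symbol, column 4 = qualifier, column 5 =
#' GO id, column 7 = evidence code) or a simple two-column id map
#' (`gene<TAB or comma>GO:id` per line). Every GO id is validated against the
#' ontology: obsolete and unknown ids are dropped with a warning, as are
#' GAF rows carrying a `NOT` qualifier (negated annotations have no defined
#' sign semantics here). Genes whose annotations were all dropped are
#' retained with an empty set, so they surface as "undefined" rows in the
#' qualitative table rather than silently vanishing.
#'
#' @param x path to the annotation file, or a character vector of its lines.
#' @param format `"gaf"` or `"idmap"`.
#' @param dag a `go_dag` used for id validation.
#' @param case_insensitive lowercase gene identifiers on load (matching is
#'   exact and case-sensitive by default, since case folding can merge
#'   distinct symbols).
#' @return an `annotation_set`: list with `by_gene` (named list of GO id
#'   sets) and `provenance` (data frame of gene, go_id, qualifier, evidence).
#' @export
parse_annotations <- function(x, format = c("gaf", "idmap"), dag,
                              case_insensitive = FALSE) {
  format <- match.arg(format)
  lines <- .read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  genes <- character(0); gos <- character(0)
  quals <- character(0); evs <- character(0)

  if (format == "gaf") {
    body <- lines[!startsWith(lines, "!")]
    for (k in seq_along(body)) {
      f <- strsplit(body[[k]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 15L)
        stop("GAF row with fewer than 15 columns at data line ", k, ": ",
             substr(body[[k]], 1, 60), call. = FALSE)
      genes <- c(genes, f[[3]]); quals <- c(quals, f[[4]])
      gos <- c(gos, f[[5]]); evs <- c(evs, f[[7]])
    }
  } else {
    body <- lines[!startsWith(lines, "#")]
    for (k in seq_along(body)) {
      f <- strsplit(body[[k]], "[\t,]")[[1]]
      f <- trimws(f[nzchar(trimws(f))])
      if (length(f) != 2L)
        stop("idmap line ", k, " does not have exactly two fields: ",
             body[[k]], call. = FALSE)
      genes <- c(genes, f[[1]]); gos <- c(gos, f[[2]])
      quals <- c(quals, ""); evs <- c(evs, "")
    }
  }
  if (case_insensitive) genes <- tolower(genes)

  keep <- rep(TRUE, length(genes))
  is_not <- grepl("(^|\\|)NOT($|\\|)", quals)
  if (any(is_not)) {
    warning(sum(is_not), " NOT-qualified annotation row(s) dropped",
            call. = FALSE)
    keep <- keep & !is_not
  }
  status <- vapply(gos, function(g) term_status(dag, g), character(1))
  if (any(keep & status == "obsolete")) {
    bad <- unique(gos[keep & status == "obsolete"])
    warning("dropped annotation(s) to obsolete GO id(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(keep & status == "unknown")) {
    bad <- unique(gos[keep & status == "unknown"])
    warning("dropped annotation(s) to unknown GO id(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  surviving <- keep & status == "valid"

  by_gene <- lapply(split(gos[surviving], factor(genes[surviving],
                                                 levels = unique(genes))),
                    function(v) sort(unique(v)))
  prov <- data.frame(gene = genes[keep], go_id = gos[keep],
                     qualifier = quals[keep], evidence = evs[keep],
                     stringsAsFactors = FALSE)
  structure(list(by_gene = by_gene, provenance = prov,
                 case_insensitive = case_insensitive),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$by_gene), " gene(s), ",
      sum(lengths(x$by_gene)), " annotation pair(s)\n", sep = "")
  invisible(x)
}

#' GO ids annotated to one gene
#'
#' Returns the stored id set. The `seen` attribute distinguishes a gene that
#' appeared in the annotation file but lost all its annotations to
#' validation (`seen = TRUE`, empty set) from a gene never seen at all
#' (`seen = FALSE`), so downstream tables can render "undefined" for both
#' while logs can tell them apart.
#'
#' @param aset an `annotation_set`.
#' @param gene_id gene identifier (case-folded if the set was loaded
#'   case-insensitively).
#' @return character vector of GO ids with logical attribute `seen`.
#' @export
annotations_of <- function(aset, gene_id) {
  stopifnot(inherits(aset, "annotation_set"))
  if (isTRUE(aset$case_insensitive)) gene_id <- tolower(gene_id)
  ids <- aset$by_gene[[gene_id]]
  if (is.null(ids))
    return(structure(character(0), seen = FALSE))
  structure(ids, seen = TRUE)
}

#' Write a Gene Information File
#'
#' One line per gene: identifier, expression value and the comma-joined GO
#' ids found for it — the intermediate file sitting between annotation
#' retrieval and effect scoring.
#'
#' @param expr expression table from [parse_expression()].
#' @param aset an `annotation_set`.
#' @param path output file.
#' @return invisibly, the lines written.
#' @export
write_gene_info <- function(expr, aset, path) {
  lines <- vapply(seq_len(nrow(expr)), function(i) {
    ids <- annotations_of(aset, expr$gene_id[[i]])
    paste(c(expr$gene_id[[i]], format(expr$value[[i]], digits = 15), ids),
          collapse = ", ")
  }, character(1))
  writeLines(lines, path)
  invisible(lines)
}
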