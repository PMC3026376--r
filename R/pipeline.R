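#' Run the full analysis pipeline
#'
#' Orchestrates the whole flow: parse the ontology, annotations, expression
#' and hypothesis inputs; build the qualitative matrix; apply optional
#' edits; weigh by expression; write the qualitative and quantitative TSVs,
#' the net-effect SVG chart and the Gene Information File. All results are
#' computed in memory before anything is written, so a failing stage leaves
#' no partial outputs behind.
#'
#' @param obo path to the OBO ontology file.
#' @param annotations path to the annotation file.
#' @param annotation_format `"gaf"` or `"idmap"`.
#' @param expr path to the expression file (`id,value` lines).
#' @param scale expression scale, see [parse_expression()].
#' @param hgt path to a prebuilt HGT file (label, comma-separated GO ids
#'   per line). Exactly one of `hgt` / `hypotheses` is required.
#' @param hypotheses path to a hypothesis file (one free-text term per
#'   line); GO ids are found by [build_hgt()] with `select = "all"`.
#' @param edits optional path to an edits file, see [parse_edits()].
#' @param out_dir output directory.
#' @param cfg a [scoring_config()].
#' @param case_insensitive lowercase gene ids on both sides before
#'   matching.
#' @return invisibly, a list with the `ql_matrix`, the `quant_summary` and
#'   the named vector of output `paths`.
#' @export
run_pipeline <- function(obo, annotations, annotation_format = "gaf",
                         expr, scale = "log2_ratio",
                         hgt = NULL, hypotheses = NULL, edits = NULL,
                         out_dir, cfg = scoring_config(),
                         case_insensitive = FALSE) {
  if (is.null(hgt) && is.null(hypotheses))
    stop("either an HGT file or a hypothesis file is required",
         call. = FALSE)
  dag <- parse_obo(obo)
  aset <- parse_annotations(annotations, format = annotation_format,
                            dag = dag, case_insensitive = case_insensitive)
  ex <- parse_expression(expr, scale = scale)
  if (case_insensitive) ex$gene_id <- tolower(ex$gene_id)
  hset <- if (!is.null(hgt)) read_hgt(hgt, dag)
          else build_hgt(dag, .read_hypothesis_file(hypotheses))
  ql <- build_qualitative(ex, aset, hset, dag, cfg)
  if (!is.null(edits)) ql <- apply_edits(ql, parse_edits(edits))
  qs <- build_quantitative(ql, ex)

  n_undef <- sum(is.na(ql$ql))
  n_conf <- sum(ql$conflict)
  message("scored ", length(ql$genes), " gene(s) x ",
          length(ql$hypotheses), " hypothesis term(s): ",
          n_conf, " conflict(s), ", n_undef, " undefined cell(s)")

  paths <- write_outputs(ql, qs, out_dir)
  gi <- file.path(out_dir, "gene_information.txt")
  write_gene_info(ex, aset, gi)
  paths <- c(paths, gene_info = gi)
  invisible(list(ql = ql, qs = qs, paths = paths))
}

.read_hypothesis_file <- function(x) {
  lines <- trimws(.read_lines_arg(x))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
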