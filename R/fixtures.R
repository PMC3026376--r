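#' Specification for synthetic toy fixtures
#'
#' Parameters of the deterministic toy ontology/annotation generators used
#' in examples and tests. Identical specs produce byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_process_terms number of base biological-process terms.
#' @param signed_fraction fraction of base terms that gain a
#'   regulation / positive regulation / negative regulation subtree.
#' @param n_genes number of genes to annotate.
#' @param annotations_per_gene length-2 integer range (min, max) of
#'   annotations drawn per gene.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(seed = 1L, n_process_terms = 4L, signed_fraction = 0.5,
                     n_genes = 6L, annotations_per_gene = c(1L, 3L)) {
  stopifnot(n_process_terms >= 1L, n_genes >= 0L,
            signed_fraction >= 0, signed_fraction <= 1,
            length(annotations_per_gene) == 2L,
            annotations_per_gene[[1]] >= 1L,
            annotations_per_gene[[1]] <= annotations_per_gene[[2]])
  structure(list(seed = as.integer(seed),
                 n_process_terms = as.integer(n_process_terms),
                 signed_fraction = signed_fraction,
                 n_genes = as.integer(n_genes),
                 annotations_per_gene = as.integer(annotations_per_gene)),
            class = "toy_spec")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a toy ontology as OBO text
#'
#' Emits a rooted DAG: one root, `n_process_terms` children named
#' "process_k", and for a seeded choice of `signed_fraction` of the base
#' terms a regulation triple — "regulation of process_k" (is_a root, part_of
#' its process) with "positive regulation of process_k" and "negative
#' regulation of process_k" as is_a children. The shape mirrors the part of
#' real GO that effect-sign parsing cares about.
#'
#' @param spec a [toy_spec()].
#' @return character vector of OBO lines.
#' @export
generate_toy_ontology <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_process_terms
  n_signed <- round(spec$signed_fraction * n)
  signed <- .with_seed(spec$seed,
                       sort(sample(seq_len(n), n_signed)))
  gid <- function(base, k) sprintf("GO:%07d", base + k)
  root <- gid(1000000, 0)
  out <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root), "name: biological_process", "")
  for (k in seq_len(n)) {
    out <- c(out, "[Term]", paste0("id: ", gid(1000000, k)),
             paste0("name: process_", k), paste0("is_a: ", root), "")
    if (k %in% signed) {
      reg <- gid(1100000, k)
      out <- c(out,
        "[Term]", paste0("id: ", reg),
        paste0("name: regulation of process_", k),
        paste0("is_a: ", root),
        paste0("relationship: part_of ", gid(1000000, k)), "",
        "[Term]", paste0("id: ", gid(1110000, k)),
        paste0("name: positive regulation of process_", k),
        paste0("is_a: ", reg), "",
        "[Term]", paste0("id: ", gid(1120000, k)),
        paste0("name: negative regulation of process_", k),
        paste0("is_a: ", reg), "")
    }
  }
  out
}

#' Generate toy annotations as GAF 2.2 text
#'
#' Annotates `n_genes` symbols (`G001`, `G002`, ...) to seeded random
#' samples of the ontology's leaf terms, within the per-gene range of the
#' spec. Output is a valid 17-column GAF 2.2 file; every emitted GO id is
#' valid against `dag` by construction.
#'
#' @param dag a `go_dag`, typically `parse_obo(generate_toy_ontology(spec))`.
#' @param spec a [toy_spec()].
#' @return character vector of GAF lines.
#' @export
generate_toy_annotations <- function(dag, spec = toy_spec()) {
  stopifnot(inherits(dag, "go_dag"), inherits(spec, "toy_spec"))
  all_ids <- go_terms(dag)
  with_kids <- unique(unlist(lapply(dag$terms, `[[`, "parents")))
  leaves <- setdiff(all_ids, with_kids)
  header <- "!gaf-version: 2.2"
  if (spec$n_genes == 0L) return(header)
  rows <- .with_seed(spec$seed + 1L, {
    unlist(lapply(seq_len(spec$n_genes), function(i) {
      g <- sprintf("G%03d", i)
      lo <- spec$annotations_per_gene[[1]]
      hi <- spec$annotations_per_gene[[2]]
      k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      ids <- sample(leaves, min(k, length(leaves)))
      vapply(ids, function(go)
        paste(c("TOY", g, g, "involved_in", go, "TOY:0000001", "IEA", "",
                "P", "", "", "protein", "taxon:0000", "20260101", "TOY",
                "", ""), collapse = "\t"),
        character(1))
    }), use.names = FALSE)
  })
  c(header, rows)
}

#' The packaged nine-cytokine qualitative-effect study matrix
#'
#' A transcription of the published comparison between tool-derived (G) and
#' immunologist-derived (M) qualitative effects of nine differentially
#' expressed cytokine genes on eight hypothesis terms (TH2 response,
#' antigen presentation, chemotaxis, metastasis, angiogenesis, T cell
#' activation, cell proliferation, apoptosis). Only the per-gene cells are
#' packaged; the summary rows are recomputed, never read. Cells holding
#' conflicting evidence are stored as the sign pair \{+1, -1\}; blank cells
#' mean no effect was found (undefined). The original annotation databases
#' behind these cells are era-specific and irrecoverable, so this fixture
#' enters the pipeline at the resolution stage via [ql_from_cells()].
#'
#' @return a `table2_fixture`: list with `genes`, `hypotheses`, character
#'   matrices `raw_g`/`raw_m`, and list matrices `cells_g`/`cells_m` of
#'   integer effect vectors (`NULL`-length for absent cells).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "cytokine_study_effects.tsv",
                      package = "goeffects", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  genes <- unique(tab$gene)
  hyps <- unique(tab$hypothesis)
  stopifnot(nrow(tab) == length(genes) * length(hyps))
  parse_cell <- function(s) {
    if (is.na(s)) return(integer(0))
    s <- trimws(s)
    if (!nzchar(s)) return(integer(0))
    as.integer(trimws(strsplit(s, "/", fixed = TRUE)[[1]]))
  }
  raw_g <- matrix(tab$G, length(genes), length(hyps), byrow = TRUE,
                  dimnames = list(genes, hyps))
  raw_m <- matrix(tab$M, length(genes), length(hyps), byrow = TRUE,
                  dimnames = list(genes, hyps))
  cells_g <- .relist_cells(raw_g, parse_cell)
  cells_m <- .relist_cells(raw_m, parse_cell)
  structure(list(genes = genes, hypotheses = hyps,
                 raw_g = raw_g, raw_m = raw_m,
                 cells_g = cells_g, cells_m = cells_m),
            class = "table2_fixture")
}

.relist_cells <- function(raw, parse_cell) {
  out <- vector("list", length(raw))
  dim(out) <- dim(raw)
  for (i in seq_len(nrow(raw))) for (j in seq_len(ncol(raw)))
    out[[i, j]] <- parse_cell(raw[i, j])
  dimnames(out) <- dimnames(raw)
  out
}

#' Net-effect columns of a study fixture
#'
#' Resolves one side (G or M) of the fixture with the configured policies,
#' applies unit gene weights and returns the quantitative summary.
#'
#' @param fix a [table2_fixture()].
#' @param which `"G"` (tool-derived) or `"M"` (manual).
#' @param cfg a [scoring_config()].
#' @return a `quant_summary`.
#' @export
fixture_summary <- function(fix, which = c("G", "M"),
                            cfg = scoring_config()) {
  which <- match.arg(which)
  cells <- if (which == "G") fix$cells_g else fix$cells_m
  ql <- ql_from_cells(cells, fix$genes, fix$hypotheses, cfg)
  build_quantitative(ql, unit_expression(fix$genes))
}

#' Agreement between tool-derived and manual net effects
#'
#' For each hypothesis term the net effect is computed independently from
#' the fixture's G and M cell matrices (conflicts resolved per `cfg`, unit
#' weights, absent cells skipped); the score is the percentage of terms
#' whose two nets point the same way, with zero counted as its own
#' direction.
#'
#' @param fix a [table2_fixture()] (or compatible structure).
#' @param cfg a [scoring_config()].
#' @return percentage in [0, 100].
#' @export
agreement_score <- function(fix, cfg = scoring_config()) {
  net_g <- fixture_summary(fix, "G", cfg)$net
  net_m <- fixture_summary(fix, "M", cfg)$net
  100 * mean(sign(net_g) == sign(net_m))
}
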