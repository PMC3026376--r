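#' Parse a gene expression file
#'
#' One `identifier,value` pair per line. Values may be fold changes
#' (treatment/control), log2 ratios, or expression differences; fold changes
#' are converted to log2 so that the sign conventions hold on every scale:
#' positive = up-regulated, negative = down-regulated, zero = no change.
#'
#' @param x path or character vector of lines.
#' @param scale `"fold_change"` (log2-converted, must be > 0),
#'   `"log2_ratio"` or `"difference"` (passed through).
#' @return data frame with columns `gene_id`, `raw_value`, `scale`, `value`
#'   (the normalized GE value), in file order.
#' @examples
#' parse_expression("IL6,2.0", scale = "fold_change")$value  # 1
#' @export
parse_expression <- function(x, scale = c("log2_ratio", "fold_change",
                                          "difference")) {
  scale <- match.arg(scale)
  lines <- .read_lines_arg(x)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  ids <- character(length(lines)); raw <- numeric(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], ",", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop("expression line ", idx[[k]],
           " is not 'id,value': ", lines[[k]], call. = FALSE)
    v <- suppressWarnings(as.numeric(trimws(f[[2]])))
    if (is.na(v))
      stop("non-numeric expression value at line ", idx[[k]], ": ",
           lines[[k]], call. = FALSE)
    ids[[k]] <- trimws(f[[1]]); raw[[k]] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in expression file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (scale == "fold_change" && any(raw <= 0))
    stop("fold-change value(s) must be positive; offending gene(s): ",
         paste(ids[raw <= 0], collapse = ", "), call. = FALSE)
  value <- if (scale == "fold_change") log2(raw) else raw
  data.frame(gene_id = ids, raw_value = raw, scale = scale, value = value,
             stringsAsFactors = FALSE)
}

#' Build the qualitative effect matrix
#'
#' For every gene G_i and hypothesis term H_j, the gene's GO annotations are
#' matched against the hypothesis ids ([match_effects()]), signs pass the
#' unsigned-term policy and the effect list is resolved
#' ([resolve_effects()]) to the qualitative value QL_ij in
#' \{+1, -1, 0, undefined\}. Genes with no annotations, or whose annotations
#' share nothing with a hypothesis term, get undefined cells. Row and column
#' order follow the input files.
#'
#' @param expr expression table from [parse_expression()].
#' @param aset an `annotation_set`.
#' @param hset a `hypothesis_set`.
#' @param dag a `go_dag`.
#' @param cfg a [scoring_config()].
#' @return a `ql_matrix`: list with `genes`, `hypotheses`, integer matrix
#'   `ql` (`NA` = undefined), logical matrices `conflict` and `edited`, and
#'   `effects` (list of per-cell `effect_list`s, kept for audit).
#' @export
build_qualitative <- function(expr, aset, hset, dag,
                              cfg = scoring_config()) {
  genes <- expr$gene_id
  hyps <- hypothesis_labels(hset)
  n <- length(genes); m <- length(hyps)
  ql <- matrix(NA_integer_, n, m, dimnames = list(genes, hyps))
  conflict <- matrix(FALSE, n, m, dimnames = list(genes, hyps))
  edited <- matrix(FALSE, n, m, dimnames = list(genes, hyps))
  effects <- vector("list", n * m)
  dim(effects) <- c(n, m)
  for (i in seq_len(n)) {
    gids <- annotations_of(aset, genes[[i]])
    for (j in seq_len(m)) {
      el <- if (length(gids)) match_effects(dag, gids, hset$terms[[j]], cfg)
            else .empty_effect_list()
      r <- resolve_effects(el, cfg)
      ql[i, j] <- r$value
      conflict[i, j] <- r$conflict
      effects[[i, j]] <- el
    }
  }
  structure(list(genes = genes, hypotheses = hyps, ql = ql,
                 conflict = conflict, edited = edited, effects = effects,
                 cfg = cfg),
            class = "ql_matrix")
}

#' @export
print.ql_matrix <- function(x, ...) {
  cat("<ql_matrix> ", length(x$genes), " gene(s) x ", length(x$hypotheses),
      " hypothesis term(s); ", sum(x$conflict), " conflict(s), ",
      sum(is.na(x$ql)), " undefined cell(s)\n", sep = "")
  print(x$ql)
  invisible(x)
}

#' Assemble a qualitative matrix from pre-resolved effect sets
#'
#' Entry point for data that arrives already scored per cell (for example a
#' transcribed qualitative table whose underlying annotations are no longer
#' available): each cell is a vector of signed effects in \{-1, 0, +1\}
#' (possibly length > 1 for conflicting evidence, empty/`NULL` for absent)
#' and is resolved with the configured conflict policy.
#'
#' @param cells a genes x hypotheses matrix (list matrix) of integer vectors.
#' @param genes,hypotheses dimension labels.
#' @param cfg a [scoring_config()].
#' @return a `ql_matrix` (with empty audit effect lists).
#' @export
ql_from_cells <- function(cells, genes, hypotheses,
                          cfg = scoring_config()) {
  n <- length(genes); m <- length(hypotheses)
  stopifnot(is.list(cells), length(cells) == n * m)
  dim(cells) <- c(n, m)
  ql <- matrix(NA_integer_, n, m, dimnames = list(genes, hypotheses))
  conflict <- matrix(FALSE, n, m, dimnames = list(genes, hypotheses))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    r <- resolve_effects(as.integer(cells[[i, j]]), cfg)
    ql[i, j] <- r$value
    conflict[i, j] <- r$conflict
  }
  effects <- vector("list", n * m); dim(effects) <- c(n, m)
  structure(list(genes = genes, hypotheses = hypotheses, ql = ql,
                 conflict = conflict,
                 edited = matrix(FALSE, n, m,
                                 dimnames = list(genes, hypotheses)),
                 effects = effects, cfg = cfg),
            class = "ql_matrix")
}

#' Quantitative summary of a qualitative matrix
#'
#' Weighs each defined qualitative cell by the gene's expression value,
#' QT_ij = QL_ij * GE_i, and totals each hypothesis column: Sum of Pro (sum
#' of positive QT), Sum of Anti (sum of negative QT) and the net effect
#' N_j = Sum of Pro + Sum of Anti. Undefined cells contribute to no sum;
#' QL = 0 cells contribute an explicit 0, keeping "no effect found" and
#' "effect is null" distinct.
#'
#' @param ql a `ql_matrix`.
#' @param expr expression table from [parse_expression()]; every gene in
#'   `ql` must appear. Pass `unit_expression(ql$genes)` for unit weights.
#' @return a `quant_summary`: list with matrix `qt` (`NA` where undefined)
#'   and per-hypothesis vectors `pro`, `anti`, `net`.
#' @export
build_quantitative <- function(ql, expr) {
  stopifnot(inherits(ql, "ql_matrix"))
  miss <- setdiff(ql$genes, expr$gene_id)
  if (length(miss))
    stop("gene(s) missing from expression table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ge <- expr$value[match(ql$genes, expr$gene_id)]
  qt <- ql$ql * ge  # recycles ge down columns
  dimnames(qt) <- list(ql$genes, ql$hypotheses)
  pro <- apply(qt, 2, function(col) sum(col[!is.na(col) & col > 0]))
  anti <- apply(qt, 2, function(col) sum(col[!is.na(col) & col < 0]))
  net <- apply(qt, 2, function(col) sum(col[!is.na(col)]))
  structure(list(qt = qt, pro = pro, anti = anti, net = net),
            class = "quant_summary")
}

#' @export
print.quant_summary <- function(x, ...) {
  cat("<quant_summary> ", nrow(x$qt), " gene(s) x ", ncol(x$qt),
      " hypothesis term(s)\n", sep = "")
  print(rbind(`Sum of Pro` = x$pro, `Sum of Anti` = x$anti, Net = x$net))
  invisible(x)
}

#' Unit-weight expression table
#'
#' Convenience for qualitative-only summaries: every gene gets GE = 1.
#'
#' @param genes character vector of gene ids.
#' @return an expression table as from [parse_expression()].
#' @export
unit_expression <- function(genes) {
  data.frame(gene_id = genes, raw_value = rep(1, length(genes)),
             scale = rep("difference", length(genes)),
             value = rep(1, length(genes)), stringsAsFactors = FALSE)
}

#' Read an effect-edits file
#'
#' Tab-separated, one override per line: `gene_id<TAB>hypothesis
#' label<TAB>value` with value in \{-1, 0, 1\}; `#` lines are comments.
#' The file-based replacement for an interactive edit screen.
#'
#' @param x path or character vector of lines.
#' @return data frame with columns `gene_id`, `hypothesis`, `value`.
#' @export
parse_edits <- function(x) {
  lines <- .read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      stop("edit line ", k, " is not 'gene<TAB>hypothesis<TAB>value': ",
           lines[[k]], call. = FALSE)
    v <- suppressWarnings(as.integer(trimws(f[[3]])))
    if (is.na(v) || !(v %in% c(-1L, 0L, 1L)))
      stop("edit line ", k, ": value must be -1, 0 or 1", call. = FALSE)
    data.frame(gene_id = trimws(f[[1]]), hypothesis = trimws(f[[2]]),
               value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(gene_id = character(0),
                                         hypothesis = character(0),
                                         value = integer(0)))))
}

#' Apply user edits to a qualitative matrix
#'
#' Domain knowledge beats automation: an edit replaces a cell's qualitative
#' value (typically to settle a conflict, or to fill a cell the ontology
#' could not score), sets the edited flag and clears the conflict flag. The
#' cell's effect list is retained for audit. Edits apply in order; the last
#' edit to a cell wins.
#'
#' @param ql a `ql_matrix`.
#' @param edits data frame from [parse_edits()].
#' @return the edited `ql_matrix`.
#' @export
apply_edits <- function(ql, edits) {
  stopifnot(inherits(ql, "ql_matrix"))
  for (k in seq_len(nrow(edits))) {
    i <- match(edits$gene_id[[k]], ql$genes)
    j <- match(edits$hypothesis[[k]], ql$hypotheses)
    if (is.na(i)) stop("edit references unknown gene: ",
                       edits$gene_id[[k]], call. = FALSE)
    if (is.na(j)) stop("edit references unknown hypothesis label: ",
                       edits$hypothesis[[k]], call. = FALSE)
    ql$ql[i, j] <- edits$value[[k]]
    ql$edited[i, j] <- TRUE
    ql$conflict[i, j] <- FALSE
  }
  ql
}
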