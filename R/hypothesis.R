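#' Stems of a free-text hypothesis term
#'
#' Lowercases, tokenizes on non-letter characters and Porter-stems each word.
#' Multi-word hypothesis terms yield one stem per word; matching against the
#' ontology requires all stems to hit the same term record.
#'
#' @param text free-text hypothesis term.
#' @return character vector of stems (length 0 for empty input).
#' @examples
#' stem_term("inflammation")      # "inflamm"
#' stem_term("T cell activation") # c("t", "cell", "activ")
#' @export
stem_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  words <- strsplit(tolower(trimws(text)), "[^a-z]+")[[1]]
  words <- words[nzchar(words)]
  if (!length(words)) return(character(0))
  vapply(words, porter_stem, character(1), USE.NAMES = FALSE)
}

#' Search the ontology for a hypothesis term
#'
#' A non-obsolete term is a candidate when every stem of the label occurs as
#' a substring of its lowercased name, synonyms or definition. Candidates
#' are sorted by matched-field priority (name > synonym > definition, then
#' id); the reported `matched_field` is the highest-priority single field
#' containing all stems, or `"combined"` when the stems are only jointly
#' covered across fields.
#'
#' @param dag a `go_dag`.
#' @param label free-text hypothesis term.
#' @return data frame with columns `go_id`, `name`, `matched_field`; zero
#'   rows when nothing matches.
#' @export
search_ontology <- function(dag, label) {
  stems <- stem_term(label)
  empty <- data.frame(go_id = character(0), name = character(0),
                      matched_field = character(0), stringsAsFactors = FALSE)
  if (!length(stems)) return(empty)
  rows <- lapply(names(dag$terms), function(id) {
    t <- dag$terms[[id]]
    if (t$obsolete) return(NULL)
    nm <- tolower(t$name)
    syn <- tolower(t$synonyms)
    def <- tolower(t$def)
    in_name <- all(vapply(stems, grepl, logical(1), x = nm, fixed = TRUE))
    in_syn <- length(syn) > 0 && any(vapply(syn, function(s)
      all(vapply(stems, grepl, logical(1), x = s, fixed = TRUE)), logical(1)))
    in_def <- nzchar(def) &&
      all(vapply(stems, grepl, logical(1), x = def, fixed = TRUE))
    everywhere <- paste(c(nm, syn, def), collapse = " \r ")
    covered <- all(vapply(stems, grepl, logical(1), x = everywhere,
                          fixed = TRUE))
    if (!covered) return(NULL)
    field <- if (in_name) "name" else if (in_syn) "synonym"
             else if (in_def) "definition" else "combined"
    data.frame(go_id = id, name = t$name, matched_field = field,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  pri <- match(out$matched_field,
               c("name", "synonym", "definition", "combined"))
  out <- out[order(pri, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a hypothesis set
#'
#' @param labels character vector of hypothesis term labels.
#' @param go_ids list (parallel to `labels`) of character vectors of GO ids.
#' @param source list of per-id origin strings (`"search"` or `"manual"`);
#'   defaults to `"manual"` for every id.
#' @param dag optional `go_dag`; when supplied every id must validate.
#' @return a `hypothesis_set` object.
#' @export
hypothesis_set <- function(labels, go_ids, source = NULL, dag = NULL) {
  stopifnot(length(labels) == length(go_ids))
  norm <- tolower(trimws(labels))
  if (anyDuplicated(norm))
    stop("duplicate hypothesis label(s): ",
         paste(unique(labels[duplicated(norm)]), collapse = ", "),
         call. = FALSE)
  if (is.null(source))
    source <- lapply(go_ids, function(v) rep("manual", length(v)))
  terms <- lapply(seq_along(labels), function(j) {
    ids <- unique(as.character(go_ids[[j]]))
    if (!is.null(dag)) {
      st <- vapply(ids, function(i) term_status(dag, i), character(1))
      if (any(st != "valid"))
        stop("hypothesis term '", labels[[j]], "': invalid GO id(s) ",
             paste0(ids[st != "valid"], " (", st[st != "valid"], ")",
                    collapse = ", "), call. = FALSE)
    }
    list(label = labels[[j]], go_ids = ids,
         source = rep_len(source[[j]], length(ids)))
  })
  structure(list(terms = terms), class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("<hypothesis_set> ", length(x$terms), " term(s)\n", sep = "")
  for (t in x$terms)
    cat("  ", t$label, ": ", paste(t$go_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Labels of a hypothesis set
#' @param hset a `hypothesis_set`.
#' @return character vector of labels in stored order.
#' @export
hypothesis_labels <- function(hset)
  vapply(hset$terms, `[[`, character(1), "label")

#' Read a hypothesis-GO-term (HGT) file
#'
#' Each non-comment line pairs a hypothesis label with one or more GO ids:
#' `label, GO:0006915, GO:0043065`. Ids are validated against the ontology;
#' obsolete or unknown ids abort with an error naming the label and id.
#'
#' @param x path or character vector of lines.
#' @param dag a `go_dag`.
#' @return a `hypothesis_set`.
#' @export
read_hgt <- function(x, dag) {
  lines <- .read_lines_arg(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  labels <- character(0); ids <- list()
  for (k in seq_along(lines)) {
    f <- trimws(strsplit(lines[[k]], ",", fixed = TRUE)[[1]])
    f <- f[nzchar(f)]
    if (length(f) < 2L)
      stop("HGT line ", k, " has no GO id: ", lines[[k]], call. = FALSE)
    labels <- c(labels, f[[1]])
    ids[[length(ids) + 1L]] <- f[-1]
  }
  hypothesis_set(labels, ids, dag = dag)
}

#' Write a hypothesis set as an HGT file
#'
#' One line per term: the label followed by its comma-separated GO ids, in
#' stored order. `read_hgt(write_hgt(hset), dag)` preserves labels, order and
#' ids.
#'
#' @param hset a `hypothesis_set`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_hgt <- function(hset, path = NULL) {
  stopifnot(inherits(hset, "hypothesis_set"))
  lines <- vapply(hset$terms, function(t)
    paste(c(t$label, t$go_ids), collapse = ", "), character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Build a hypothesis set from free-text terms by ontology search
#'
#' Replaces the interactive checkbox selection of a web HGT builder: for each
#' label, [search_ontology()] proposes candidates and `select` picks from
#' them. Labels with no surviving candidate are dropped with a warning (a
#' term without GO ids cannot be scored).
#'
#' @param dag a `go_dag`.
#' @param labels character vector of hypothesis term labels, e.g. the lines
#'   of a hypothesis file.
#' @param select `"all"` to accept every candidate, or an integer vector of
#'   candidate indices applied to each label's candidate list.
#' @param add_ids optional named list label -> extra GO ids to append
#'   (validated; the manual text-box route).
#' @return a `hypothesis_set`.
#' @export
build_hgt <- function(dag, labels, select = "all", add_ids = list()) {
  labs <- character(0); ids <- list(); src <- list()
  for (lab in labels) {
    cand <- search_ontology(dag, lab)
    pick <- if (identical(select, "all")) seq_len(nrow(cand))
            else intersect(as.integer(select), seq_len(nrow(cand)))
    chosen <- cand$go_id[pick]
    extra <- as.character(add_ids[[lab]])
    if (!length(chosen) && !length(extra)) {
      warning("no GO ids found for hypothesis term '", lab, "'; dropped",
              call. = FALSE)
      next
    }
    labs <- c(labs, lab)
    ids[[length(ids) + 1L]] <- c(chosen, extra)
    src[[length(src) + 1L]] <- c(rep("search", length(chosen)),
                                 rep("manual", length(extra)))
  }
  hypothesis_set(labs, ids, source = src, dag = dag)
}
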