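#' @title Gene Ontology DAG from OBO text
#' @description
#' `parse_obo()` reads an OBO 1.2/1.4 flat file into a `go_dag` object: a
#' directed acyclic graph of GO terms with `is_a` and `part_of` parent edges.
#' Only the tags `id`, `name`, `synonym`, `def`, `is_a`, `relationship`,
#' `is_obsolete`, `alt_id` and `namespace` are interpreted; all other tags are
#' ignored. Relationship types other than `part_of` (e.g. `regulates`) are
#' stored on the term but are not traversed by default, because upward
#' traversal here implements the true path rule (generalisation), and
#' regulates-type edges change effect semantics rather than generalise.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `go_dag` with elements `terms` (named list of
#'   term records), `alt` (named character vector mapping alternate ids to
#'   canonical ids), and `roots` (ids of non-obsolete terms without
#'   traversable parents). Ancestor queries are memoised inside the object.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: example process")
#' dag <- parse_obo(obo)
#' go_terms(dag)
#' @export
parse_obo <- function(x) {
  lines <- .read_lines_arg(x)
  n <- length(lines)
  terms <- list()
  alt <- character(0)

  cur <- NULL
  cur_line <- NA_integer_
  in_term <- FALSE

  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id) || !nzchar(cur$id))
      stop("malformed [Term] stanza starting at line ", cur_line,
           ": missing 'id'", call. = FALSE)
    if (is.na(cur$name) || !nzchar(cur$name))
      stop("malformed [Term] stanza starting at line ", cur_line,
           ": missing 'name' for ", cur$id, call. = FALSE)
    terms[[cur$id]] <<- cur
    if (length(cur$alt_id))
      alt[cur$alt_id] <<- cur$id
  }

  for (i in seq_len(n)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NA_character_, name = NA_character_,
                    synonyms = character(0), def = "",
                    parents = character(0), relations = character(0),
                    other_edges = list(), obsolete = FALSE,
                    alt_id = character(0), namespace = NA_character_)
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) next
    tag <- m[[2]]
    val <- m[[3]]
    if (tag == "id") {
      cur$id <- trimws(val)
    } else if (tag == "name") {
      cur$name <- trimws(val)
    } else if (tag == "synonym") {
      sm <- regmatches(val, regexec("^\"(.*)\"", val))[[1]]
      if (length(sm) == 2L) cur$synonyms <- c(cur$synonyms, sm[[2]])
    } else if (tag == "def") {
      dm <- regmatches(val, regexec("^\"(.*)\"", val))[[1]]
      if (length(dm) == 2L) cur$def <- dm[[2]]
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, .strip_obo_comment(val))
      cur$relations <- c(cur$relations, "is_a")
    } else if (tag == "relationship") {
      rv <- strsplit(trimws(.strip_obo_comment(val)), "\\s+")[[1]]
      if (length(rv) >= 2L) {
        if (rv[[1]] == "part_of") {
          cur$parents <- c(cur$parents, rv[[2]])
          cur$relations <- c(cur$relations, "part_of")
        } else {
          cur$other_edges[[length(cur$other_edges) + 1L]] <-
            c(relation = rv[[1]], id = rv[[2]])
        }
      }
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    } else if (tag == "alt_id") {
      cur$alt_id <- c(cur$alt_id, trimws(val))
    } else if (tag == "namespace") {
      cur$namespace <- trimws(val)
    }
  }
  flush()

  dag <- structure(
    list(terms = terms, alt = alt, roots = character(0),
         cache = new.env(parent = emptyenv())),
    class = "go_dag")

  # resolve parent ids through alt_id and validate presence
  for (id in names(dag$terms)) {
    t <- dag$terms[[id]]
    if (t$obsolete) {
      # obsolete terms take no part in traversal
      dag$terms[[id]]$parents <- character(0)
      dag$terms[[id]]$relations <- character(0)
      next
    }
    if (length(t$parents)) {
      resolved <- vapply(t$parents, function(p) .resolve_id(dag, p),
                         character(1))
      missing <- !(resolved %in% names(dag$terms))
      if (any(missing))
        stop("term ", id, " references unknown parent id(s): ",
             paste(t$parents[missing], collapse = ", "), call. = FALSE)
      dag$terms[[id]]$parents <- unname(resolved)
    }
  }

  .check_acyclic(dag)
  live <- vapply(dag$terms, function(t) !t$obsolete, logical(1))
  no_parent <- vapply(dag$terms, function(t) length(t$parents) == 0L,
                      logical(1))
  dag$roots <- names(dag$terms)[live & no_parent]
  dag
}

.read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  out <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  if (is.null(out)) character(0) else out
}

.strip_obo_comment <- function(val) {
  trimws(sub("\\s*!.*$", "", val))
}

.resolve_id <- function(dag, id) {
  if (!is.null(dag$terms[[id]])) return(id)
  hit <- dag$alt[id]
  if (!is.na(hit)) return(unname(hit))
  id
}

# DFS three-colour cycle check over traversable parent edges
.check_acyclic <- function(dag) {
  state <- new.env(parent = emptyenv())
  path <- character(0)
  visit <- function(id) {
    s <- get0(id, envir = state, ifnotfound = 0L)
    if (s == 1L) {
      cyc <- c(path[which(path == id)[1]:length(path)], id)
      stop("cycle detected in ontology parent graph: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    if (s == 2L) return()
    assign(id, 1L, envir = state)
    path <<- c(path, id)
    for (p in dag$terms[[id]]$parents) visit(p)
    path <<- path[-length(path)]
    assign(id, 2L, envir = state)
  }
  for (id in names(dag$terms)) visit(id)
  invisible(TRUE)
}

#' Serialise a DAG back to OBO text
#'
#' Emits the interpreted subset of tags; `parse_obo(write_obo(dag))` yields an
#' isomorphic DAG (same ids, names, edges, flags).
#'
#' @param dag a `go_dag`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "go_dag"))
  out <- c("format-version: 1.2", "")
  for (id in names(dag$terms)) {
    t <- dag$terms[[id]]
    blk <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$namespace)) blk <- c(blk, paste0("namespace: ", t$namespace))
    for (a in t$alt_id) blk <- c(blk, paste0("alt_id: ", a))
    if (nzchar(t$def)) blk <- c(blk, paste0("def: \"", t$def, "\" []"))
    for (s in t$synonyms)
      blk <- c(blk, paste0("synonym: \"", s, "\" EXACT []"))
    if (length(t$parents)) {
      for (k in seq_along(t$parents)) {
        if (t$relations[[k]] == "is_a")
          blk <- c(blk, paste0("is_a: ", t$parents[[k]]))
        else
          blk <- c(blk, paste0("relationship: part_of ", t$parents[[k]]))
      }
    }
    for (e in t$other_edges)
      blk <- c(blk, paste0("relationship: ", e[["relation"]], " ", e[["id"]]))
    if (t$obsolete) blk <- c(blk, "is_obsolete: true")
    out <- c(out, blk, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' @export
print.go_dag <- function(x, ...) {
  obs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat("<go_dag> ", length(x$terms), " terms (", obs, " obsolete), ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Term ids held by a DAG
#' @param dag a `go_dag`.
#' @return character vector of canonical term ids.
#' @export
go_terms <- function(dag) names(dag$terms)

#' Look up a single term record
#' @param dag a `go_dag`.
#' @param id a GO id (alternate ids resolve to their canonical term).
#' @return the term record (list) or `NULL` when absent.
#' @export
go_term <- function(dag, id) dag$terms[[.resolve_id(dag, id)]]

#' Classify a GO id against a DAG
#'
#' A total function used to validate user-supplied ids: `"valid"` when the id
#' (or an alternate id) names a non-obsolete term, `"obsolete"` when it names
#' an obsolete term, `"unknown"` otherwise (including strings that do not look
#' like GO ids at all).
#'
#' @inheritParams go_term
#' @return one of `"valid"`, `"obsolete"`, `"unknown"`.
#' @export
term_status <- function(dag, id) {
  if (!is.character(id) || length(id) != 1L) return("unknown")
  t <- dag$terms[[.resolve_id(dag, id)]]
  if (is.null(t)) return("unknown")
  if (t$obsolete) "obsolete" else "valid"
}

#' Ancestors of a term under the true path rule
#'
#' Transitive closure over `is_a` and `part_of` parent edges, excluding the
#' query term itself. Results are memoised in the DAG object, so repeated
#' queries cost a single lookup. Optionally the stored non-traversed
#' relationship edges (regulates and friends) can be followed as well.
#'
#' @inheritParams go_term
#' @param traverse_regulates also follow regulates-type relationship edges.
#' @return character vector (a set) of ancestor ids.
#' @export
ancestors <- function(dag, id, traverse_regulates = FALSE) {
  cid <- .resolve_id(dag, id)
  t <- dag$terms[[cid]]
  if (is.null(t)) stop("unknown GO id: ", id, call. = FALSE)
  if (t$obsolete) stop("obsolete GO id: ", id, call. = FALSE)
  key <- paste0(cid, if (traverse_regulates) "+reg" else "")
  hit <- get0(key, envir = dag$cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  frontier <- .parents_of(dag, cid, traverse_regulates)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, .parents_of, dag = dag,
                              traverse_regulates = traverse_regulates),
                       use.names = FALSE)
  }
  assign(key, seen, envir = dag$cache)
  seen
}

.parents_of <- function(dag, id, traverse_regulates = FALSE) {
  t <- dag$terms[[id]]
  if (is.null(t) || t$obsolete) return(character(0))
  p <- t$parents
  if (traverse_regulates && length(t$other_edges)) {
    extra <- vapply(t$other_edges, `[[`, character(1), "id")
    extra <- vapply(extra, function(e) .resolve_id(dag, e), character(1))
    p <- c(p, unname(extra[extra %in% names(dag$terms)]))
  }
  p
}
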