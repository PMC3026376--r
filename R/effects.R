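#' Scoring configuration
#'
#' Bundles the user policies that shape effect scoring. The defaults are the
#' combination used for the nine-cytokine demonstration analysis: unsigned
#' GO terms count as positive (many annotations imply positive regulation
#' without saying so) and conflicts resolve in favour of +1.
#'
#' @param unsigned_policy effect of GO terms whose name carries no sign cue:
#'   `"positive"` maps them to +1, `"no_effect"` to 0.
#' @param conflict_policy resolution when one gene/hypothesis pair collects
#'   both +1 and -1: `"positives_override"`, `"negatives_override"`, or
#'   `"greater_of"` (sign of the count difference, ties resolve to 0).
#' @param sign_from which term name the sign is parsed from on an ancestor
#'   match: `"original"` (the gene's annotated, most specific term, falling
#'   back to the matched hypothesis-side term when unsigned) or `"matched"`
#'   (the reverse order). Generalisation discards sign — "negative
#'   regulation of X" matched via its parent "regulation of X" must still be
#'   -1 — hence the `"original"` default.
#' @param traverse_regulates follow regulates-type edges during matching.
#' @param max_depth optional cap on upward traversal depth (`Inf` = none).
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(unsigned_policy = c("positive", "no_effect"),
                           conflict_policy = c("positives_override",
                                               "negatives_override",
                                               "greater_of"),
                           sign_from = c("original", "matched"),
                           traverse_regulates = FALSE,
                           max_depth = Inf) {
  stopifnot(is.numeric(max_depth), max_depth >= 1)
  structure(list(unsigned_policy = match.arg(unsigned_policy),
                 conflict_policy = match.arg(conflict_policy),
                 sign_from = match.arg(sign_from),
                 traverse_regulates = isTRUE(traverse_regulates),
                 max_depth = max_depth),
            class = "scoring_config")
}

.POS_TOKENS <- c("positive", "pro", "stimulates", "upregulates")
.POS_STEMS <- c("increas", "stimulat", "upregulat")
.NEG_TOKENS <- c("negative", "anti", "suppresses", "inhibits",
                 "downregulates")
.NEG_STEMS <- c("decreas", "suppress", "inhibit", "downregulat")

#' Parse the effect sign of a GO term name
#'
#' GO names rarely say "positive"/"negative" outright; cues like "pro-B cell
#' differentiation" (+1), "anti-apoptosis" (-1) or "suppression of host
#' defenses" (-1) carry the sign instead. The name is lowercased and
#' tokenized on whitespace, hyphens, underscores and slashes; a token
#' signals +1 when it equals positive/pro/stimulates/upregulates or begins
#' with increas/stimulat/upregulat, and -1 when it equals
#' negative/anti/suppresses/inhibits/downregulates or begins with
#' decreas/suppress/inhibit/downregulat. Short cues ("pro", "anti") match
#' only as whole tokens, so "process" and "antigen" stay unsigned. When a
#' name carries both cues the leftmost token wins, since GO names are
#' left-modified ("negative regulation of pro-B cell differentiation" is
#' -1). Names without any cue are unsigned and fall to the unsigned-term
#' policy.
#'
#' @param term_name a GO term name.
#' @return `1L`, `-1L`, or `NA_integer_` for an unsigned name.
#' @examples
#' parse_effect_sign("pro-B cell differentiation")   # 1
#' parse_effect_sign("anti-apoptosis")                # -1
#' parse_effect_sign("regulation of apoptosis")       # NA (unsigned)
#' @export
parse_effect_sign <- function(term_name) {
  stopifnot(is.character(term_name), length(term_name) == 1L,
            nzchar(term_name))
  tokens <- strsplit(tolower(term_name), "[\\s/_-]+", perl = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    if (tok %in% .POS_TOKENS ||
        any(startsWith(tok, .POS_STEMS))) return(1L)
    if (tok %in% .NEG_TOKENS ||
        any(startsWith(tok, .NEG_STEMS))) return(-1L)
  }
  NA_integer_
}

#' Apply the unsigned-term policy
#'
#' Signed values pass through untouched; unsigned values (`NA`) become 0
#' under `"no_effect"` and +1 under `"positive"`.
#'
#' @param sign output of [parse_effect_sign()] (vectorised).
#' @param cfg a [scoring_config()].
#' @return integer vector in \{-1, 0, +1\}.
#' @export
apply_unsigned_policy <- function(sign, cfg = scoring_config()) {
  fill <- if (cfg$unsigned_policy == "positive") 1L else 0L
  out <- as.integer(sign)
  out[is.na(out)] <- fill
  out
}

#' Match a gene's GO ids against a hypothesis term's GO ids
#'
#' The matching step of the analysis: for each annotated GO id of the gene,
#' an exact hit in the hypothesis id list is recorded at depth 0; otherwise
#' the search walks up the is_a/part_of parent graph — valid under the true
#' path rule, because every ancestor of an annotated term also applies to
#' the gene product — recording each hypothesis id at the first (minimal)
#' depth at which it is reached. The record's sign is parsed from the
#' original annotated term's name, falling back to the matched term's name
#' when the original is unsigned (or the reverse under
#' `sign_from = "matched"`). Records are deduplicated on
#' (gene id, matched id), so DAG fan-in cannot inflate counts under the
#' `greater_of` conflict policy.
#'
#' @param dag a `go_dag`.
#' @param gene_go_ids character vector of the gene's annotated GO ids.
#' @param hyp one element of a `hypothesis_set` (list with `label` and
#'   `go_ids`), or a plain character vector of hypothesis GO ids.
#' @param cfg a [scoring_config()].
#' @return an `effect_list`: data frame with columns `gene_go_id`,
#'   `matched_go_id`, `depth`, `sign` (integer, `NA` = unsigned).
#' @export
match_effects <- function(dag, gene_go_ids, hyp, cfg = scoring_config()) {
  hyp_ids <- if (is.character(hyp)) hyp else hyp$go_ids
  hyp_ids <- vapply(hyp_ids, function(i) .resolve_id(dag, i), character(1))
  for (i in c(gene_go_ids, hyp_ids)) {
    st <- term_status(dag, i)
    if (st != "valid")
      stop(st, " GO id in match_effects: ", i, call. = FALSE)
  }
  recs <- list()
  for (g in gene_go_ids) {
    g <- .resolve_id(dag, g)
    # breadth-first walk up the closure; a hypothesis id is recorded at the
    # first depth it appears, and the walk continues past matches so that
    # hypothesis ids lying above other hypothesis ids are still found
    depth <- 0L
    frontier <- g
    seen <- character(0)
    while (length(frontier) && depth <= cfg$max_depth) {
      frontier <- setdiff(unique(frontier), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      for (m in intersect(frontier, hyp_ids))
        recs[[length(recs) + 1L]] <-
          list(gene_go_id = g, matched_go_id = m, depth = depth)
      frontier <- unlist(lapply(frontier, .parents_of, dag = dag,
                                traverse_regulates = cfg$traverse_regulates),
                         use.names = FALSE)
      depth <- depth + 1L
    }
    if (length(frontier) && depth > cfg$max_depth)
      warning("traversal from ", g, " truncated at max_depth = ",
              cfg$max_depth, call. = FALSE)
  }
  if (!length(recs)) return(.empty_effect_list())
  out <- data.frame(
    gene_go_id = vapply(recs, `[[`, character(1), "gene_go_id"),
    matched_go_id = vapply(recs, `[[`, character(1), "matched_go_id"),
    depth = vapply(recs, `[[`, integer(1), "depth"),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("gene_go_id", "matched_go_id")]), ,
             drop = FALSE]
  out$sign <- vapply(seq_len(nrow(out)), function(k) {
    orig <- dag$terms[[out$gene_go_id[[k]]]]$name
    mat <- dag$terms[[out$matched_go_id[[k]]]]$name
    first <- if (cfg$sign_from == "original") orig else mat
    second <- if (cfg$sign_from == "original") mat else orig
    s <- parse_effect_sign(first)
    if (is.na(s)) s <- parse_effect_sign(second)
    s
  }, integer(1))
  rownames(out) <- NULL
  class(out) <- c("effect_list", "data.frame")
  out
}

.empty_effect_list <- function() {
  structure(data.frame(gene_go_id = character(0),
                       matched_go_id = character(0),
                       depth = integer(0), sign = integer(0),
                       stringsAsFactors = FALSE),
            class = c("effect_list", "data.frame"))
}

#' Resolve an effect list to one qualitative value
#'
#' Reduces the multiset of per-match effects for one gene/hypothesis pair to
#' a single qualitative value QL in \{+1, -1, 0, undefined\}. An empty list
#' is undefined (`NA`). When both +1 and -1 are present the pair is flagged
#' as a conflict and the configured policy decides: positives override,
#' negatives override, or the greater of the two counts (ties resolve to 0).
#'
#' @param effects integer vector of per-record effects after
#'   [apply_unsigned_policy()], or an `effect_list` (its signs are passed
#'   through the policy first).
#' @param cfg a [scoring_config()].
#' @return list with `value` (`1`, `-1`, `0` or `NA` = undefined) and
#'   `conflict` (logical).
#' @export
resolve_effects <- function(effects, cfg = scoring_config()) {
  if (inherits(effects, "effect_list") || is.data.frame(effects))
    effects <- apply_unsigned_policy(effects$sign, cfg)
  effects <- as.integer(effects)
  if (!length(effects)) return(list(value = NA_integer_, conflict = FALSE))
  npos <- sum(effects == 1L)
  nneg <- sum(effects == -1L)
  conflict <- npos > 0L && nneg > 0L
  value <- if (!conflict) {
    if (npos > 0L) 1L else if (nneg > 0L) -1L else 0L
  } else switch(cfg$conflict_policy,
    positives_override = 1L,
    negatives_override = -1L,
    greater_of = as.integer(sign(npos - nneg)))
  list(value = value, conflict = conflict)
}
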