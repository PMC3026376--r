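# Shared fixtures and independent oracles for property tests.

toy_obo_path <- function() {
  system.file("extdata", "toy_apoptosis.obo", package = "goeffects")
}
toy_gaf_path <- function() {
  system.file("extdata", "toy_apoptosis.gaf", package = "goeffects")
}

# A random rooted DAG of <= n_max terms, returned as parsed dag plus its raw
# child -> parent edge list (the oracle's input, independent of the dag
# object's own bookkeeping).
make_random_dag <- function(seed, n_max = 50) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  words <- c("regulation", "of", "cell", "growth", "signal", "response",
             "membrane", "transport", "binding", "pathway", "negative",
             "positive", "cycle", "division")
  ids <- sprintf("GO:%07d", 2000000 + seq_len(n))
  edges <- list()  # list of c(child, parent)
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    nm <- paste(sample(words, sample(2:4, 1), replace = TRUE),
                collapse = " ")
    blk <- c("[Term]", paste0("id: ", ids[[i]]), paste0("name: ", nm))
    if (i > 1) {
      nparents <- sample(0:min(2, i - 1), 1)
      if (nparents > 0) {
        for (p in sample(seq_len(i - 1), nparents)) {
          blk <- c(blk, paste0("is_a: ", ids[[p]]))
          edges[[length(edges) + 1L]] <- c(ids[[i]], ids[[p]])
        }
      }
    }
    lines <- c(lines, blk, "")
  }
  list(dag = parse_obo(lines), ids = ids, edges = edges)
}

# Brute-force reachability over a raw edge list (naive BFS; the oracle that
# ancestors() must agree with).
bf_ancestors <- function(edges, id) {
  out <- character(0)
  frontier <- id
  repeat {
    nxt <- unlist(lapply(edges, function(e)
      if (e[[1]] %in% frontier) e[[2]] else NULL))
    nxt <- setdiff(unique(nxt), out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# A small ontology around cell proliferation, used for the conflicting
# IL6-style annotation scenario.
proliferation_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process", "",
    "[Term]", "id: GO:0008283", "name: cell proliferation",
    "is_a: GO:0008150", "",
    "[Term]", "id: GO:0042127", "name: regulation of cell proliferation",
    "is_a: GO:0008150", "relationship: part_of GO:0008283", "",
    "[Term]", "id: GO:0008284",
    "name: positive regulation of cell proliferation",
    "is_a: GO:0042127", "",
    "[Term]", "id: GO:0008285",
    "name: negative regulation of cell proliferation",
    "is_a: GO:0042127", "")
}

# Random pre-resolved cell matrices for conservation/linearity properties.
random_cells <- function(seed, n = 3, m = 3) {
  set.seed(seed)
  cells <- vector("list", n * m)
  for (k in seq_along(cells)) {
    len <- sample(0:3, 1)
    cells[[k]] <- if (len == 0) integer(0)
                  else sample(c(-1L, 0L, 1L), len, replace = TRUE)
  }
  dim(cells) <- c(n, m)
  list(cells = cells,
       genes = sprintf("g%d", seq_len(n)),
       hyps = sprintf("h%d", seq_len(m)),
       ge = round(stats::runif(n, -4, 4), 3))
}
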