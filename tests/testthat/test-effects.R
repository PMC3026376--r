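test_that("parse_effect_sign reads cue tokens with correct anchoring", {
  expect_identical(parse_effect_sign("pro-B cell differentiation"), 1L)
  expect_identical(parse_effect_sign("anti-apoptosis"), -1L)
  expect_identical(parse_effect_sign("suppression of host defenses"), -1L)
  expect_identical(parse_effect_sign("regulation of apoptosis"),
                   NA_integer_)

  expect_identical(parse_effect_sign("positive regulation of growth"), 1L)
  expect_identical(parse_effect_sign("increased heart rate"), 1L)
  expect_identical(parse_effect_sign("inhibits kinase activity"), -1L)
  expect_identical(parse_effect_sign("downregulates transcription"), -1L)

  # short cues only as whole tokens: no hits inside "process"/"antigen"
  expect_identical(parse_effect_sign("antigen presentation"), NA_integer_)
  expect_identical(parse_effect_sign("metabolic process"), NA_integer_)
  expect_identical(parse_effect_sign("protein binding"), NA_integer_)

  # mixed cues: leftmost wins (GO names are left-modified)
  expect_identical(
    parse_effect_sign("negative regulation of pro-B cell differentiation"),
    -1L)
  expect_identical(
    parse_effect_sign("positive regulation of anti-apoptosis"), 1L)
})

test_that("parse_effect_sign never signs a cue-free name", {
  pool <- c("regulation", "of", "cell", "membrane", "transport", "binding",
            "response", "signal", "pathway", "process", "antigen",
            "protein", "growth", "production", "cycle")
  set.seed(99)
  for (k in 1:200) {
    nm <- paste(sample(pool, sample(1:5, 1), replace = TRUE),
                collapse = " ")
    expect_identical(parse_effect_sign(nm), NA_integer_)
  }
})

test_that("apply_unsigned_policy maps NA per policy, passes signs through", {
  pos <- scoring_config(unsigned_policy = "positive")
  nil <- scoring_config(unsigned_policy = "no_effect")
  expect_identical(apply_unsigned_policy(NA_integer_, pos), 1L)
  expect_identical(apply_unsigned_policy(NA_integer_, nil), 0L)
  expect_identical(apply_unsigned_policy(c(-1L, 1L, NA), pos),
                   c(-1L, 1L, 1L))
  expect_identical(apply_unsigned_policy(c(-1L, 1L, NA), nil),
                   c(-1L, 1L, 0L))
})

test_that("match_effects finds exact and ancestor matches with signs", {
  dag <- parse_obo(toy_obo_path())

  el <- match_effects(dag, "GO:0006915", "GO:0006915")
  expect_identical(nrow(el), 1L)
  expect_identical(el$depth, 0L)
  expect_identical(el$sign, NA_integer_)  # "apoptosis" is unsigned

  # negative regulation of apoptosis matched via parent regulation term:
  # depth 1 and the sign comes from the original, more specific name
  el <- match_effects(dag, "GO:0043066", "GO:0042981")
  expect_identical(el$matched_go_id, "GO:0042981")
  expect_identical(el$depth, 1L)
  expect_identical(el$sign, -1L)

  expect_identical(nrow(match_effects(dag, "GO:0043065", "GO:0006915")),
                   0L)
  expect_error(match_effects(dag, "GO:9999999", "GO:0006915"), "unknown")
})

test_that("sign falls back to the matched name, switchable by sign_from", {
  dag <- parse_obo(toy_obo_path())
  # original "apoptosis" (unsigned) matching hypothesis id whose own name
  # is signed: anti-apoptosis is below apoptosis? no -- use reverse: gene
  # annotated to unsigned "regulation of apoptosis" has signed child? build
  # a chain where the ancestor name is signed
  obo <- c("[Term]", "id: GO:0000001", "name: suppression of growth", "",
           "[Term]", "id: GO:0000002", "name: growth arrest",
           "is_a: GO:0000001")
  d2 <- parse_obo(obo)
  el <- match_effects(d2, "GO:0000002", "GO:0000001")
  expect_identical(el$sign, -1L)  # original unsigned -> matched name used

  # sign_from = "matched" parses the hypothesis-side name first
  cfgm <- scoring_config(sign_from = "matched")
  el2 <- match_effects(dag, "GO:0043066", "GO:0042981", cfgm)
  expect_identical(el2$sign, -1L)  # matched unsigned -> original fallback
})

test_that("fan-in dedupes and max_depth truncates with a warning", {
  obo <- c("[Term]", "id: GO:0000004", "name: top", "",
           "[Term]", "id: GO:0000002", "name: left", "is_a: GO:0000004", "",
           "[Term]", "id: GO:0000003", "name: right",
           "is_a: GO:0000004", "",
           "[Term]", "id: GO:0000001", "name: negative base",
           "is_a: GO:0000002", "is_a: GO:0000003")
  dag <- parse_obo(obo)
  el <- match_effects(dag, "GO:0000001", "GO:0000004")
  expect_identical(nrow(el), 1L)  # two paths, one (gene, matched) record
  expect_identical(el$depth, 2L)

  cfg1 <- scoring_config(max_depth = 1)
  expect_warning(el1 <- match_effects(dag, "GO:0000001", "GO:0000004",
                                      cfg1),
                 "max_depth")
  expect_identical(nrow(el1), 0L)
})

test_that("matched ids equal the ancestor-closure intersection (oracle)", {
  cfg <- scoring_config()
  for (seed in 1:100) {
    rd <- make_random_dag(seed, n_max = 50)
    set.seed(seed + 10000)
    gene_ids <- sample(rd$ids, min(length(rd$ids), sample(1:4, 1)))
    hyp_ids <- sample(rd$ids, min(length(rd$ids), sample(1:5, 1)))
    el <- match_effects(rd$dag, gene_ids, hyp_ids, cfg)
    expected <- unique(unlist(lapply(gene_ids, function(g)
      intersect(hyp_ids, c(g, bf_ancestors(rd$edges, g))))))
    expect_setequal(unique(el$matched_go_id),
                    if (is.null(expected)) character(0) else expected)
  }
})

test_that("enlarging the hypothesis id set never removes records", {
  rd <- make_random_dag(7)
  set.seed(77)
  gene_ids <- sample(rd$ids, 3)
  small <- sample(rd$ids, 3)
  large <- union(small, sample(rd$ids, 5))
  el_small <- match_effects(rd$dag, gene_ids, small)
  el_large <- match_effects(rd$dag, gene_ids, large)
  key <- function(el) paste(el$gene_go_id, el$matched_go_id)
  expect_true(all(key(el_small) %in% key(el_large)))
})

test_that("resolve_effects applies conflict policies and flags", {
  po <- scoring_config(conflict_policy = "positives_override")
  no <- scoring_config(conflict_policy = "negatives_override")
  go <- scoring_config(conflict_policy = "greater_of")

  expect_identical(resolve_effects(integer(0), po),
                   list(value = NA_integer_, conflict = FALSE))
  expect_identical(resolve_effects(c(1L, 1L), po),
                   list(value = 1L, conflict = FALSE))
  expect_identical(resolve_effects(c(0L, 0L), po),
                   list(value = 0L, conflict = FALSE))
  expect_identical(resolve_effects(c(1L, -1L), po),
                   list(value = 1L, conflict = TRUE))
  expect_identical(resolve_effects(c(1L, -1L), no),
                   list(value = -1L, conflict = TRUE))
  expect_identical(resolve_effects(c(1L, 1L, -1L), go),
                   list(value = 1L, conflict = TRUE))
  expect_identical(resolve_effects(c(1L, -1L), go),
                   list(value = 0L, conflict = TRUE))
  expect_identical(resolve_effects(c(1L, -1L, -1L), go),
                   list(value = -1L, conflict = TRUE))
})

test_that("positives_override dominates negatives_override pointwise", {
  po <- scoring_config(conflict_policy = "positives_override")
  no <- scoring_config(conflict_policy = "negatives_override")
  set.seed(5)
  for (k in 1:200) {
    eff <- sample(c(-1L, 0L, 1L), sample(1:6, 1), replace = TRUE)
    expect_gte(resolve_effects(eff, po)$value,
               resolve_effects(eff, no)$value)
  }
})
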