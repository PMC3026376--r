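---
title: "Hypothesis-driven signed effect analysis with the Gene Ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis-driven signed effect analysis with the Gene Ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goeffects)
```

## The problem

Enrichment analysis asks which GO categories are over-represented in a gene
list. That framing fails in two common situations: when the scientist began
the experiment with explicit hypotheses to test rather than discover, and
when the biological process of interest involves so few genes that no
over-representation statistic can ever fire. `goeffects` addresses both: the
user names the hypotheses ("apoptosis", "chemotaxis", "TH2 response"), and
the package scores the *direction* and *weight* of the dataset's support
for each one, gene by gene, using the GO's own structure and vocabulary.

The underlying assumption is that differential-expression statistics have
already been done: the input is a list of gene identifiers with a signed
expression value each (positive = up-regulated, negative = down-regulated,
zero = no change). Fold changes are log2-converted on input so these
conventions hold on every scale.

## The model

Let gene $G_i$ carry GO annotations $A_i$ and hypothesis term $H_j$ carry a
GO id list. Matching walks each $g \in A_i$ up the ontology:

* an exact hit $g \in H_j$ is recorded at depth 0;
* otherwise the `is_a`/`part_of` parents of $g$ are searched breadth-first,
  and every hypothesis id found in the ancestor closure is recorded at the
  first depth it is reached.

The walk is justified by the true path rule: an annotation to a term is
implicitly an annotation to all of its ancestors. We deliberately record
*every* hypothesis id in the closure, not just the first along each path —
this makes the matched set exactly
$H_j \cap (\{g\} \cup \mathrm{anc}(g))$, a property the test suite checks
against a brute-force reachability oracle on random DAGs. Records are
deduplicated per (gene id, matched id), so diamond-shaped fan-in in the
DAG cannot inflate effect counts.

Each record gets a sign by parsing a term name for cue tokens
(+1: *positive, pro, stimulates, increases/d, upregulates*; −1: *negative,
anti, suppresses, inhibits, decreases/d, downregulates*). Tokenization is
on whitespace, hyphens, underscores and slashes; the short cues "pro" and
"anti" match only as whole tokens so that "process" and "antigen" stay
unsigned; longer cues match as stem prefixes so both inflections
("increases", "increased") count. When a name carries both cues, the
leftmost wins, because GO names are left-modified ("negative regulation of
pro-B cell differentiation" is a negative effect). Names with no cue are
*unsigned*.

The per-pair effect multiset is then resolved to one qualitative value
$QL_{i,j} \in \{+1, -1, 0, \mathit{undefined}\}$:

* unsigned effects take the **unsigned-term policy** value: +1 (default —
  annotations frequently imply positive regulation without saying so, and
  positive findings dominate the literature) or 0;
* a mix of +1 and −1 is a **conflict**, decided by policy: positives
  override (default), negatives override, or the greater of the two counts
  with ties going to 0 (the tie rule is ours; no published convention
  exists). Conflicts stay flagged and render as `+1/-1` in the qualitative
  table;
* an empty effect list is *undefined* — distinct from 0, which means "an
  effect was found and it is null".

Quantitatively, $QT_{i,j} = QL_{i,j} \cdot GE_i$, and per hypothesis
$\mathrm{Pro}_j = \sum_{QT>0} QT_{i,j}$,
$\mathrm{Anti}_j = \sum_{QT<0} QT_{i,j}$,
$N_j = \mathrm{Pro}_j + \mathrm{Anti}_j$. Undefined cells enter no sum;
$QL = 0$ cells contribute an explicit 0. Conservation
($N = \mathrm{Pro} + \mathrm{Anti}$) and linearity in the expression
values are exercised as properties over random matrices.

### Sign source on ancestor matches

When "negative regulation of X" matches a hypothesis via its parent
"regulation of X", which name carries the sign? Generalisation discards
sign, so by default we parse the *original* annotated name first and fall
back to the matched name only when the original is unsigned; the reverse
order is available as `scoring_config(sign_from = "matched")`. The
fallback is symmetric in both modes so that sign information present on
either end of the match is never discarded silently.

## Building hypothesis GO-term sets

Free-text hypothesis terms are mapped to GO ids by stemmed search: each
word of the label is reduced with the original Porter (1980) algorithm and
a non-obsolete term is a candidate when every stem occurs as a substring
of its name, a synonym or its definition. The stem of "inflammation" is
"inflamm", which finds "inflammatory response" by substring. Multi-word
labels match conjunctively against one term record; disjunctive matching
floods the candidate list with noise. Selection is non-interactive: the
library returns the full candidate list, and the caller (or the CLI's
`--select-all` / index list / prebuilt HGT file) chooses. Manually known
ids can be added directly; all ids are validated (present, not obsolete)
before scoring. The resulting hypothesis/GO-id pairs round-trip through a
plain-text HGT file, one `label, GO:id, GO:id...` line per term.

```{r}
dag <- parse_obo(system.file("extdata", "toy_apoptosis.obo",
                             package = "goeffects"))
search_ontology(dag, "apoptosis")
```

## Parameters that matter

| parameter | values (default first) | meaning |
|---|---|---|
| `unsigned_policy` | `positive`, `no_effect` | effect value of cue-free GO names |
| `conflict_policy` | `positives_override`, `negatives_override`, `greater_of` | resolution of mixed +1/−1 evidence |
| `sign_from` | `original`, `matched` | which term name is parsed first on ancestor matches |
| `traverse_regulates` | `FALSE` | whether regulates-type edges join the upward walk; off because they change effect semantics rather than generalise |
| `max_depth` | `Inf` | cap on upward traversal depth |
| `scale` | `log2_ratio`, `fold_change`, `difference` | expression input scale; fold changes are log2-converted |

The defaults reproduce the packaged case study. Note the documented bias:
positive-override plus positive-unsigned defaults make the method find
more positive than negative effects; users testing inhibition hypotheses
should consider `no_effect`/`greater_of` and inspect conflict flags.

## The packaged cytokine study

`table2_fixture()` ships a transcription of a nine-cytokine / eight-
hypothesis qualitative effect matrix scored both automatically (`G`) and
by an immunologist (`M`). The annotation databases behind it are
era-specific and irrecoverable, so the fixture enters the pipeline at the
resolution stage (`ql_from_cells()`), with conflicting cells stored as the
sign pair. Under the default policies and unit weights the package
reproduces all 24 tool-side summary values, and `agreement_score()` —
the percentage of hypothesis terms whose tool and manual net effects point
the same way, zero counting as its own direction — returns 75:

```{r}
fix <- table2_fixture()
fixture_summary(fix, "G")
agreement_score(fix)
```

The two disagreeing terms (apoptosis, antigen presentation) illustrate the
method's limits: conflicting annotation evidence resolved by policy rather
than context, and expert knowledge not yet curated into the ontology. The
file-based edit step (`apply_edits()`) exists precisely for that gap.

## Synthetic data

`generate_toy_ontology()` / `generate_toy_annotations()` build seeded,
byte-reproducible fixtures: a rooted DAG of base processes where a chosen
fraction gains regulation / positive regulation / negative regulation
subtrees, and a GAF 2.2 file annotating synthetic genes to random leaf
terms. They emulate the structural features the method depends on — signed
and unsigned names, is_a chains, part_of links — but not the statistical
texture of real GO: term fan-out, annotation depth distributions, evidence
codes and inter-ontology links are all idealised. Green tests on these
fixtures validate the algorithmic machinery, not performance on any real
annotation corpus.

## Numerical and degenerate-input choices

* All arithmetic is exact integer work on QL values times double GE
  values; the only tolerance anywhere is 1e−9 in self-consistency checks
  of written TSVs.
* Duplicate gene ids in the expression file are an error (not merged);
  gene-symbol matching is exact and case-sensitive unless
  `case_insensitive = TRUE` folds both sides.
* `NOT`-qualified GAF rows are dropped entirely rather than sign-flipped;
  negated annotation has no defined sign semantics here. Evidence codes
  are recorded but never filtered on — conflicting evidence is surfaced,
  not hidden.
* Genes whose annotations are all dropped by validation keep an empty
  entry and render as undefined rows, distinguishable in code from genes
  never seen.
* Cycles in the ontology's parent graph are a hard parse error (the
  matcher assumes a DAG); alternate ids resolve to their canonical term
  everywhere.
* Empty inputs degrade gracefully: empty ontology, header-only GAF and
  zero-gene expression files all produce structurally valid empty outputs.
* Problem sizes in the test suite: oracle-equivalence runs on 100 random
  DAGs of up to 50 terms, conservation on 1000 random 3×3 matrices —
  sizes at which the brute-force oracles are still trivially checkable by
  hand if ever in doubt.

## Known limitations

Sign parsing is lexical; it cannot see context-dependent effects (the same
cytokine can promote a process in one tissue and suppress it in another).
The true-path walk generalises annotations but never specialises them.
The method presumes annotation coverage: a hypothesis whose genes are
unannotated yields undefined columns, which is information about the
ontology, not the biology. Retrieval of annotations by sequence similarity
is out of scope — annotations arrive as GAF or id-map files.
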