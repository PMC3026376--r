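# goeffects

Hypothesis-driven signed effect analysis of differential gene-expression
data with the Gene Ontology (GO).

Most GO tooling answers a discovery question — *which terms are enriched in
my gene list?* Enrichment has nothing to say when the scientist already
holds concrete hypotheses ("this treatment promotes apoptosis", "it
suppresses chemotaxis") and the process of interest involves only a handful
of genes, too few ever to reach statistical over-representation. `goeffects`
answers the reverse, hypothesis-testing question: given a set of
differentially expressed genes and a set of user-chosen hypothesis terms,
what is the direction and magnitude of the dataset's support for each
hypothesis?

## Method

For each gene *G<sub>i</sub>* with GO annotations and each hypothesis term
*H<sub>j</sub>* with an associated GO id list:

1. **Match.** Each annotated GO id of *G<sub>i</sub>* is compared with
   *H<sub>j</sub>*'s ids; failing an exact match, the search walks up the
   ontology's `is_a`/`part_of` parent DAG. This is valid under the GO's
   *true path rule*: every ancestor of an annotated term also applies to
   the gene product.
2. **Sign.** The matched term's name is parsed for effect cues:
   *positive / pro / stimulates / increases(d) / upregulates* give +1;
   *negative / anti / suppresses / inhibits / decreases(d) / downregulates*
   give −1 (e.g. "pro-B cell differentiation" → +1, "anti-apoptosis" → −1).
   Cue-free names ("regulation of apoptosis") are *unsigned* and take a
   user policy value (+1 or 0).
3. **Resolve.** The effects collected for the pair are reduced to one
   qualitative value QL<sub>i,j</sub> ∈ {+1, −1, 0, undefined}; when both
   signs occur, a conflict policy decides (*positives override*, *negatives
   override*, or the *greater of* the two counts).
4. **Summarize.** QT<sub>i,j</sub> = QL<sub>i,j</sub> · GE<sub>i</sub>
   weighs each effect by the gene's expression value, and each hypothesis
   column is totalled into Sum of Pro (Σ QT > 0), Sum of Anti (Σ QT < 0)
   and the net effect N<sub>j</sub> = Pro + Anti.

Results are written as a qualitative TSV, a quantitative TSV with the three
summary rows, an SVG bar chart of the net effects (green positive, red
negative) and a Gene Information File. A file-based edit step lets a domain
expert override individual cells — sign assignment from ontology term names
is deliberately simple, and context-dependent effects belong to the user.

## Worked example

```r
library(goeffects)

fix <- table2_fixture()   # packaged nine-cytokine study effect matrix
cfg <- scoring_config(unsigned_policy = "positive",
                      conflict_policy = "positives_override")
qs <- fixture_summary(fix, "G", cfg)
print(qs)
#> <quant_summary> 9 gene(s) x 8 hypothesis term(s)
#>             TH2 Antigen Presentation Chemotaxis Metastasis Angiogenesis
#> Sum of Pro    5                    0          7          6            6
#> Sum of Anti   0                   -1          0          0            0
#> Net           5                   -1          7          6            6
#>             T Cell Activation Cell Proliferation Apoptosis
#> Sum of Pro                  4                  6         7
#> Sum of Anti                -1                 -3        -1
#> Net                         3                  3         6

agreement_score(fix, cfg)
#> [1] 75
```

The matrix records the qualitative effects of nine differentially expressed
cytokines on eight immunological hypothesis terms, scored both by the
automated method (`G`) and by an immunologist (`M`). With unit gene weights,
the net row says the gene set supports e.g. a TH2-type response (net +5) and
chemotaxis (net +7). `agreement_score()` compares the direction of the
automated and manual net effects per hypothesis: 6 of 8 terms agree (75%);
the two disagreements (apoptosis, antigen presentation) trace to
positive-override conflict resolution and to expert knowledge not yet
annotated in the ontology.

A complete file-based run (ontology → annotations → expression → outputs)
is one call:

```r
run_pipeline(obo = "go.obo", annotations = "genes.gaf", expr = "expr.csv",
             scale = "fold_change", hgt = "hypotheses.hgt",
             out_dir = "results")
```

or from a shell via the thin CLI wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/goeffects.R", package="goeffects"))') \
  run --obo go.obo --gaf genes.gaf --expr expr.csv --scale fold_change \
  --hgt hypotheses.hgt --out-dir results
```

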