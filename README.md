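# slimfilter

Function-based filtering of short linear motif (minimotif) predictions.

## The problem

Minimotifs are short contiguous peptides (roughly 4–15 residues) that bind,
are modified by, or traffic another protein. Scanning a query protein with
consensus patterns such as `[ST]P` or `yytm` predicts candidate triples —
*source protein*, *motif*, *target protein* — but the overwhelming majority
of consensus matches are false positives, which limits the usefulness of
motif-prediction tools for bench scientists choosing candidates to test.

`slimfilter` implements a data-driven filter family for such predictions:

- **Function filters.** A predicted triple is retained only when the source
  and target protein share a Gene Ontology annotation. With GO's directed
  acyclic graph (edges run from child terms to parent terms), "share" is
  relaxed by a distance threshold *t*: the pair is retained when some source
  term and some target term have a common ancestor *c* with
  `dist(s, c) + dist(t, c) <= t` (edge counts). At `t = 0` this is exactly a
  non-empty term-set intersection. The *cellular function filter* uses the
  `biological_process` ontology; the *molecular function filter* uses
  `molecular_function`. Pairs where either protein has no annotation in the
  namespace are **not evaluable** and excluded from all totals.
- **Frequency-score filter.** A motif is retained when its expected number
  of chance occurrences in the source protein,
  `(L − k + 1) × ∏ᵢ P(class i)`, is at or below a threshold (typical values
  0.02–0.04): complex, information-rich patterns score low.
- **Either-or combination.** The combined filter retains a triple when
  either component retains it; the function side defines the evaluable
  universe.
- **Invert ("exclude") mode** swaps retained and rejected among evaluable
  triples, for users looking for *new* functions of their query protein.

Filters are evaluated by **sensitivity** (% of verified minimotifs
retained), **selectivity** (% of random negative pairs retained — lower is
better), their ratio the **discrimination ratio (DR)**, trapezoidal
**ROC/AUC** over a threshold sweep, and rank-sum or permutation
**p-values**. A seeded synthetic generator produces ontologies (OBO),
annotations (GAF 2.x), alias tables, FASTA sequences and disjoint
positive/negative pair sets with planted signal, so the entire pipeline is
testable end to end without downloads.

## Worked example

Generate a benchmark with a planted retention probability of 0.6 at
distance 1, sweep the cellular-function filter, and evaluate:

```r
library(slimfilter)

cfg <- synthetic_config(seed = 7, n_pos = 1000, n_neg = 1000)  # q = 0.6, d_pos = 1
ds  <- generate_dataset(cfg)
res <- dataset_resources(ds)

sw <- threshold_sweep(ds$positives, ds$negatives, res, filter_config(), 0:5)
print(sw, digits = 3)
#>   threshold n_pos n_neg sensitivity selectivity   dr
#> 1         0   703   722        20.3        2.49 8.16
#> 2         1   703   722        63.9       13.02 4.91
#> 3         2   703   722        72.1       34.63 2.08
#> 4         3   703   722        86.2       67.31 1.28
#> 5         4   703   722        96.6       91.41 1.06
#> 6         5   703   722        99.9       98.61 1.01

roc_from_sweep(sw)
#> roc_curve over distance : 8 points, AUC 0.757 (0.8 at one decimal)

frequency_score("[ST]P", 400)   # expected chance matches of [ST]P in a 400-mer
#> [1] 1.995
```

Reading the sweep: of the 1000 positives, 703 have annotations on both
proteins (the rest are not evaluable). At `t = 1` the filter keeps 63.9% of
verified pairs — the planted 60% plus background coincidences — but only
13.0% of random pairs, a 4.9-fold preference for true minimotifs. As *t*
grows the filter loosens: both columns climb toward 100% and the DR decays
toward 1, which is why small distance thresholds are the useful operating
range. The ROC over the sweep (selectivity as false-positive rate,
sensitivity as true-positive rate, trapezoidal rule) summarizes the family
in one number.

Real data go through the same functions: `parse_obo()`, `parse_gaf()`,
`read_alias_table()`, `read_fasta()`, `read_minimotifs()`, then
`apply_filter()` / `threshold_sweep()`. A command-line wrapper with
`filter`, `evaluate`, `simulate` and `score` subcommands is installed at
`system.file("scripts", "slimfilter", package = "slimfilter")`.

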