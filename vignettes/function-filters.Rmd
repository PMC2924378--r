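---
title: "Function filters for minimotif predictions: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function filters for minimotif predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimfilter)
```

## The filtering model

A minimotif prediction is a triple (source protein *S*, motif *p*, target
protein *T*): *p* is a short consensus match in *S*, and *T* is the protein
hypothesized to recognize it. Consensus scanning produces such triples in
vast excess over the true ones, so the package's job is to rank or cull
them using independent evidence.

The **function filter** rests on one biological assumption: proteins that
genuinely interact through a minimotif tend to participate in the same or
related processes, so their Gene Ontology annotations should be close in
the ontology graph. GO is a directed acyclic graph whose edges run from a
child term to its more general parent. Let `A(x)` be the set of ancestors
of term `x` (including `x` itself, at distance 0) with `d(x, a)` the
minimal number of edges from `x` up to `a`. For two terms we define

```
pd(s, t) = min { d(s, c) + d(t, c) : c in A(s) ∩ A(t) }
```

and for two annotated proteins the filter statistic is the minimum of
`pd(s, t)` over the cross product of their term sets. The triple is
retained when that minimum is at most the distance threshold `t`. Two
special cases anchor the semantics:

* `t = 0` retains exactly the pairs whose term sets intersect — a shared
  annotation. This identity is enforced by a dedicated test against a
  set-intersection oracle.
* If the two terms have no common ancestor at all (possible when namespace
  restriction leaves several roots), `pd` is the sentinel `Inf`. In R,
  `Inf` is an explicit, totally ordered sentinel: `Inf <= t` is `FALSE` for
  every finite threshold, never `NA`, so threshold comparisons remain total
  without a special code path.

Distances are unweighted edge counts. No information-content weighting and
no semantic-similarity measure (Resnik/Lin) is used: the filter is meant to
be a transparent, monotone-in-`t` criterion whose sweep from 0 to 5
titrates stringency.

Annotations are **not** propagated upward to ancestor terms before
filtering. Up-propagation would make every `t = 0` comparison succeed at
the root and would collapse the distinction between the basic (`t = 0`)
and expanded (`t > 0`) filters; the distance computation itself supplies
the generalization, one edge at a time.

The **cellular function filter** runs on the `biological_process`
namespace and the **molecular function filter** on `molecular_function`;
the user-facing names follow the minimotif literature's usage, and the
mapping is stated wherever the flags are documented.

## Not-evaluable pairs

A protein with no annotation in the namespace gives the filter nothing to
compare. Such triples receive the verdict `not_evaluable` and are excluded
from every denominator: totals, sensitivity and selectivity. This matches
how annotation attrition is handled when filtering real databases, where
only a fraction of source/target pairs have GO terms on both sides. The
invert ("exclude") mode swaps retained and rejected only among evaluable
triples; inverting twice restores the original verdicts.

## The frequency score

The frequency-score filter ranks motifs by sequence complexity. For a
pattern of length `k` whose position `i` admits residue class `Cᵢ`, and a
background composition `f`, the package defines

```
score(p, L) = max(L − k + 1, 0) × ∏ᵢ ( Σ_{a ∈ Cᵢ} f(a) )
```

— the expected number of chance matches in a random sequence of the source
protein's length `L`. A motif is retained when the score is at or below
the threshold; published thresholds in the 0.02–0.04 range select patterns
unlikely to occur even once by chance. The exact functional form used by
the original minimotif web tool is not published alongside its thresholds,
so this package defines the score explicitly as expected chance
occurrences — the definition is consistent with an occurrence-count-based
score and with those threshold magnitudes for short patterns in
average-length proteins — and isolates it behind `frequency_score()` so an
alternative form can be swapped in. A Monte-Carlo test checks that
empirical scan counts on uniform random sequences agree with the analytic
expectation within three standard errors.

The default background is uniform (1/20 per canonical residue), which is
reproducible and assumption-free; a user-supplied composition (e.g.
proteome-wide frequencies) is accepted anywhere a background is taken.
Non-canonical residue codes (B, J, O, U, X, Z) never match any pattern
class, which keeps scanning deterministic on real-world sequences.

## Combining filters

The either-or combination retains a triple when either component retains
it, on the rationale that the two filters see entirely different evidence
(annotation proximity vs. sequence complexity) and can complement each
other. Two design points needed a decision:

* **Evaluation universe.** The combined filter is evaluated on triples
  whose *function* side is evaluable. The frequency component cannot pull
  an annotation-less triple into the denominator; but among evaluable
  triples, a missing sequence leaves the function side to decide alone
  (`combine_either_or()` itself stays total: retained beats rejected beats
  not-evaluable). This keeps combined and single-filter denominators
  comparable in one sweep table.
* **Tie-breaking.** When several term pairs achieve the minimal distance,
  diagnostics report the lexicographically smallest (source term, target
  term) pair, making outputs byte-stable for golden tests.

Activity labels (binds / modifies / traffics) are carried through but play
no role in any filter.

## Evaluation

Sensitivity is the percentage of evaluable positives retained; selectivity
the percentage of evaluable negatives retained (lower is better); DR their
ratio, with an `NA` sentinel when selectivity is zero. The ROC for a
filter family is built from the swept (selectivity/100, sensitivity/100)
points plus the (0,0) and (1,1) anchors, deduplicated and sorted by
false-positive rate with ties by true-positive rate, and integrated by the
trapezoidal rule. Tied sweep points are handled by deterministic
deduplication rather than by adding random jitter; jitter helps plotting
libraries draw step curves but contributes nothing to the integral.
Applied to the published cellular- and molecular-function operating points,
this construction reproduces their one-decimal areas (0.7 and 0.8), which
is the package's arithmetic anchor for the ROC machinery.

Significance has two routes. `rank_test` is the one-sided Wilcoxon
rank-sum test (normal approximation with tie correction) that positives do
not score higher than negatives, where the per-pair score is the negated
minimal distance (sentinel `Inf` ranks worst) or the negated frequency
score. `permutation` shuffles labels with a mandatory seed and applies
`(hits + 1) / (n + 1)` smoothing. The two are linked through the
Mann–Whitney identity `U / (n₁ n₂) = AUC`, which the tests verify on
tie-free scores, and the permutation route is checked against exhaustive
label enumeration at 4 + 4.

Per the field's reporting conventions, printed summaries round DR and AUC
to one decimal and percentages to whole numbers; raw values are kept in
every returned object.

## The synthetic generator

`generate_dataset()` emulates the inputs the real pipeline reads: a rooted
acyclic term DAG (each term after the root draws 1–2 parents among earlier
terms), per-protein term sets, an alias table exercised by the motif
tables, uniform-random sequences with implanted motifs, and
positive/negative pair lists written in OBO/GAF/TSV/FASTA so end-to-end
runs exercise the same parsers as real data.

The planted structure is the generator's core: with probability `q` a
positive pair receives a target term within distance `d_pos` of a source
term. Planting acts on annotations, not topology — that is the mechanism
by which functionally related proteins actually come to share GO terms —
and plants by *adding* a term, never removing one, so plants can never
disturb each other when a protein serves as both a source and another
pair's target. Positive targets are drawn without replacement for the same
reason. Negatives are uniform ordered pairs resampled until disjoint from
the positives (capped at 100× the requested count), and
`disjointness_check()` re-verifies the contract.

Default study conditions: `n_pos = n_neg = 1000`, `q = 0.6`,
`d_pos = 1`. The remaining sizes are desk-scale choices made once: 300
terms and 2000 proteins keep the background coincidence rate at `t = 1`
around 10–15%, so the planted signal is visible but not trivial, roughly
matching the published sweeps' low-threshold selectivity; 3 terms per
protein and sequences of 400 residues are typical annotation and protein
sizes; 15% of proteins are left unannotated to emulate the roughly
one-third to one-half attrition real pair sets show when both proteins
must carry GO terms. With these conditions the sweep reproduces the
qualitative published shape — sensitivity and selectivity rise with `t`
while DR peaks at small `t` and decays toward 1 — and a parameter-recovery
test checks measured sensitivity at `t = 1` against
`q + (1 − q) × background` within three binomial standard errors, with the
background measured on a `q = 0` twin dataset.

What the generator does *not* emulate: real GO topology statistics
(fan-out distributions, depth profile, term counts of any particular
release), correlated annotations between interacting protein families,
evidence-code structure, or realistic amino-acid composition. Passing
tests therefore demonstrate that the algorithms are correct and recover
planted signal under controlled conditions — not that any particular
sensitivity or DR will be attained on a given release of real databases,
which are version-dependent external inputs.

## Numerical and degenerate-input choices

* RNG: the generator seeds R's global RNG once at entry
  (`set.seed(config$seed)`), making every artifact a pure function of the
  configuration; determinism is tested by double generation and
  byte-compare of written fixtures.
* Obsolete OBO terms are dropped before graph construction; annotations
  pointing at terms absent from the graph are skipped and counted.
* Edge relations default to the `is_a` backbone; `part_of` (or any label)
  is admissible by configuration, since ontology releases differ in which
  relations they ship and the distance semantics are relation-agnostic.
* Cycles in the input ontology are a hard error naming the offending
  terms; multiple roots are permitted (see the `Inf` sentinel above).
* `L < k` gives a frequency score of 0 (no windows); empty threshold
  sweeps and anchor-only ROCs integrate to 0.5 (the diagonal).
* Distance thresholds are validated against a configured range (default
  0–5, the published sweep); the range is an argument, not a constant.

## Problem sizes used in the test-suite

Unit and property tests run on DAGs of 25–120 terms, 50–200 proteins and
pair sets of 10–150; the oracle-equivalence suite checks 200 random DAGs
of up to 50 terms against exhaustive common-ancestor enumeration; the
parameter-recovery check and the acceptance script use the full default
conditions (1000 + 1000 pairs, 300 terms, 2000 proteins). These sizes were
chosen so the statistical assertions (3-SE bands, KS uniformity) have
adequate power while the whole suite stays fast enough to run habitually.

## Known limitations

* The frequency score is this package's explicit reconstruction of an
  occurrence-based complexity score; tools using a different normalization
  will rank borderline motifs differently.
* Cross-namespace comparisons are out of scope: a graph is restricted to
  one namespace and `pair_distance()` is only defined within it.
* No surface-exposure, conservation, disorder or compartment filters are
  provided; the either-or machinery would accept them, but they require
  evidence sources this package does not model.
* AND-combinations of filters are deliberately not exposed: the published
  combination design is either-or, and the monotonicity/superset
  guarantees tested here are specific to it.
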