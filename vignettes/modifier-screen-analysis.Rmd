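---
title: "Quantifying genetic modifier screens and their interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic modifier screens and their interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modnet)
```

## Scope and model

modnet implements the computational chain of a dominant modifier screen:
a sensitized tester genotype (driver + pathogenic transgene) is crossed
against candidate alleles, and each cross is quantified for suppression
or enhancement of the tester phenotype. The package covers four
statistical layers — screen quantification, ontology-term enrichment
with de-correlation, network-topology significance, and consensus
orthology mapping — plus seeded synthetic-data generators so that every
layer is testable against planted ground truth.

## Screen quantification

**Suppression percentage.** With mean eye areas `m̄_con` (driver-only
control), `m̄_tes` (tester) and `m̄_mod` (tester + modifier),

```
suppression_pct = 100 · (m̄_mod − m̄_tes) / (m̄_con − m̄_tes)
```

is 0 at the tester level and 100 at full rescue. Areas are
unit-agnostic (pixels or µm²): only ratios enter, and the statistic is
invariant to rescaling all areas by a positive constant. Values outside
[0, 100] are biologically meaningful (overshoot or worsening) and are
reported unclamped with an `out_of_range` flag rather than truncated;
`m̄_con = m̄_tes` is a degenerate baseline and raises a classed error.

**Viability and normalized lethality.** `V = observed/expected` against
the Mendelian expectation, and `(1 − V_enh/V_tes)·100` for enhancers: 0
when the enhancer leaves viability at the tester's level, 100 at
complete lethality, negative (flagged `improved`) when viability rises.

**Climbing.** A trial's climb fraction is `n_above/n_total` (flies above
the 8 cm mark within 15 s); 10 trials are run per time point, 5 time
points spaced 48 h. Curves report the mean fraction per genotype × time
point with the standard error over trials (variance with n − 1
denominator).

**Strength classification.** The published star convention (*** p <
0.001, ** p < 0.01, * p < 0.05) is mapped onto per-time-point
comparisons of a modifier's trial fractions against the tester's:
*strong* = suppressing direction with p < 0.001 at ≥ 3 of 5 time
points; *intermediate* = suppressing with p < 0.05 at exactly 2 (when
not strong); *weak* = suppressing with p < 0.001 at exactly 1, or
p < 0.05 at exactly 2 with neither below 0.01; a worsening direction
meeting any of these patterns is an *enhancer*; otherwise *none*.
Precedence is strong > intermediate > weak, so the intermediate rule
claims every exactly-two-points case and the weak two-point clause is
effectively subsumed — we kept both clauses as published rather than
invent sharper thresholds. The rule is deliberately not exhaustive: a
profile such as worsening at four time points with only two of them
below 0.001 matches no clause and classifies as *none*. We chose not to
paper over these gaps; classification is deterministic and total, and
the per-time-point p-values are always reported alongside so a reader
can see why a profile fell through.

**Group comparisons.** More than two genotypes: one-way ANOVA with
Tukey's HSD post hoc; exactly two: two-tailed unpaired Student's t-test;
genotype × time designs: two-way ANOVA with per-time-point pairwise
Welch tests, Bonferroni-corrected across the five time points. These are
ordinary model fits and are delegated to `stats::aov`,
`stats::TukeyHSD` and `stats::t.test`.

## Term enrichment with elim de-correlation

Annotations are first closed under the true-path rule (a gene annotated
to a term is annotated to all its ancestors; diamonds count once). The
universe N is the set of genes with at least one propagated annotation —
not a whole-genome list — because it is the only self-consistent choice
given the inputs and matches standard ontology-enrichment practice.

Each term is tested with the exact hypergeometric upper tail
`P(X ≥ k)` for `k` of `n` study genes among `K` of `N` universe genes
(`stats::phyper`; an exhaustive-enumeration oracle checks it in the test
suite for all N ≤ 12).

De-correlation uses the *elim* algorithm: terms are processed bottom-up
(decreasing depth, depth being the longest path from the root; ties
broken by term id for determinism), and when a term's **raw** p-value
falls below `elim_cutoff` its propagated gene set is removed from all
of its ancestors — on both the universe side (K) and the study side (k)
— before those ancestors are tested. The phrase "weighted elimination"
in the literature conflates two related algorithms (elim and weight); we
implement elim because hard gene removal at a cutoff is exactly
specifiable and reproducible, and we record the choice in the result's
metadata. `elim_cutoff` defaults to 0.01 (the conventional default for
this algorithm) and 0 disables elimination. One property worth knowing:
elimination usually *raises* an ancestor's p-value (its study genes came
through the significant child), but it is not guaranteed to — when the
eliminated set is rich in non-study genes the ancestor's K shrinks
faster than its k and the p-value can drop slightly (we observed
decreases of order 0.01 on synthetic DAGs). This is inherent to
hard-elimination schemes; the test suite asserts the properties that do
hold (raw p untouched, deepest terms tested before any elimination,
only ancestors of significant terms affected).

Multiple testing uses Benjamini–Yekutieli (`stats::p.adjust`,
`method = "BY"`), valid under the arbitrary dependence that survives
de-correlation, applied to the eliminated p-values; `significant` flags
`p_by ≤ alpha` (default 0.05), and `neg_log10_by` is provided for
plotting.

## Network topology against a random-list null

The background network is built from a typed edge table with
co-expression rows excluded, pairs normalised to `gene_a < gene_b`,
self-loops dropped, and duplicate typed records kept as parallel
records but collapsed to simple edges for metric computation. The node
universe is every gene incident to a retained edge.

For a gene list, the induced subnetwork keeps listed genes absent from
the background as isolated, flagged nodes, and both topology metrics —
mean node-degree (= 2E/N on the collapsed graph) and mean unnormalised
Brandes betweenness (each unordered source–target pair counted once) —
include isolated nodes in their denominators. A published figure may
drop unconnected genes, so the summaries report the connected-only
averages alongside; the permutation machinery uses the all-nodes
convention throughout.

The null resamples gene lists of the observed size uniformly without
replacement from the background node universe (not from an external
genome list: the test then needs nothing beyond its own inputs), induces
each subnetwork and recomputes both metrics. We report
`Z = (obs − null mean)/null sd` (n − 1 denominator), the two-sided
normal `p = 2·(1 − Φ(|Z|))` — which matches how Z/p pairs are
conventionally reported for this test — and, because metric nulls can
be skewed, the upper-tail empirical `p = (r + 1)/(n_perm + 1)`. A null
with zero standard deviation (e.g. a vertex-transitive background)
raises a classed degeneracy error rather than returning an infinite Z.
`n_perm` defaults to 1000, the customary scale for this procedure; the
full null vectors are retained in the result for inspection.

Connector expansion adds background genes adjacent to ≥ 2 list genes or
on a length-2 path between a designated seed gene and another list
gene. This is our concrete, documented stand-in for proprietary
"direct and indirect interactor" growth in commercial pathway tools; it
is flagged as such in the run report, and the count of list genes it
newly connects is monotone non-decreasing by construction. Edge weights
are carried through to exports but never enter the metrics: the
procedures we emulate state no weighting. Networks export to GraphML
(Cytoscape-compatible, with `is_list_gene`, `is_connector`,
`flagged_isolated` node attributes) and SIF.

## Orthology mapping

Candidate scores are integer algorithm-vote counts; `min_score = 2`
removes single-algorithm predictions. Filtering and mapping commute, and
coverage is monotone non-increasing in the score threshold — both are
asserted as properties in the suite. All surviving targets are kept per
source gene (screens map lists, not single best hits); maximum-score
ties are flagged ambiguous rather than resolved arbitrarily. Disease
joins are plain left joins on the human gene id, preserving sources
without hits as empty-annotated rows.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions used throughout the tests:

* **Interactome** (`interactome_spec`): per-type Erdős–Rényi over gene
  pairs — each unordered pair gains an edge of type t with probability
  `background_edge_prob · mix_t · n_active` (uniform default mix, so
  the base rate applies per pair per type) — with an independently
  densified planted module (`module_edge_prob` for every
  non-co-expression type; densifying co-expression would be invisible
  downstream since those edges are filtered out). Defaults: 300 genes,
  background 0.02, module of 15 at 0.5 — a module size and contrast at
  which degree-Z recovery is essentially certain while the background
  stays sparse, matching the screen-scale lists the pipeline targets. A
  configuration-model background (matching real degree distributions)
  is deliberately out of scope: the synthetic interactome calibrates
  the statistics, it does not replicate any database's weighting or
  degree structure.
* **Ontology** (`ontology_spec`): a rooted random DAG (each term
  attaches to one earlier term, with probability 0.3 to a second,
  creating diamonds; depth capped at `max_depth`), 1–3 direct
  annotations per gene, and a study set drawn with odds
  `planted_enrichment_odds` for genes carrying the planted term. Odds
  of 1 give a calibrated null: the planted term's hypergeometric p is
  then stochastically no smaller than uniform (upper-tail discreteness
  makes it conservative, which the calibration test accounts for).
* **Screen** (`screen_spec`): eye areas normal per genotype, truncated
  at zero by resampling (areas are physical); eclosion
  binomial(expected, p); climbing binomial(10, p_t) per trial. Defaults
  encode the study conditions: tester mean 30 vs control 100 (the
  tester eye is about 30% of wild type), tester eclosion 0.8, control
  climbing flat near 0.8 with a declining tester, ≥ 15 flies per
  genotype (default 20). Two modifier genotypes ship by default — a
  suppressor at mean 80 (true suppression 71.4%) and a strong enhancer
  at mean 15 with eclosion 0.4 (true lethality 50%) — so end-to-end
  runs exercise both directions.
* **Orthology** (`generate_orthology_table`): sources map with
  probability `mapping_rate` (default 0.9, the order of coverage such
  consensus tools achieve on screen hits); votes are drawn over 1–10
  algorithms with mid-range mass.

Real data differ in ways the generators do not model: scale-free degree
distributions and hub genes, correlated annotations beyond the DAG
structure, batch effects and truncation in eye-area measurements, and
non-binomial overdispersion in climbing counts. Passing tests therefore
demonstrate calibration and correctness of the *procedures* under their
stated assumptions, not robustness to those violations.

Each generator consumes its own RNG stream, derived from the top-level
seed by fixed offsets, with the generator kinds pinned
(Mersenne-Twister/Inversion/Rejection) so seeds are portable; identical
specs and seeds give byte-identical outputs.

## Numerical choices and degenerate inputs

* Hypergeometric and normal tails come from R's exact implementations;
  no asymptotic approximations are introduced anywhere.
* SEMs and null standard deviations use the n − 1 denominator.
* Ties: reverse-topological ties break by term id; node iteration and
  output tables are lexically ordered; network rows sort by
  (gene_a, gene_b, type) — all outputs are byte-deterministic.
* Degenerate inputs raise classed errors (`modnet_config_error`,
  `modnet_data_error`, `modnet_degenerate_error`) that the CLI wrapper
  maps to exit codes 2/3/4: equal control and tester means, zero
  expected counts, zero-variance permutation nulls, cyclic ontologies,
  malformed edge rows (reported with line numbers).
* Zero-variance climbing comparisons (all trials identical in both
  genotypes) are defined as p = 1 when means agree and p = 0 otherwise,
  so classification stays total.

## Problem sizes in the test suite

The suite runs entirely on synthetic data built at test time: oracle
equivalence on 200 random graphs of ≤ 8 nodes and exhaustive
hypergeometric enumeration to N = 12; null calibration with 200
repetitions of a 500-permutation test on a 200-gene background (list
size 30); planted-module recovery over 100 generations at the default
conditions; 300–500-repetition calibration checks for the generators.
These sizes put Monte-Carlo error comfortably inside the asserted
bands while keeping a full run in a few minutes on one core.

## Limitations

* The elim variant implemented here is the hard-removal algorithm; the
  "weight" family of soft down-weighting schemes is intentionally not
  implemented.
* Only is-a-style parent edges are modelled; part-of/regulates
  relations, semantic-similarity reduction and live ontology downloads
  are out of scope.
* The connector-expansion rule is a documented approximation to
  proprietary network-growth algorithms and will not reproduce their
  output.
* Database-derived quantities (fold enrichments, Z-scores, orthology
  coverage of a real screen) depend on interactome and orthology
  database versions; the package reproduces the procedures and their
  calibration, not version-specific numbers.
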