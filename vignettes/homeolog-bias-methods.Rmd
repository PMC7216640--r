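---
title: "Methods: quantifying homeolog expression bias in allopolyploid triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying homeolog expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadbias)
```

## The problem

Hexaploid wheat expresses most genes from a triad of homeologs, one per
subgenome (A, B, D). Two questions drive this package: how is expression
partitioned within each triad, and does a stress treatment re-partition it?
Both are questions about *compositions* — the homeolog shares, not the
absolute levels — so the analysis lives on the 2-simplex.

## Relative expression values and their aggregation

The relative expression value (REV) of a homeolog is its percentage share of
the triad's total mean TPM in one condition, e.g.
$D\% = 100\,\mathrm{TPM}_D / (\mathrm{TPM}_A + \mathrm{TPM}_B +
\mathrm{TPM}_D)$. Replicates are aggregated by the arithmetic mean of TPM
per condition before forming shares; the mean is the conventional aggregator
for TPM in triad analyses, and forming shares after averaging (rather than
averaging per-replicate shares) keeps low-count replicates from dominating
the composition.

Two numerical conventions matter:

* **Closure**: every REV record sums to 100 within an absolute tolerance of
  1e-9 — the slack of double-precision division, nothing more.
* **Zero totals**: a triad with zero total TPM in a condition has no defined
  composition; the record is omitted for that condition and logged, never
  silently set to a vertex or error-ed.

A triad counts as *detected* when its summed homeolog mean TPM exceeds
`min_total_tpm` (default 0.5) in at least one condition. Detection criteria
for triads are rarely reported precisely in the literature, so the threshold
is a first-class, logged parameter rather than a constant.

## Seven-category classification

Each composition is assigned to the nearest of seven ideal compositions
(centroids) under Euclidean distance on fractions: balanced (⅓,⅓,⅓);
dominance of one subgenome at each vertex; suppression of one subgenome at
the opposite edge midpoint. Distance is computed in the 3-dimensional
fraction space, not on the 2-D ternary plane; the two differ by a fixed
isometry up to scale, so the argmin — and therefore every label — is
identical, which the test suite verifies against a brute-force oracle.
Classification is *hard* nearest-centroid: no low-expression exclusions or
fuzzy refinements are layered on, because the downstream comparisons
(category percentages, stress-induced category changes) are defined on the
plain seven-way assignment.

Ties are possible on exact grid compositions (e.g. (75, 25, 0) is
equidistant from A-dominant and D-suppressed) and are broken
deterministically by the fixed centroid order: balanced, A/B/D-dominant,
A/B/D-suppressed. Ties have measure zero on continuous data but occur on
synthetic grids, so determinism beats sophistication here.

Ternary plot coordinates use the standard barycentric map with vertices
A = (0,0), B = (1,0), D = (½, √3/2): $x = b + d/2$, $y = d\sqrt{3}/2$ on
fractions. The map is injective on the simplex, so no information is lost in
plotting.

## Stress-induced shifts

For one homeolog, the shift statistic is the ratio of its control and stress
REVs. The rule is symmetrized — significant when
$\max(r, 1/r) \ge$ `fold_threshold` (default 1.2) — because "a ≥ 20 % fold
change" should catch increases and decreases alike; a one-sided ratio would
silently miss one direction. The threshold is inclusive (exactly 1.2 is
significant).

Zero REVs make the ratio undefined. These are tracked as their own outcome
class rather than dropped: a homeolog whose share moves between zero and a
positive value has genuinely shifted (counted significant), while a homeolog
at zero in both conditions has not (counted not significant). Summaries
report significant / not-significant / undefined counts that partition the
total, so no triad disappears from the bookkeeping.

## DEG filter, enrichment and the naive DE stand-in

The DEG rule is adjusted p ≤ α (default 0.05) and |log2FC| ≥ 1, both bounds
inclusive, reading the conventional "≤ / ≥" phrasing literally. Raw p-values
are never substituted when adjusted ones are missing — that fails loudly.

Gene-set enrichment is the exact upper-tail hypergeometric probability
(`phyper`) of the observed overlap, BH-adjusted across the tested sets with
`p.adjust`. The universe defaults to all genes in the DE table and is
configurable, since the appropriate universe is analysis-specific. No
pathway database is bundled or downloaded; sets are user-supplied two-column
TSVs.

`naive_de()` exists so the synthetic pipeline is self-contained: fold change
of pseudocounted means (pseudocount 0.5, the standard continuity
correction) and a Welch t-test on log2(count + 0.5), BH-adjusted. It is
labelled as such in its output metadata and is *not* a negative-binomial
DE model; real analyses should import a DE table produced by a dedicated
tool. Under a null NB simulation its type-I error stays at or below nominal
plus Monte-Carlo slack, which is all that is claimed for it.

## Biochemical utilities

*Percent contribution*: a solute's condition-mean molarity × 100 / total
mean molarity; scale-invariant and closing to 100 by construction.

*Solute change calls*: up when the stress/control mean ratio ≥ 1.5 **and**
t-test p < 0.05; down at ratio ≤ 2/3, symmetrically, since up- and
down-regulated solutes are reported under one rule. The rule is applied to
concentrations (not to percent contributions, which are reported alongside),
matching how such changes are described in practice. Welch's correction is
the default at n = 3 replicates, with the pooled test available as a switch.

*ΔΔCt*: fold change $2^{-\Delta\Delta C_t}$ with
$\Delta\Delta C_t = (C_t^{target,trt} - C_t^{ref,trt}) -
(C_t^{target,ctl} - C_t^{ref,ctl})$. With two reference genes (a common
design, e.g. actin plus RLI) the reference $C_t$ is their arithmetic mean
per sample. Replicates are aggregated by mean $C_t$ before differencing,
with per-replicate fold propagation available as an option. The statistic is
invariant to per-sample plate offsets, which the tests assert.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes: triads
with compositions scattered around the seven centroids, lognormal triad
abundances, negative-binomial counts over 3 replicates × 2 conditions, and
condition effects that are either shared across the triad (leaving the
composition untouched) or homeolog-specific (the only mechanism that can
change the true category).

Default parameters, chosen once as a realistic stress RNA-seq design:

| parameter | default | why |
|---|---|---|
| `n_replicates` | 3 | standard bulk design |
| `category_mix` | balanced 0.70; suppressed 0.08 each; dominant 0.02 each | balanced dominates triad surveys (~67–77 %), suppressed categories outnumber dominant ones |
| `dirichlet_concentration` | 50 | visible within-category scatter without blurring category boundaries |
| `abundance_log_mean`, `sd` | log 30, 1.2 | right-skewed TPM totals spanning ~3 orders of magnitude |
| `nb_dispersion` | 0.05 | typical biological-replicate overdispersion |
| `library_size` | 2×10⁷ | a routine bulk sequencing depth (lognormal jitter, sd 0.1) |
| `shared_effect_sd` | 1 (log2) | triad-level stress responses of a few fold |
| `homeolog_effect_prob` | 0.15 | yields category-change rates in the ~10–17 % band seen in stress studies |
| `homeolog_effect_log2` | 2 | a 4-fold homeolog-specific response, random sign |

Design details: Dirichlet parameters are floored at 0.01 × concentration for
zero centroid components (a Dirichlet with zero parameters is undefined, and
vertex categories must keep full support); at most one homeolog-specific
effect per triad (sufficient to create every single-step category
transition); its sign is random because homeolog-specific induction and
suppression both occur; counts→TPM assumes equal effective gene lengths
(homeologs are near-identical in length, and length modelling would add
nothing to what is being tested); the seed is a required argument so no run
ever depends on ambient RNG state.

The truth table records both the *drawn* category and the category of the
*realized* control composition. Recovery is scored against the latter: with
moderate concentration a draw can legitimately land in a neighbouring
category's cell, and the identifiable question is whether the pipeline reads
back the composition it was actually given.

What the simulator does **not** emulate: subgenome mapping bias, gene-length
variation, correlated noise between homeologs, batch effects, and count
distributions beyond NB. Green tests therefore demonstrate correctness of
the computations and recoverability under the stated model — not robustness
to every artefact of real wheat RNA-seq.

## Validation strategy and problem sizes

Every non-trivial computation is checked against an independent oracle:
exhaustive 7-centroid argmin for the classifier (10,000 uniform simplex
points), a brute-force reimplementation of the ratio rule for shift calls
(1,000 random pairs including exact-boundary cases), exact combinatorial
tail sums for enrichment (universes up to 30 genes), and the textbook
step-up procedure for BH. Property tests cover closure, scale invariance
(rescaling one condition's TPMs changes nothing), permutation equivariance
of the classifier, and condition-swap symmetry of shift and solute calls.
End-to-end, a 2,000-triad simulation at concentration 200 with effects off
must recover ≥ 95 % of categories with ≤ 5 % spurious category changes, and
the pipeline must be byte-identical across reruns of the same seed. These
sizes keep the full suite under a minute while leaving the statistical
assertions comfortably powered.

## Known limitations

* The detection criterion and the enrichment universe are genuinely
  analysis-specific; both are parameters, and results can be sensitive to
  them.
* Nearest-centroid classification has hard boundaries; triads near a
  boundary can flip categories under small noise, which inflates apparent
  category change at low expression. The `distance` column is exposed so
  users can filter or weight by classification confidence.
* The symmetric shift rule treats control/stress and stress/control ratios
  identically; analyses that require a directional rule should filter on
  the signed `ratio` column instead of the `significant` flag.
* `naive_de()` is a stand-in with t-test power characteristics, not an NB
  model; its purpose is pipeline plumbing on synthetic data.
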