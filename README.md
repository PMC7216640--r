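# triadbias

Homeolog expression bias analysis for allopolyploid triads.

Allohexaploid bread wheat (*Triticum aestivum*, genomes AABBDD) carries most
of its genes as **triads**: three homeologs, one from each of the A, B and D
subgenomes. A central question in polyploid transcriptomics is how expression
is partitioned within a triad and whether an applied stress re-partitions it.
`triadbias` implements that analysis for anyone with a triad table, a TPM
expression matrix and a control/stress sample sheet — plus a ground-truthed
simulator so the whole pipeline can be validated without any external data.

## The model

For a triad with homeolog mean expressions (TPM<sub>A</sub>, TPM<sub>B</sub>,
TPM<sub>D</sub>), the **relative expression value** (REV) of each homeolog is
its share of the triad total, e.g. for D:

    D% = 100 · TPM_D / (TPM_A + TPM_B + TPM_D)

The three REVs form a composition on the 2-simplex. Each triad × condition is
assigned to one of **seven homeolog expression bias categories** by
nearest-centroid classification (Euclidean distance on fractions) against the
ideal compositions

| category | (A, B, D) |
|---|---|
| balanced | (⅓, ⅓, ⅓) |
| A-, B-, D-dominant | (1,0,0), (0,1,0), (0,0,1) |
| A-, B-, D-suppressed | (0,½,½), (½,0,½), (½,½,0) |

Stress effects are called two ways:

* **REV shifts** — for a homeolog, the ratio r = REV<sub>control</sub> /
  REV<sub>stress</sub>; the shift is significant when max(r, 1/r) ≥ 1.2
  (a ≥ 20 % change in either direction). Zero REVs are tracked as an
  undefined-ratio class.
* **Category changes** — a triad whose bias category differs between
  conditions.

Supporting tools: the standard DEG filter (adjusted p ≤ 0.05 and
|log2 fold change| ≥ 1), upper-tail hypergeometric gene-set enrichment with
BH adjustment, solute percent-contribution and fold + t-test calls, ΔΔCt
qPCR relative expression, and a negative-binomial triad simulator with
Dirichlet compositions and known ground truth.

## Worked example

```r
library(triadbias)

sim <- simulate_dataset(sim_config(n_triads = 500, seed = 42))
fit <- triad_bias(sim$tpm, sim$triads, sim$sheet, tissue = "root")
fit
```

```
Homeolog expression bias analysis (tissue: root)
  500 of 500 triads detected (summed homeolog TPM > 0.5)
  balanced triads (control): 69.0%
  triads changing bias category under stress: 15.0% (n = 500)
  D% change < 1.2-fold in 67.8% of triads
```

Reading it: all 500 simulated triads pass the detection filter (summed
homeolog TPM > 0.5 in at least one condition); 69 % sit nearest the balanced
centroid under control conditions; stress moves 15 % of triads into a
different bias category; and for 67.8 % of triads the D homeolog's share
changes by less than the 1.2-fold threshold. `summary(fit)` prints the full
per-category percentages and per-homeolog shift tables, and `plot(fit)`
draws the ternary plot. With real data, replace the simulated pieces with
`read_expression_matrix()`, `read_triad_table()` and `read_sample_sheet()`,
or drive everything from a YAML config with `run_pipeline()` (also exposed
as the `inst/scripts/triadbias` command with `simulate` and `run-all`
subcommands). Since the simulation carries ground truth, `truth_report()`
scores how well the pipeline recovered it.

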