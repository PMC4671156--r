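# generank

Multi-criteria ranking, selection, and prioritisation of genes (or any
-omics features) with **desirability functions**.

After a differential-expression analysis you rarely pick follow-up
candidates on the p-value alone: fold change, expression level,
variability, correlation with nuisance programs (e.g. proliferation),
and database annotations all matter. The common practice — hard
thresholds on each statistic, intersected — discards information at
every cut, weights all criteria equally, and drops genes that miss one
threshold by a hair. (Stacking hard per-comparison cuts also compounds
false negatives: at power 0.7 per comparison, three intersected
comparisons detect a truly changed gene with probability only
0.7³ = 0.343.)

`generank` instead maps every criterion onto a continuous 0–1
*desirability* scale with one of six mapping functions —
`d_high()`, `d_low()`, `d_central()`, `d_ends()` (extreme values
desirable), `d_cat()` (categorical), `d_sigmoid()` — and combines the
per-criterion desirabilities d₁…dₙ with importance weights w₁…wₙ into
an overall desirability by a weighted geometric mean:

    D = exp( Σᵢ wᵢ ln dᵢ / Σᵢ wᵢ )

Only the weight ratios matter, a zero on any weighted criterion forces
D = 0 (an unacceptable feature cannot be rescued elsewhere), and
missing criteria are dropped with weight renormalisation so the
observed criteria keep their relative importance. Features are ranked
by D. The package also provides:

* **Hierarchical data fusion** (`fuse_experiments()`): combine
  experiment-level D's across studies with experiment weights, outer
  join on feature ID, plus an evidence-count column.
* **Sensitivity analysis** (`perturb_and_rank()`): jitter cut points
  and weights, recompute the ranking, and report top-k overlap, rank
  correlation, and per-feature selection frequencies.
* **A declarative YAML criteria configuration** with a preset
  six-criterion specification
  (`inst/extdata/breast_cancer_six_criteria.yaml`) and a command-line
  interface (`exec/generank`, subcommands `rank`, `fuse`,
  `sensitivity`, `simulate`, `validate-study`).
* **A synthetic differential-expression generator**
  (`simulate_table()`) with planted ground truth, so the whole
  pipeline is validated end to end without any download.

## Worked example

Simulate a 5,000-feature two-group experiment, rank it with the
default six criteria, and check stability:

```r
library(generank)

sim    <- simulate_table(sim_config(n_features = 5000, seed = 7))
crit   <- synthetic_criteria()
ranked <- rank_genes(sim$table, crit, comparison = "p_value")

head(ranked[, c("feature_id", "logFC", "AveExpr", "p_value",
                "Overall_D", "comparison_rank", "rank")], 6)
#>   feature_id logFC AveExpr  p_value Overall_D comparison_rank rank
#> 1     g00211  2.22   11.12 1.64e-07         1             262    1
#> 2     g00417  1.80   12.32 7.57e-05         1             437    2
#> 3     g00480  2.11   12.10 2.71e-08         1             154    3
#> 4     g00741  2.38   10.79 1.15e-10         1               9    4
#> 5     g01011 -2.38    9.81 8.00e-09         1              94    5
#> 6     g01099  2.10   13.18 5.93e-08         1             198    6

nrow(select_top(ranked, threshold = 0.7))
#> [1] 188
```

The top-ranked features max out every criterion (D = 1), yet their
p-value-only ranks (`comparison_rank`) reach into the hundreds: the
best candidates under the full set of criteria are *not* simply the
smallest-p features, which is the point of the method.

The generator plants features that are desirable by construction (DE,
highly expressed, annotated, free of the proliferation-like factor);
the full pipeline recovers all of them:

```r
recovery_benchmark(sim)[c("n_planted", "recovery", "max_p_rank_recovered")]
#> $n_planted [1] 67   $recovery [1] 1   $max_p_rank_recovered [1] 437

perturb_and_rank(sim$table, crit,
                 default_plan(crit, rel = 0.1, n_draws = 20, seed = 1))
#> Rank-stability report (20 draws, top-188)
#>   top-188 Jaccard overlap: median 0.989, min 0.979
#>   Spearman rank correlation: median 0.955, min 0.906
#>   repaired invalid draws: 0
```

So the selected list is stable under ±10% jitter of every cut point
and weight: a reassuring sensitivity analysis to report alongside the
ranking.

From the shell, the same pipeline is:

```sh
generank simulate --out sim.csv --n-features 5000 --seed 7
generank rank --input sim.csv --config criteria.yaml --out ranked.csv
generank sensitivity --input sim.csv --config criteria.yaml --out stability.json
```

Every run writes a `.provenance.json` record (resolved criteria, seed,
input digests) alongside its output, so a ranking is always traceable
to the exact criteria that produced it.

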