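---
title: "Ranking genes with desirability functions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking genes with desirability functions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generank)
```

## The problem

After a differential-expression analysis, a biologist typically has
thousands of features (probe sets, genes, proteins) and a handful of
statistics per feature: a p-value, a log fold-change, the average
expression level, the variability across samples, and whatever extra
evidence is relevant — correlation with a proliferation marker,
database annotations, and so on. The conventional way to shortlist
candidates is to stack hard thresholds (p < 0.05, |logFC| > 1, "is
expressed") and intersect. That practice discards information at every
cut, treats all criteria as equally important, and drops genes that
miss one threshold by a hair while keeping genes that scrape past all
of them.

`generank` replaces hard thresholds with *desirability functions*:
each criterion is mapped onto a continuous 0–1 scale, where 1 is
maximally desirable and 0 is unacceptable, and the per-criterion
desirabilities are combined into a single overall score used to rank
every feature.

## Mapping functions

Six shapes cover the usual situations (`d_high`, `d_low`, `d_central`,
`d_ends`, `d_cat`, `d_sigmoid`). The piecewise shapes are
Derringer–Suich-style transformations: flat at `des_min` on the
undesirable side, flat at `des_max` on the desirable side, and a
power-transformed linear interpolation in between,

$$d(x) = d_{\min} + (d_{\max}-d_{\min})
  \left(\frac{x - c_1}{c_2 - c_1}\right)^{s}, \qquad c_1 < x < c_2,$$

with `scale` $s > 0$ controlling curvature ($s = 1$, the default, is
linear). Cut points are user choices in data units — substantively
motivated (p = 0.1 as "no longer interesting") or distributional
("top 10% of average expression"), for which `quantile_cuts()` and the
`cuts_quantiles` field of `criterion()` are provided.

Conventions that matter numerically:

* **Boundaries.** At a cut point the plateau value applies (closed
  plateaus, open interpolation intervals), so every curve is
  continuous for distinct cuts.
* **Degenerate cuts.** `cut1 == cut2` collapses the interpolation to a
  right-closed step (`x >= cut` takes the high side). That reproduces
  the implicit status quo of hard thresholding — a step function to a
  binary 0/1 scale — and behaves conventionally for "p < 0.05"-style
  rules.
* **Missing data** map to missing desirabilities, never to 0: zero
  means "observed and unacceptable", whereas missing means "no
  evidence", and the two must not be conflated because zeros
  annihilate the overall score. Missingness is resolved at
  aggregation time by weight renormalisation.
* **Infinite inputs** (fold-change columns can contain ±Inf after log
  transforms) take the corresponding plateau value rather than
  erroring.
* The sixth shape, `d_sigmoid`, is a smooth logistic alternative to
  the piecewise-linear monotone maps, included for cases where a hard
  plateau boundary is unwanted; its `steepness` sign sets the
  direction and `d(midpoint)` is exactly the middle of the band.

A non-zero `des_min` (e.g. 0.2 for "not annotated to the process of
interest") deprioritises without excluding — useful when the
criterion's source (an annotation database) is incomplete.

## The overall desirability

Per-criterion desirabilities $d_i$ with importance weights $w_i$ are
combined as a weighted geometric mean:

$$D = \exp\!\left(\frac{\sum_i w_i \ln d_i}{\sum_i w_i}\right).$$

Only weight *ratios* matter (weights 20 and 10 are the same as 2 and
1). The geometric mean is chosen over the arithmetic one because a
zero on any weighted criterion forces $D = 0$: an unacceptable feature
cannot be rescued by excellence elsewhere. Implementation details:

* Computation is in log space, exponentiated once, and clamped into
  [0, 1] against rounding overshoot.
* Zeros are short-circuited before any $\ln$ is taken, so no
  $-\infty$ arithmetic leaks into the result; $D$ is *exactly* 0.
* A zero **weight** is a true off switch: the criterion is removed
  before the zero check, so `d = 0, w = 0` does not annihilate.
* Missing $d_i$ are dropped and the remaining weights renormalised
  (`effective_weights()`), preserving the relative importance of the
  observed criteria. A feature with no observed criterion gets a
  missing $D$.

The same rule applies recursively one level up: `fuse_experiments()`
combines experiment-level $D$'s across studies (microarray +
proteomics, say) with experiment weights reflecting relevance or
quality, matching features by ID with an outer join. A feature absent
from a study is missing there, so its second-level score uses the
remaining studies only, and an `evidence_count` column records how
many studies observed it.

## Ranking, selection, and ties

`rank_genes()` sorts by decreasing $D$ and breaks ties by feature ID —
an arbitrary but deterministic rule (the alternative, random
tie-break, would make reruns disagree). `select_top()` uses a strict
threshold (`Overall_D > t`) or top-$k$ with clamping.
`comparison_rank()` provides the conventional single-statistic
baseline ranking (ties share the smallest rank, `ties.method =
"min"`), with optional prefilters that mimic the usual practice of
removing low-expressed and near-constant features before ranking by
p-value. Column names are matched case-sensitively and exactly;
mismatches are configuration errors, not silent drops.

## Sensitivity analysis

Cut points and weights are judgement calls, so the stability of the
final list under perturbation is part of the analysis.
`perturb_and_rank()` jitters targeted parameters uniformly —
relatively for weights (scale-free), absolutely in data units for cut
points, with `default_plan()` sizing the cut jitter as a fraction of
each criterion's cut span — recomputes the full ranking per draw, and
reports top-$k$ Jaccard overlap with the baseline, Spearman rank
correlation, and per-feature selection frequencies. Draws that violate
an invariant (cuts out of order, negative weight) are repaired (cuts
re-sorted, values clamped) and counted, rather than discarded, which
would bias coverage toward the interior of the perturbation box. The
default $k$ is the baseline selection size at the 0.7 threshold.
Everything is reproducible given the plan seed, and the global RNG
stream is left untouched.

## The synthetic data generator

`simulate_table()` generates a two-group log2 expression matrix and
summarises it into exactly the columns the ranking consumes, with
known ground truth — so the entire pipeline is testable end to end
without downloading anything. The model, per feature $g$ and sample
$j$:

$$x_{gj} = b_g + \delta_g\,\mathbb{1}[j \in \text{group 2}]
  + \lambda_g z_j + \varepsilon_{gj},
  \qquad \varepsilon_{gj} \sim N(0, \sigma^2),$$

* $b_g$: average expression, a two-component mixture — a background
  component at the array noise floor (location 4.5, half-normal
  spread) and an expressed, right-skewed gamma component starting
  2.5 log2 units above it (40% of features). Real array intensity
  distributions are bimodal in just this way (unexpressed probes pile
  up at background), and the clear separation makes "highly
  expressed" a well-defined truth attribute instead of a knife-edge
  on a continuous scale.
* $\delta_g = \pm$ `effect_size` for a `prop_de` fraction of features
  (random sign), 0 otherwise.
* $z_j \sim N(0,1)$ is a proliferation-like latent factor;
  a `marker_frac` fraction of features load on it ($\lambda_g = 2$),
  and feature 1 is the designated marker (loading 3, never DE), so
  `marker_cor` behaves like a correlation with a proliferation marker
  gene: near ±0.95 for loaded features, noise around 0 for clean
  ones.
* Annotation is Bernoulli with background probability
  `prop_annotated`, enriched threefold (by default) among DE
  features, emulating the situation where the process of interest is
  genuinely active in the contrast.

Summary columns are computed from the simulated matrix: `logFC`
(difference of group means), `AveExpr`, Welch two-sample `p_value`
(the closed-form rowwise computation is unit-tested against
`stats::t.test`; a moderated test would also have been fine — any
valid p-value source exercises the ranking), pooled `SD`, and the
Pearson `marker_cor`. *Planted* features are those desirable by
construction: DE, highly expressed, annotated, and free of the latent
factor.

`recovery_benchmark()` runs the full pipeline and reports the
fraction of planted features inside the top of the list; its default
top-$k$ is the selection size at $D > 0.7$ (the package's selection
rule), so "recovery 1.0" means every planted feature cleared the
selection bar. Under a null configuration nothing is planted, so the
benchmark requires an explicit reference set; because the ranking is
independent of those labels, their recovery sits at the chance level
$k/n$.

**What the generator does not emulate.** Probe-level artefacts,
between-array normalisation effects, correlated gene programs beyond
the single latent factor, heavy-tailed noise, and intensity-dependent
variance. Passing the recovery and calibration tests therefore shows
the pipeline's logic is sound under a faithful but idealised null +
signal mixture; it does not certify performance on any particular
real data set.

One consequence of the latent factor is worth knowing: features
sharing $z_j$ are mutually dependent, so a pooled KS test of the
p-value histogram can reject uniformity in a factor-on null dataset
even though each individual test is valid — exactly what correlated
proliferation programs do to real p-value histograms. Calibration
properties (uniform p, 5% below 0.05, sign-balanced logFC) are
therefore stated for the exchangeable null, `prop_de = 0, marker_frac
= 0`.

## Default criteria and weights

`synthetic_criteria()` encodes the package's reference six-criterion
specification, matched to the generator's scales: p-value low-is-good
(cuts 1e-4 and 0.1, weight 1) and fold-change extremes-are-good (cuts
±0.5, ±1, weight 1) as the two key criteria; average expression and
SD high-is-good as *soft filters* (weight 0.1, floor `des_min = 0.05`
so they deprioritise but can never exclude — a filter that can
annihilate $D$ through zero-propagation is not soft); marker
correlation as a central-is-good function on the signed correlation
(plateau |cor| ≤ 0.5, weight 0.5 — equivalent to low-is-good on
|cor| but exercising the trapezoid shape); and annotation 1 vs 0.2
(weight 1; the criterion expresses a genuine biological interest, so
it gets a key-criterion weight, and it remains user-settable). The
shipped YAML preset (`inst/extdata/breast_cancer_six_criteria.yaml`)
carries the same structure for a prepared breast-cancer table, with
the cut points that are not fixed by the published criteria encoded
as data quantiles to resolve against the user's own table.

## Validation problem sizes

The shipped tests and the acceptance script exercise: mapping-function
properties on 10,000 random specifications; aggregation against an
independent brute-force oracle on 10,000 random rows (agreement within
1e-12); a strong-signal recovery run and an exchangeable-null
calibration run at 10,000 features × 2 × 10 samples; and sensitivity
analyses of 10–30 draws on tables of a few hundred to a few thousand
features. These sizes make the whole validation run in well under a
minute while leaving the binomial/KS checks enough resolution to fail
on real calibration errors.

## Known limitations

* Desirabilities are preferences, not probabilities: there is no
  uncertainty statement attached to $D$, and the method is for
  prioritising follow-up, not for declaring discoveries.
* The ranking is only as honest as the criteria; since cut points and
  weights can be tuned to push favourite genes up the list, the
  intended workflow is criteria → ranked list → validation, with the
  sensitivity module quantifying how much the list depends on the
  choices.
* Cut-point selection is not optimised from data beyond the quantile
  helper, by design.
* The hierarchical fusion joins on exact feature IDs; cross-platform
  identifier mapping is the user's responsibility.
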