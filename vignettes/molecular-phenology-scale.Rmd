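---
title: "Building and using a molecular phenology scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and using a molecular phenology scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molstage)
```

## The model

`molstage` assumes that fruit development is governed by a single latent
developmental coordinate shared across genotypes and seasons, and that
the transcriptome is a high-dimensional, noisy readout of that
coordinate. Under this assumption, replicated expression time series
from several cultivar × vintage combinations trace out one common
one-dimensional trajectory in expression space; genotype and season
contribute separate, approximately orthogonal directions of variation.
The pipeline makes that structure explicit:

1. **Screening** keeps the core set *F* of genes whose expression is
   observable, replicable and consistent across series — the genes that
   actually read out the latent coordinate.
2. **LOESS smoothing** (degree-2 local polynomials, tricube weights,
   span 0.75, replicates as separate points) removes replicate-level
   noise per gene and series before any multivariate step, which makes
   the subsequent decomposition markedly more stable than smoothing
   after it.
3. **PCA on the column-standardized smoothed matrix** (population
   moments, so the decomposition equals that of the correlation matrix)
   separates the latent coordinate from genotype and season: the
   developmental signal spreads over up to three components — one
   dominant monotone component plus weaker, typically U-shaped or
   late-acting ones — while cultivar and vintage each capture their own
   components.
4. **A Bézier curve of order 5** fit through the three stage-component
   scores gives a smooth one-dimensional model of the trajectory, and
   **30 equal-arc-length marks** along it turn the curve into a linear
   graduation: the molecular stages. Time enters only through the
   *ordering* of timepoints, never their spacing, so stages measure
   developmental progression, not calendar time.

Projection of new data uses only the frozen artifact (gene list,
standardization constants, eigenvectors, curve, marks). The
reduced-panel path imputes every unobserved core gene, per component,
with the sample's mean standardized expression over observed genes of
matching eigenvector sign — a deliberately simple rule that needs
nothing but the panel measurements and the frozen loadings.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_mean_expr` | 1.0 | RPKM-like | screening: expression presence per series |
| `max_replicate_cv` | 0.8 | — | screening: median replicate CV bound |
| `min_cross_series_corr` | 0.6 | correlation | screening: cross-series consistency |
| `min_reference_corr` | 0.5 | correlation | screening: reference-panel congruence |
| `degree`, `span` | 2, 0.75 | —, fraction | LOESS local polynomial and window |
| `n_pcs` | 6 | components | PCA pool searched for stage components |
| `k` | 5 | control points | Bézier order (degree 4) |
| `n_marks` | 30 | stages | graduation resolution |
| `s_min` | 20 | stage | late-development window for marker selection |
| `n_trees`, `max_depth`, `learning_rate`, `subsample` | 500, 3, 0.05, 1 | — | boosting for importance measures |
| sizes | 120, 60, 30, 12 | genes | reduced core-set panels (pools of 20/10/5/2 per component × sign) |

The screening thresholds are package defaults for the four filter
families the method needs (presence, noise, consistency, congruence);
they are deliberately exposed because appropriate values depend on the
expression units and sampling density of the data at hand. The LOESS
span of 0.75 with quadratic local fits matches near-weekly sampling of
10–14 timepoints: the window holds most of a series, so fitted values
borrow strength broadly while the quadratic term tracks curvature. The
window counts *points* (replicates included), not distinct timepoints.

## Component triage

Which components carry the developmental signal is decided by effect
sizes, with `pc_indices` always available as a manual override. For
cultivar and vintage the effect size is eta-squared of the component
scores. For stage we use the R² of a single cubic polynomial in the
within-series normalized timepoint, shared across all series: a
component that tracks development follows one common smooth time
profile in every series — monotone or not — whereas genotype- or
season-driven components differ between series by offsets that a shared
time profile cannot absorb. A pooled rank correlation was rejected for
this role because the second stage component is typically U-shaped over
development and its pooled Spearman correlation with time is near zero.
A component is labelled by its largest effect if it dominates by ≥ 0.1,
otherwise "mixed"; if fewer than three components are labelled "stage",
the remaining slots are filled by mixed components whose largest effect
is nonetheless stage (weak stage components explaining a few percent of
variance are expected — the third stage component on the reference data
explains ~4%), and the searched pool of components is widened when even
that fails. An error asks for explicit `pc_indices` only when no
stage-dominated component exists.

## Numerical choices

* **Standardization** uses population moments (denominator *n*)
  everywhere, to 1e-10; a zero-variance column is an error at build time
  and a warning + imputation at projection time.
* **PCA** is an SVD of the standardized matrix; explained variance from
  squared singular values; each component's sign is oriented so its
  scores correlate non-negatively with timepoint order, making "later
  development" the positive direction deterministically.
* **LOESS** is computed through a per-series linear smoother matrix
  (the smoother applied to unit responses), so all genes of a series
  share one set of local fits; this is exact because LOESS without
  robustness iterations is linear in the response. Local systems with
  replicated predictors can be rank-deficient; the fitter's
  pseudoinverse fallback is the intended behavior there.
* **Bézier fitting** is linear least squares on the Bernstein basis at
  initial parameters \((t_j - 1)/(T_\text{series} - 1)\), followed by
  two rounds of foot-point correction (re-projecting each point onto a
  dense sampling of the current curve and re-solving); the iterate with
  the lowest residual sum wins. The procedure is deterministic and
  seed-free.
* **"Evenly spaced" marks** mean equal arc length, computed on a
  ≥ 10,001-point polyline with linear inverse interpolation; spacing is
  uniform to well below 0.1%.
* **Ties** break downward: nearest-mark ties take the lower stage;
  panel ranking ties break by cluster size, then |p-corr|, then gene id.
* **Scale orientation**: if assigned stages correlate negatively with
  timepoints, curve and marks are reversed so stage 1 is the
  earliest-development end.
* **Quantiles** are linear-interpolation (type 7) throughout; Lin's
  concordance uses population moments per its original definition.
* **Serialization** writes 17 significant digits, which round-trips
  IEEE doubles exactly; the scale artifact carries a format version and
  a gene-list checksum.

## Reduced core-set construction

Per gene and stage component, *p-corr* is the Pearson correlation
between the standardized smoothed profile and the component scores
(identical in sign to the eigenvector coefficient). The candidate list
takes the strongest positive and negative correlators of each of the
three components in equal shares (~100 genes total) — a single pooled
ranking would be monopolized by the dominant component — and clusters
their profiles (1 − Pearson distance, average linkage, 20 clusters).
Panels allocate equal pools per component × sign; within a pool,
candidates come from a shortlist of the top 2 × pool-size genes by
|p-corr|, preferring populated clusters (large panels) or distinct
clusters (small panels, to avoid redundant co-expressed markers), pure
|p-corr| order for the weakest component. Restricting cluster
preferences to the shortlist matters: unconstrained cluster-first rules
can force weakly correlated genes into a pool when one co-expression
cluster dominates a sign group, and a panel is only as good as its
worst pool.

## Projection conventions

Column standardization of projected data is dataset-local (the
projected dataset's own means and population sds), matching scale
construction. This is undefined for a single sample;
`standardize = "training"` applies the frozen training constants
instead, with the caveat that cross-platform level differences then
leak into the coordinates. When *every* observed column is constant
within the dataset the centered values are exactly zero and samples map
to the mark nearest the origin, with a warning. Cross-platform
normalization beyond column standardization is out of scope: samples
processed with different pipelines should be compared on the scale with
caution.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the training design: 2 cultivars × 3
vintages × 10–14 near-weekly timepoints × 3 replicates, a latent stage
following a slow–rapid–slow trajectory in calendar time (two logistic
rises plus a gentler third one, so late development keeps progressing),
per-vintage time shifts up to ±10 days, a fixed cultivar lag, gene
archetypes (monotone up/down, transient peak, switch, pure noise)
evaluated at the latent stage on lognormal baselines, small per-gene
cultivar/vintage multiplicative offsets, and mean-preserving
multiplicative lognormal replicate noise (CV 0.15, optionally U-shaped
in stage). Transient peaks have sd 0.18 in latent-stage units so that a
pulse spans several weekly samples. For marker-selection scenarios,
`frac_stage_only` plants purely stage-driven monotone genes among
confound-driven genes whose cultivar/vintage effect magnitudes are
bounded away from zero — with unbounded Gaussian draws a sizeable
fraction of nominally confounded genes is indistinguishable from the
planted markers, which makes recovery ill-defined rather than hard.

The generator does **not** emulate: read-count sampling (profiles, not
counts), cross-platform effects, batch structure, gene–gene correlation
beyond the shared latent coordinate and archetype families, or missing
replicates. Passing tests therefore demonstrate that the pipeline
recovers planted low-dimensional structure under realistic noise — not
that it is robust to everything real RNA-seq can do.

A deliberate consequence of the design: transient or switch genes whose
active window is compressed by the rapid mid-development transition
into one or two sampling intervals are rejected by the cross-series
consistency screen (their profiles genuinely do not align across
time-shifted seasons at weekly sampling). This mirrors how a
consistency-based screen behaves on real data and is why screening
validation scenarios plant monotone trajectory genes.

## Pipeline order matters

Screening must precede scale construction. Building a scale on an
unscreened matrix leaves noise genes in the core set; they dilute the
components only mildly, but reduced-panel construction is then free to
pick noise genes whose sample correlation with a weak component is
spuriously high, and panel projections degrade sharply. All shipped
examples, tests and the acceptance script run
`screen_genes() → build_scale() → project / select`.

## Known limitations

* **Late-window marker selection is leaky.** Variable-importance
  selection in the stage ≥ 20 window conditions on the *assigned* stage,
  an integer discretization of the latent coordinate. Within a stage
  bin, time-shifted seasons sit at slightly different latent positions,
  so genuinely stage-only genes acquire a small real vintage signal and
  a fraction of them fails the vintage-importance quantile cut. Recovery
  of planted markers is therefore seed-dependent (roughly 60–90% across
  generator seeds at the default thresholds) even though false
  inclusions stay near zero.
* **Stage resolution saturates at the ends.** Conditions pile up on the
  first and last marks where development is slow; consecutive samples
  can legitimately share a stage.
* **Single-sample projection** requires training-referenced
  standardization and inherits any level differences between platforms.
* **The Bézier fit is global.** Order 5 cannot follow more than a few
  inflections; trajectories with more structure would need a different
  one-dimensional model, which is out of scope.

## Problem sizes used in validation

The test suite exercises the pipeline end to end on 300–600-gene
fixtures and the acceptance script on the full default design (2,000
genes, ~70 conditions, 3 replicates) plus a 500-gene marker-selection
scenario; these sizes preserve every structural property of the method
(six series, planted factors, all archetypes) while keeping a complete
run in the tens of seconds on one CPU.
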