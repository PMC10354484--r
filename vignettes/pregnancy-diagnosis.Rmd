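---
title: "Diagnosing gray whale pregnancy from faecal hormones and drone-measured body width"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing gray whale pregnancy from faecal hormones and drone-measured body width}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregmix)
library(dplyr)
```

## The problem

Pregnancy in baleen whales cannot be confirmed by handling the animal; the
only definitive field evidence is a calf seen the following year, which
misses pregnancies lost before calving and arrives a year late. Two
non-invasive data streams offer a way forward for Pacific Coast Feeding
Group (PCFG) gray whales:

* **fP4m** — faecal progesterone metabolites quantified by immunoassay, in
  ng of immunoreactive hormone per g of dried faeces, analysed on the
  natural-log scale. Progesterone sustains pregnancy, so pregnant females
  should excrete more of its metabolites.
* **W50** — the body width at 50% of total body length measured from drone
  images and standardized by total length (unitless). Pregnant females get
  wider through gestation.

`pregmix` implements the full analysis: quality control and annual
aggregation of both streams, reproductive-class assignment from sighting
histories, two-component normal mixture models fitted by EM, a constrained
bootstrap that turns mixture fits into per-whale pregnancy probabilities
with uncertainty, Monte Carlo propagation of photogrammetric uncertainty
into group comparisons, and confusion-matrix evaluation against whales of
known status.

## Reproductive classes

Each whale-year is assigned exactly one class from the sighting record:

| class | definition |
|-------|------------|
| `PF`  | presumed pregnant: seen with a calf the year after sampling |
| `LF`  | lactating: seen with a calf in the sampling year |
| `JF`  | juvenile: immature female |
| `MF`  | mature female of unknown pregnancy status |

Maturity is decided by age when the sighting history is informative (known
or minimum age at least 8 years, the mean age of sexual maturity), and
otherwise by the photogrammetric length posterior: mature when more than
half of a Normal(mean, sd²) posterior for total length lies above
11.7 m, the average female length at maturity. The boundary case (exactly
half) conservatively classifies as juvenile. `LF` and `JF` are pooled as
presumed non-pregnant for evaluation; `MF` truth is unknown, so those
records are excluded from performance metrics and are instead the group
the fitted models are applied to.

One convention the source data do not pin down: the length of the sighting
history is counted as `sampling year - first year` (a whale first seen in
2012 and sampled in 2020 has LSH 8). The "year after sampling" rule uses
calendar years, not a breeding-season boundary; gray whale births cluster
in January, so a calendar boundary and a season boundary disagree only for
calves first seen extremely late in the calving year.

## Preparing the two data streams

**Hormones.** Raw immunoassay readings (pg ml⁻¹, duplicate
wells) pass through: a replicate-CV flag (sample sd over mean above 15%
marks a rerun; the paper protocol reruns such assays, so surviving values
are kept by default), a dry-mass filter (below 0.02 g excluded — the
"small sample effect" inflates concentrations), substitution of readings
below the limit of detection (LOD 8.57 pg ml⁻¹) by LOD/2 *on the
raw assay scale before unit conversion*, unit conversion

\\[ \text{ng g}^{-1} = \text{pg ml}^{-1} \times \text{dilution} \times
\frac{\text{extract volume (ml)}}{1000 \times \text{dry mass (g)}}, \\]

resolution of separately-assayed same-day duplicates (keep the heavier
sample; ties break on sample id), and annual aggregation as the **log of
the natural-scale median**. The order matters for even counts: the median
of two samples is their natural-scale midpoint, then logged, so
`aggregate_annual_fp4m(exp(c(3, 5)))` is `log((exp(3)+exp(5))/2)` =
4.4338, not 4. Reconstitution at 1:1 is taken as contributing no extra
factor to the conversion; the formula above is the package's declared
convention.

**Widths.** Standardized widths arrive as posterior means and sds per
measurement (the photogrammetric calibration that produces them is outside
this package's scope). Only measurements strictly after 26 August count
("after" read strictly: the 26th itself is excluded): early-season whales
have just arrived from the fasting migration, while late-season
measurements catch pregnant females nearest late gestation. Within a
whale-year the measurement with the **maximum** W50 posterior mean is the
annual value (pregnant females widen over time), ties breaking toward the
most recent date. Total length, by contrast, is a property of the whale,
not the season, so length posteriors for maturity classification may come
from any measurement, including early-season flights.

## The mixture model

For each model the records are assumed to come from a two-component
normal mixture,

\\[ f(x) = \lambda_L\,\phi(x;\mu_L,\Sigma_L) +
           \lambda_H\,\phi(x;\mu_H,\Sigma_H), \\]

with the low component interpreted as non-pregnant and the high component
as pregnant. Model 1 is bivariate in (log-fP4m, W50) with full
covariance matrices; Model 2 uses log-fP4m alone; Model 3 uses W50 alone.
`mix_fit()` runs EM with log-space E-steps and weighted-moment M-steps.
Convergence requires the relative log-likelihood improvement to fall
below `tol = 1e-8`; the iteration cap is 2000, set generously because
heavily overlapping components separate slowly and the width data's
two-decimal ties slow the geometry further. A fit is *degenerate* when
any covariance eigenvalue falls below `1e-10` — the classic collapse of a
component onto (near-)tied points, where the likelihood is unbounded and
the "fit" meaningless.

The pregnant component is identified by **dominance**: one component's
mean must strictly exceed the other's in *every* modelled dimension.
When the bivariate fit pairs high fP4m with low W50 the labelling is
invalid — that is data, not an error, and the bootstrap discards such
replicates.

### Initialization: two protocols, used in different places

For a one-off fit (`init = "best"`), EM runs from a deterministic
rank-split start plus ten restarts seeded at random pairs of
distinct-valued data points, and the best converged, non-degenerate
log-likelihood wins. Two numerical details earn their keep here. Restart
seeds must differ in *value*, not just index: with 34 of 77 width values
tied at 0.15, seeding both components at the same value places EM on an
exactly symmetric manifold it can never leave — a saddle that "converges"
with bitwise-equal means. And random-responsibility seeding (an obvious
alternative) concentrates both components on the global moments, giving
restarts with almost no diversity.

The bootstrap uses `init = "partition"`: one random hard partition of the
records into two halves, retried only when the run fails. The reason is
empirical and important. On the joint data the likelihood surface
typically carries a dominance-*invalid* optimum with higher likelihood
than the valid one. A best-of-many protocol therefore finds the invalid
optimum systematically and the retention rate collapses (about 41% of
replicates survive); a single canonical-EM start lands in the valid basin
at the rate a standard mixture implementation would (about 61-65%),
which is also what the original analysis of this dataset reports. Since
the retained-replicate distribution *is* the scientific output of the
bootstrap, the default reproduces standard single-start EM behaviour.

### The probability of pregnancy

Two definitions are implemented:

* `responsibility` — the usual EM posterior,
  \\(\lambda_H \phi_H(x) / (\lambda_H \phi_H(x) + \lambda_L \phi_L(x))\\);
* `literal` — the plain density ratio
  \\(\phi_H(x) / (\phi_H(x) + \phi_L(x))\\), i.e. equal prior odds.

Both are evaluated in log space (never NaN, even 500 sds from both
means). The package default is **per model**: `responsibility` for the
fP4m model, `literal` for the W50 and joint models. This choice was
calibrated against the reference per-record probabilities shipped with
`gray_whale_records()`: the published fP4m-model values match the
weighted posterior almost exactly (mean absolute deviation about 0.02
across all 76 records), while the published W50-model values match the
unweighted ratio (the published probability rises past 0.9 at W50 = 0.17,
which only the unweighted form reproduces on these data — the fitted
high-component weight here is about 0.14, and weighting by it depresses
every probability by about two logits). The likely cause is rounding:
this package fits the two-decimal published widths, whereas the original
fit of full-precision widths plausibly had a larger high-component
weight, making its weighted posterior look like our unweighted one. Both
modes are available everywhere via `weighting =`.

## The constrained bootstrap

Only five PF records anchor the high component, so a plain bootstrap
would regularly lose them. `boot_pregnancy()` therefore forces the PF
records into every sample: they are held fixed once each and the
remaining `n - 5` slots are resampled with replacement from the non-PF
records (an alternative scheme that resamples everyone and appends missed
PF records is available; the hold-fixed reading is the simpler one).
Each of the 10 000 replicates is fitted; a replicate is **retained** only
if its fit converged *and* its labelling is dominance-valid; each
retained fit is evaluated at every *original* record (including records
absent from that particular sample); and the per-record probabilities are
summarised across retained replicates: mean (Model 1) or median
(Models 2-3) as the point estimate — following how the original analysis
presents them — plus 25/75 quartiles and a 2.5/97.5 percentile 95%
confidence interval, all with the linear-interpolation (type 7) quantile
convention.

A record counts as classified pregnant when its point probability is
**at or above 0.75** — inclusive, which is what the published
classifications imply.

On the packaged dataset the bivariate model retains about 61%, the fP4m
model about 96%, and the W50 model about 75-80% of replicates. The W50
shortfall relative to the >95% reported for the original data is a
rounding artifact worth understanding: after two-decimal rounding, 34 of
the 77 widths are exactly 0.15, and for roughly a fifth of bootstrap
samples *no* non-degenerate two-component optimum exists — EM (ours, and
an independent implementation checked on the same samples) can only
collapse onto the tie mass. The retained replicates are unaffected; the
artifact costs retention, not correctness.

## Monte Carlo ANOVA with HPDIs

To compare W50 across demographic units while honouring photogrammetric
uncertainty, `mc_anova()` redraws every record's W50 from
Normal(posterior mean, posterior sd²) in each of 80 000 replicates,
computes per-group means (the cell-means coding of a one-way ANOVA —
algebraically the same pairwise differences any contrast coding yields)
and all pairwise differences, and summarises with means and 95% highest
posterior density intervals. `hpdi()` returns the shortest contiguous
window of the sorted sample containing `ceiling(level * n)` points, ties
breaking toward the lowest start — so `hpdi(1:100, 0.95)` is (1, 95) by
construction. The published per-measurement width sds are not available
in the packaged dataset, so this module's validation is synthetic
recovery (calibration of the HPDI and convergence of the difference means
to their plug-in values) rather than reproduction of the original group
means.

## The synthetic generator

`simulate_dataset()` emits the three raw tables the pipeline ingests
(assays, morphometrics, sightings) plus latent truth. Its defaults *are*
the study conditions: class sizes (5 PF / 4 LF / 19 JF / 48 MF),
log-fP4m components Normal(4.60, 1.15²) for pregnant vs
Normal(4.10, 0.77²) for non-pregnant — deliberately overlapping, so
the simulator reproduces the hormone stream's real failure mode — and
W50 components Normal(0.178, 0.01²) vs Normal(0.150, 0.01²)
with 0.005 per-measurement noise. A 15% fraction of MF whale-years is
truly pregnant (about the rate the width model flags); this fraction is
also the calf-loss channel, since a pregnancy whose calf is never sighted
stays MF. Every QC path is exercised by construction: multi-sample years,
same-day duplicates, below-LOD readings, sub-threshold masses,
early-season flights.

What the generator does *not* emulate: repeat measurements of the same
whale across years (every synthetic whale-year is a new whale, so
individual-level trajectories are absent), seasonal width growth within a
year, assay plate structure, and heteroskedastic photogrammetric error
growing with altitude. Passing tests on synthetic data therefore
demonstrate correct pipeline mechanics and estimator behaviour under the
assumed distributions — not robustness to individual heterogeneity.

## Problem sizes in the test-suite

The unit suite runs bootstraps at 40-1000 replicates and the end-to-end
checks at the full 10 000; the HPDI calibration uses 10⁶ draws once
and 1000 replicates of 1000 draws; EM recovery uses n = 500. These sizes
put Monte Carlo error comfortably inside the asserted tolerances (3
standard errors wherever a closed form exists).

## Known limitations

* The packaged widths carry two decimals; consequences (retention
  ceiling, weighting calibration) are described above.
* Bivariate retention (~61%) means the Model 1 summaries average over a
  somewhat selected set of replicates; the original analysis shares this
  property.
* The 0.75 threshold and the LOD/2 substitution are conventions, not
  estimates; sensitivity to them is one pipeline call away but not
  automated.
* `MF` truth is unknowable from sightings alone: a "false positive" MF
  may be a true pregnancy that lost its calf.
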