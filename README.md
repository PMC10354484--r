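# pregmix

Non-invasive pregnancy diagnosis for Pacific Coast Feeding Group (PCFG)
gray whales from two data streams that require no contact with the
animal: faecal progesterone metabolite (fP4m) immunoassays and body
widths measured from drone images.

## Who this is for

Marine mammal physiologists and population ecologists with (i) per-sample
immunoassay tables, (ii) per-measurement photogrammetric width posteriors,
and (iii) photo-ID sighting histories, who want per-whale pregnancy
probabilities with honest uncertainty, and an evaluation of how well each
indicator actually diagnoses pregnancy.

## The method

Each whale-year is assigned a reproductive class from sightings — `PF`
(presumed pregnant: calf seen the following year), `LF` (lactating), `JF`
(juvenile), `MF` (mature, status unknown) — and two annual indicators are
built: the log of the median faecal fP4m concentration (ng g⁻¹), and the
maximum late-season standardized width at 50% of body length (W50).

Records are modelled as a two-component normal mixture

&nbsp;&nbsp;&nbsp;&nbsp;*f*(x) = λ_L φ(x; μ_L, Σ_L) + λ_H φ(x; μ_H, Σ_H),

fitted by EM, with the higher-mean component read as "pregnant". Three
models are compared: bivariate log-fP4m + W50 (Model 1), fP4m only
(Model 2), W50 only (Model 3). A constrained non-parametric bootstrap
(10 000 replicates, the few PF records forced into every sample,
replicates retained only when the fit converges *and* one component's
mean dominates in every variable) yields a per-record probability of
pregnancy with quartiles and a 95% percentile interval. Records at or
above a 0.75 probability are classified pregnant, and classifications are
scored against the known-status whales (PF vs LF∪JF) as a confusion
matrix. Photogrammetric uncertainty is propagated into group comparisons
by a Monte Carlo ANOVA (80 000 redraws of every width from its posterior)
summarized with highest-posterior-density intervals.

The headline science: fP4m distributions of pregnant and non-pregnant
females overlap too much for reliable diagnosis, while W50 separates the
groups almost cleanly — the width-only model classifies 23 of 25
known-status whale-years correctly and flags 8 additional likely
pregnancies among the unknown-status mature females.

## Worked example

The six-year PCFG dataset (111 whale-years, 2016–2021) ships with the
package:

```r
library(pregmix)
recs <- gray_whale_records()
indicator_summary(recs)
```

```
# A tibble: 4 x 9
  group n_fp4m mean_fp4m min_fp4m max_fp4m n_w50 mean_w50 min_w50 max_w50
  <fct>  <int>     <dbl>    <dbl>    <dbl> <int>    <dbl>   <dbl>   <dbl>
1 PF         5      4.60     2.8      5.73     5    0.178    0.17    0.19
2 LF         4      3.51     2.85     4.51     3    0.147    0.13    0.16
3 JF        19      4.12     2.02     5.08    17    0.15     0.13    0.18
4 MF        48      4.05     2.3      6.11    52    0.148    0.12    0.18
```

The PF row reproduces the published descriptives (mean log-fP4m 4.60,
mean W50 0.18), and already shows the story: pregnant females are ~0.03
wider (about 35 cm on a 12 m whale) but barely half a log-unit higher in
fP4m with wide spread.

Bootstrap the width-only model and inspect the unknown-status females:

```r
bw <- boot_pregnancy(recs, model = "w50", n_boot = 1000, seed = 1)
glance(bw)
tidy(bw) |>
  dplyr::filter(group == "MF", point >= 0.75) |>
  dplyr::arrange(dplyr::desc(point))
```

```
# A tibble: 1 x 7
  model n_records n_boot n_retained retention point_rule weighting
  <chr>     <int>  <dbl>      <int>     <dbl> <chr>      <chr>
1 w50          77   1000        750      0.75 median     literal

# A tibble: 8 x 7
  record_id    group point    lq    uq ci_low ci_high
  <chr>        <fct> <dbl> <dbl> <dbl>  <dbl>   <dbl>
1 Er-0018:2019 MF    0.988 0.971 0.996  0.512   1
2 Er-0096:2016 MF    0.988 0.971 0.996  0.512   1
3 Er-0323:2019 MF    0.910 0.839 0.955  0.197   1.000
4 Er-0004:2021 MF    0.910 0.839 0.955  0.197   1.000
5 Er-0332:2019 MF    0.910 0.839 0.955  0.197   1.000
6 Er-0011:2019 MF    0.910 0.839 0.955  0.197   1.000
7 Er-0268:2016 MF    0.910 0.839 0.955  0.197   1.000
8 Er-0276:2018 MF    0.910 0.839 0.955  0.197   1.000
```

`retention` is the fraction of bootstrap replicates whose mixture fit was
usable (converged, valid labelling); each retained fit scores every
record, and `point` is the across-replicate median probability with
`ci_low`/`ci_high` the 2.5/97.5 percentiles. Eight mature females of
unknown status exceed the 0.75 classification threshold — putative
pregnancies that calf counts alone would miss. `autoplot(bw)` draws the
per-record probabilities with intervals by class, and
`performance_table()` tabulates accuracy, true/false positive and
negative rates against the known-status records.

The full pipeline — from raw assay, morphometry and sighting tables to
probabilities and performance — is one call:

```r
pp <- run_pipeline(assays, morph, sightings, n_boot = 10000, seed = 1)
```

A seeded synthetic generator (`simulate_dataset()`) emits raw tables with
the study's statistical structure (overlapping fP4m components,
well-separated W50, LOD censoring, same-day duplicates, early-season
flights) plus ground truth, so the entire pipeline is testable end to
end and parameter recovery can be verified.

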