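---
title: "Methods: bulk-segregant scanning and drought-context analyses for early root growth"
author: "seedlingqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulk-segregant scanning and drought-context analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedlingqtl)
library(dplyr)
```

seedlingqtl implements the statistical core of a QTL study of early
primary-root growth in pearl millet: a bulk-segregant (BSA-seq) scan with a
Euclidean-distance allele-frequency statistic, the variant-filtering
cascade that feeds it, broad-sense heritability from line-replicated
phenotypes, root-tip growth kinematics from cell-length profiles, and
classification of seasonal soil-water trajectories into drought-stress
patterns. Every input can be simulated, so the full pipeline runs and is
tested without any external data. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish.

## The bulk-segregant scan

### Model and statistic

Two phenotypically extreme bulks (here: highest and lowest early root
growth among F2 seedlings of a biparental cross) are pool-sequenced. At a
marker, let $f_{a,H}, f_{A,H}$ be the alternate- and reference-allele
frequencies estimated from read counts in the high bulk and likewise for
the low bulk. The per-marker statistic is the Euclidean distance between
the bulks' allele-frequency vectors,

$$
ED = \sqrt{(f_{a,H} - f_{a,L})^2 + (f_{A,H} - f_{A,L})^2}
    = \sqrt{2}\,\lvert f_{a,H} - f_{a,L} \rvert ,
$$

zero for identical bulks and $\sqrt 2$ at fixation for opposite alleles.
To suppress sequencing noise and accumulate signal over linked markers,
the scan statistic is the fourth power of the ED sum in a sliding window
of 100 consecutive markers, placed at the window's midpoint marker.
Windows never span chromosomes; a chromosome with fewer markers than the
window contributes a single flagged whole-chromosome window. We read
"windows of consecutive markers" as sliding by one marker; disjoint
tiling is available via `sliding = FALSE`.

### Significance by simulation

Under the null (no linkage anywhere), bulk allele frequencies differ only
through two sampling layers: segregation sampling of $2 \times 75$
chromosomes per bulk and binomial read sampling at the site depth.
`null_threshold()` simulates unlinked genomes under exactly these layers
(depths negative-binomial with the study means of 1028X and 814X,
dispersion 0.2 by default) and returns either

* the **pooled** 95% quantile of all null window statistics (the default;
  a per-window confidence threshold), or
* the 95% quantile of each null genome's **maximum** window statistic
  (`method = "max"`), which controls the genome-wide (family-wise)
  probability of calling any false region.

The pooled threshold is self-calibrating (about 5% of null windows exceed
it); only the max-based threshold controls the rate of false *regions*,
which is why the type-I-error property is asserted on that variant.

Markers above the threshold seed regions of $\pm 8$ Mbp; overlapping
intervals merge, the peak is the strongest window (leftmost on ties), and
an external GWAS hit list can be intersected with the called regions on
closed intervals.

### Variant filtering

`filter_biallelic_parental()` retains biallelic sites where both parents
are confidently homozygous (major-allele read fraction at least 0.9 at
depth at least 5, a conventional homozygosity call made explicit here) for opposite
alleles, and re-polarizes alleles so the low-growth parent carries the
reference. `filter_frequency_depth()` then applies, in a fixed order:
multi-allelic removal; pooled bulk alternate-allele frequency < 0.25;
total depth outside the closed nearest-rank 25th–95th percentile window;
more than 50% of samples with zero depth; pooled-count minor-allele
frequency < 5%. "Total allele frequency" is interpreted as the pooled
alternate frequency across the two bulks, and both frequency filters
operate directly on read counts rather than genotype calls.

One subtlety: percentile bounds are computed from the dataset being
filtered, and the percentiles of an already-truncated depth distribution
move inward, so naively recomputing them on a second pass would remove
more sites. The calibrated numeric bounds are therefore part of the
filter's output (`filter_report()$config_used`); re-applying the cascade
with those bounds is exactly idempotent, which is the operational meaning
of "filtering twice changes nothing".

## Heritability and adjusted means

Line-replicated phenotypes follow the one-way random-effects model
$y_{ij} = \mu + \alpha_i + \varepsilon_{ij}$ with
$\alpha_i \sim N(0, \sigma^2_{line})$ and
$\varepsilon_{ij} \sim N(0, \sigma^2_{res})$. Components are estimated by
method-of-moments from the unbalanced one-way expected mean squares
($\hat\sigma^2_{res} = MS_W$,
$\hat\sigma^2_{line} = (MS_B - MS_W)/n_0$ with
$n_0 = (N - \sum_i n_i^2/N)/(k-1)$); a negative line-variance estimate is
truncated to zero and flagged. Method-of-moments is dependency-free and
exactly testable, and coincides with REML on balanced designs with
interior estimates; REML (`method = "reml"`, via lme4) is available and
used as a cross-check. Broad-sense heritability of line means is

$$
H^2 = \frac{\mathrm{Var}(line)}
           {\mathrm{Var}(line) + \mathrm{Var}(res)/\bar n},
$$

with $\bar n$ the average number of plants measured per line.

Adjusted (least-squares) line means for multi-environment data fit
`value ~ line + year:block` by OLS and average predictions with equal
weight over the *observed* year-by-block cells; inestimable combinations
under rank deficiency are dropped with a warning. Trait relationships use
Pearson correlation on pairwise-complete lines.

```{r h2-demo}
panel <- simulate_panel_phenotypes(n_lines = 122, plants_per_line_mean = 7,
                                   var_line = 1, var_res = 1, seed = 42)
variance_components(panel)
```

## Root-tip kinematics

Cell walls are detected as prominent local maxima of a cell-wall-stain
intensity profile traced from the quiescent center (plateaus resolve to
their leftmost sample; of two walls closer than the minimum separation
the higher is kept). Consecutive walls give cell lengths; each cell sits
at the midpoint between its walls, with the first wall as origin. Cell
length versus distance is summarized by the four-parameter logistic

$$
l(x) = l_{min} + \frac{l_{max} - l_{min}}{1 + e^{-k (x - x_0)}} ,
$$

fitted by bounded Levenberg–Marquardt least squares with data-driven
starts (5th/95th length percentiles for the asymptotes, the distance at
half-range for $x_0$, the central slope for $k$). A lower-asymptote curve
through zero is wrong for meristems, whose initial cells have nonzero
length; a three-parameter variant that pins $l_{min}$ at the positivity
floor is available. The floor is 0.1 µm and scales down automatically if
the data arrive in larger units. Non-convergence is reported as a flag,
never an exception; downstream rate computation then either errors or
falls back to the observed 95th length percentile, as requested.

Under steady-state growth, cell production (cells/day leaving the
meristem) is the externally measured root elongation rate divided by the
mature cell length, taken as the fitted asymptote $l_{max}$ (the observed maximum is the
documented fallback). Two lines can thus share a
production rate while differing in elongation rate purely through mature
cell length — the contrast between the slow- and fast-growing parents.

```{r kinematics-demo}
fit <- fit_logistic(simulate_cell_profile(noise_sd = 0, seed = 1))
tidy(fit)
kinematic_rates(fit, elongation_rate = 2000)$cell_production
```

## Water-stress patterns

A single-layer bucket turns daily rain into the fraction of transpirable
soil water: $FTSW_t = ATSW_t / TTSW$, with transpiration at full demand
above the 0.3 onset and declining linearly to zero below it, and the
store clamped to $[0, TTSW]$. Exact water conservation (rain =
transpiration + drainage + storage change) is asserted to $10^{-9}$ mm.

Sowing is the first day the available store reaches 10 mm. A constant
deep bucket makes this rule degenerate — 10 mm is far below 0.3 of any
deep profile, so every establishment window would be "stressed". The
generator therefore offers the standard crop-model mechanism: the rooted
capacity ramps linearly from a 25 mm sowing horizon to the full 100 mm
profile over 40 days from sowing, rain infiltrating past the rooted zone
is held in an unrooted reserve and recovered pro rata as roots deepen,
and demand develops in proportion to the rooted fraction. With growth
disabled (the default) the recurrence reduces exactly to the constant
form above.

The rainfall generator is an abrupt-monsoon stand-in for a Sahelian
station, not a calibration: a wet-day Bernoulli chain (gamma depths,
mean about 12 mm) that switches on at a season onset day drawn per year
(mean day 55, SD 12), persists for a drawn length (mean 125 d, SD 15) at
wet-day probability 0.45, plus rare isolated pre-monsoon storms
(0.003/day). Those "false starts" can trigger sowing weeks before the
reliable rains and are the chief source of early rain gaps. These values
were chosen once for a qualitatively Sahelian mixture of outcomes
(roughly a third of seasons with early stress, a fifth to a third with
terminal stress over long simulations) and are not tuned to any station
record.

Seasons are classified from sowing, on days-after-sowing series:
**early stress** if FTSW drops below 0.3 on any day before panicle
initiation, otherwise **late stress** if it does so between flowering
and maturity, otherwise **no stress**. Stress confined to the
panicle-initiation-to-flowering window counts as early by default
(`mid_window`); the boundary treatment is configurable. Demonstrations
use a 120-day cycle (panicle initiation 40, flowering 75, maturity 120
days after sowing). Season trajectories are clustered by average-linkage
hierarchical clustering on pairwise dynamic-time-warping distances
(symmetric steps, absolute-difference cost, no warping window), with the
cluster count chosen by mean silhouette over 2–6 — silhouette stands in
for the multi-index vote of the original cluster-number procedure, which
is not available here. Identical seasons give an undefined silhouette
and collapse to a single flagged cluster. Frequencies and
baseline-relative yield/biomass penalties per label come from
`stress_impact()`.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the analyses
assume, at the study's design scale:

* a 737-individual F2 cross between fully homozygous opposite parents
  over seven chromosomes, recombining under the Haldane map function
  with no interference (Haldane is the minimal standard meiosis model);
* phenotypes $\sum_q a_q (d_q - 1) + \delta_q 1\{d_q = 1\}$ plus
  Gaussian noise; 10% tails of 75 plants per bulk, ties broken by
  individual index with the low bulk filled first;
* pooled sequencing with negative-binomial site depth (mean 1028X/814X,
  dispersion 0.2 — GBS depth is overdispersed; dispersion 0 gives
  Poisson) and sequencing error (0.001) folded into the binomial read
  success probability, with equimolar contribution of individuals to
  the pool assumed;
* a 122-line phenotyping panel with Poisson plants per line (mean 7,
  minimum 1); year and block effect SDs default to zero because the
  heritability model is one-way — they are switched on explicitly for
  adjusted-means demonstrations;
* logistic cell-length profiles laid end to end from the quiescent
  center, so recorded distances are exactly cumulative lengths;
* 21-season batches of daily rainfall driving the bucket model.

What passing tests do **not** show: real GBS data have alignment and
calling artifacts, linked selection, and segregation distortion that the
binomial/negative-binomial model does not produce; real meristems deviate
from a clean logistic (vacuolation, oblique walls); and the weather
generator shares only the gross phenology of a Sahelian season with any
real station series. Results on synthetic data validate the estimators
and their calibration, not the biology of any particular dataset.

## Numerical choices and problem sizes

* Percentiles in the depth filter use the nearest-rank definition with a
  closed retention interval, so a degenerate (all-equal) depth
  distribution removes nothing.
* Window statistics use per-chromosome cumulative sums; the brute-force
  double loop is kept in the test suite as the oracle and the two agree
  to machine precision on instances up to 500 markers.
* Null thresholds use quantile type 7 on pooled (or per-genome-maximum)
  statistics; thresholds are deterministic given the seed.
* Region merging works on 1-based closed intervals; touching intervals
  merge; peak ties resolve leftmost.
* The logistic fit caps at 200 Levenberg–Marquardt iterations; the
  degenerate constant profile short-circuits to an unconverged result.
* DTW is exact dynamic programming ($O(nm)$); the enumeration oracle in
  the tests covers all binary series up to length 5.
* Test and demonstration problem sizes — 2,000 markers per chromosome,
  500 null simulations, 100 QTL-recovery replicates, 200 seeds per
  heritability grid cell — were chosen so the complete suite exercises
  every calibration claim at meaningful Monte-Carlo precision while
  remaining a routine desktop run.

## Known limitations

* The ED scan assumes biallelic markers after filtering; multi-allelic
  information is discarded.
* Markers with zero depth in either bulk are excluded from the scan
  rather than imputed (the count is logged).
* The null simulation treats markers as unlinked, which is conservative
  for window sums over linked nulls at high marker density.
* Method-of-moments heritability can truncate at zero in low-signal
  designs; the truncation is flagged and REML is available.
* The bucket model has one layer and no runoff partition, phenology is
  fixed rather than thermal-time-driven, and yield summaries in the
  demonstrations use transpiration-based proxies — it contextualizes
  root-growth QTLs, it does not replace a crop model.
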