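# seedlingqtl

Mapping early primary-root-growth QTLs in pearl millet from
bulk-segregant sequencing, and placing them in their drought-stress
context.

Pearl millet is sown in the Sahel on the first rains; a seedling whose
primary root grows fast enough to track the wetting front survives the
rain gaps that follow. This package implements, as tested reusable R
functions, the bespoke computations of a study of that trait:

* **BSA-seq scan** — the Euclidean-distance allele-frequency statistic
  between phenotypically extreme bulks,
  `ED = sqrt((fa_H − fa_L)² + (fA_H − fA_L)²)`, smoothed as the fourth
  power of the ED sum over 100-marker sliding windows, with a
  simulation-based significance threshold, ±8 Mbp region calling, and
  intersection with an external GWAS hit list.
* **Variant filtering** — the cascade feeding the scan: biallelic sites
  segregating between homozygous parents (re-polarized so the
  low-growth parent carries the reference allele), then multi-allelic /
  pooled-AF < 0.25 / depth-percentile (25th–95th) / missingness > 50% /
  MAF < 5% removal with a per-step report.
* **Heritability** — one-way random-effects variance components
  (method-of-moments, REML optional) and
  `H² = Var(line) / (Var(line) + Var(res)/n̄)`, plus least-squares
  adjusted line means and trait correlations.
* **Kinematics** — cell-wall detection in root-tip intensity profiles,
  logistic fits `l(x) = l_min + (l_max − l_min)/(1 + exp(−k(x − x0)))`
  to cell length vs distance from the quiescent center, and cell
  production = elongation rate / mature cell length.
* **Stress patterns** — a soil-water bucket (FTSW, stress onset 0.3),
  sowing and rain-gap rules, dynamic-time-warping clustering of
  seasonal FTSW trajectories, early/late/no-stress classification
  anchored to phenology, and frequency/penalty summaries.
* **Synthetic data** — generators for every input at the study's scale
  (737 F2s, 75-plant bulks, 1028X/814X pooled depths, a 122-line
  panel, logistic cell profiles, monsoon rainfall), so the whole
  pipeline is testable offline.

All user-facing functions take and return tibbles (or small classed
objects with `tidy()`/`glance()`/`autoplot()` methods) and chain with
the pipe.

## Worked example: scan a simulated cross

```r
library(seedlingqtl)

map <- genetic_map(millet_chromosomes(2), markers_per_chrom = 1500)
qtl <- data.frame(chrom = "chr1", pos_bp = 145e6,
                  additive = 0.97, dominance = 0)   # ~0.8 phenotype SD
des <- cross_design(n_f2 = 737, tail_fraction = 0.10, bulk_size = 75,
                    qtl = qtl, residual_sd = 1)
sm  <- sequencing_model()            # 1028X / 814X, NB dispersion 0.2

pop     <- simulate_f2_population(map, des, seed = 1)
phe     <- simulate_phenotypes(pop, des, seed = 2)
bulks   <- select_bulks(phe, des)
markers <- simulate_pooled_reads(pop, bulks, sm, seed = 3)

windows <- markers |>
  filter_biallelic_parental() |>
  filter_frequency_depth() |>
  allele_frequencies() |>
  euclidean_distance() |>
  windowed_statistic(window = 100)

thr <- null_threshold(des, sm, n_markers = 1500, window = 100,
                      n_sim = 500, q = 0.95, method = "max", seed = 4)
call_regions(windows, thr, flank = 8e6,
             chrom_lengths = c(chr1 = 290e6, chr2 = 250e6))
#> # A tibble: 1 × 6
#>   chrom   start       end  peak_pos peak_stat n_significant_markers
#>   <chr>   <dbl>     <dbl>     <int>     <dbl>                 <int>
#> 1 chr1  5823333 285530000 142390000 77187321.                   955
```

One region is called, on the chromosome carrying the simulated QTL and
none elsewhere; its peak window sits at 142.4 Mbp, about 1.6 cM from the
true locus at 145 Mbp, and the family-wise threshold (6613 on this
genome) keeps the second, QTL-free chromosome clean. The interval is
wide because every significant marker contributes ±8 Mbp and this strong
signal recruits 955 significant windows. `autoplot(windows, threshold =
thr, regions = ...)` draws the scan.

Heritability from a simulated 122-line panel:

```r
panel <- simulate_panel_phenotypes(n_lines = 122, plants_per_line_mean = 7,
                                   var_line = 1, var_res = 1, seed = 42)
variance_components(panel)
#> Variance components (mom): Var(line) = 1.065, Var(res) = 1.002
#>   122 lines, 6.99 plants/line on average; H2 = 0.881
```

Real data enter through `read_variants()` (VCF with per-sample `AD` for
the two bulks and two parents) and plain data frames of phenotypes,
intensity or cell-length profiles, and daily weather; see the methods
vignette (`vignettes/seedlingqtl-methods.Rmd`) for the models,
assumptions and limitations.

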