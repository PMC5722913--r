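# elongrate

Genome-wide inference of RNA polymerase elongation rates (transcription
speeds) in bacteria from three steady-state observables: per-gene mRNA
level, RNAP occupancy along the genome, and mRNA half-life.

Direct measurements of transcription speed (run-on or shut-off time
series) are limited to long transcripts and need dedicated experiments.
At balanced growth, however, the polymerase load on a gene, the mRNA pool
and its decay are in equilibrium, and the elongation rate follows
algebraically from quantities that are routinely measured. `elongrate`
implements that model together with the normalization, validation and
downstream association analyses a genome-wide speed study needs, and a
synthetic-data generator with known ground truth so the whole pipeline is
testable end to end.

## The model

For a gene of length *l* (nt), with mRNA level *n*<sub>r</sub>, mRNA
half-life *λ* (s) and RNAP density *d*<sub>p</sub> (the fraction of the
gene coverable by 40-nt elongating footprints):

- **Promoter activity** (initiations/s, all promoters feeding the gene):
  *a* = *n*<sub>r</sub> (1 − 0.5<sup>1/λ</sup>) — at steady state the
  mRNA synthesised per second equals the share of the pool that decays
  per second.
- **Polymerase count**: *n*<sub>p</sub> = (*l* / 40 nt) *d*<sub>p</sub>.
- **Elongation rate**: *v* = *a* · 40 nt / *d*<sub>p</sub>
  (equivalently *a l* / *n*<sub>p</sub>), in nt/s.

Array units are arbitrary, so raw speeds are defined up to a factor; the
scale is fixed at a reference gene of externally known speed (default
49.5 nt/s). Regulation delays along an operon accumulate as
delay<sub>k</sub> = Σ<sub>i≤k</sub> *l*<sub>i</sub>/*v*<sub>i</sub>, and
a single per-cell total (e.g. 1300 transcribing RNAP) converts both
measurement scales into absolute molecule counts.

Around this core the package provides: tiling-array processing
(quantile normalization, strand-max selection, median scaling,
running-quantile background subtraction, probe-to-gene aggregation);
validation of the steady-state assumption against promoter-reporter
time series; an independent clearance-lag grid optimizer for decay time
series with a zero-intercept agreement fit; codon-usage features
(positional GC, wobble-pairing classes) with a Spearman /
Mann-Whitney / Benjamini-Hochberg statistical battery and delay-based
regulation-order prediction; and random-forest speed estimation that
needs no half-life data.

## Worked example

Simulate a 120-gene genome, observe it with 10% multiplicative noise,
and run the estimator:

```r
library(elongrate)

genome <- generate_genome(120, seed = 1)
truth  <- generate_truth(genome, seed = 2)
obs    <- generate_observables(genome, truth, noise_cv = 0.1, seed = 3)

speeds <- obs$measurements |>
  transcription_speed() |>
  scale_speeds(reference_gene = "g0001",
               reference_speed = truth$true_speed[1]) |>
  filter_genes(min_rnap_signal = 0) |>
  regulation_delay(genome)

dplyr::select(speeds, gene, activity, n_p, v, delay)[1:5, ]
#> # A tibble: 5 × 5
#>   gene  activity   n_p     v  delay
#>   <chr>    <dbl> <dbl> <dbl>  <dbl>
#> 1 g0001  0.00302 7.28   2.30 2540.
#> 2 g0002  0.147   7.20  20.9    51.5
#> 3 g0003  0.0101  0.817 12.2    85.2
#> 4 g0004  0.0208  3.76   1.89  276.
#> 5 g0005  0.0337  1.32  63.2   754.
```

Each row gives the inferred initiations per second (`activity`), the
polymerase count on the gene (`n_p`), the scaled elongation rate in nt/s
(`v`) and the seconds from initiation at the operon promoter to a
complete transcript (`delay`). Against the hidden truth, the median
relative speed error under this noise level is ~11%; with
`noise_cv = 0` the recovery is exact to machine precision. Anchoring on
1300 transcribing polymerases per cell converts the arbitrary units into
molecule counts:

```r
molecule_census(speeds, total_rnap = 1300)
#> Molecule census (anchored on total rnap per cell)
#>   genes: 120
#>   total transcribing RNAP: 1300
#>   total mRNA molecules:    1897
```

`stationarity_robustness()`, `clearance_lag_fit()` and
`zero_intercept_fit()` validate the model's assumptions;
`codon_features()` + `association_battery()` relate speeds to sequence
features; `cv_train()` estimates speeds without half-life data;
`run_pipeline()` composes the probe-level stages from raw tracks to the
speed table. Result objects have `tidy()`/`glance()` and `autoplot()`
methods.

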