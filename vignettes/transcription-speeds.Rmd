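---
title: "Inferring transcription elongation rates from steady-state data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription elongation rates from steady-state data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elongrate)
```

## The model and its assumptions

At balanced growth a gene's polymerase load and mRNA pool are at
equilibrium. Three identities then connect the elongation rate *v*
(nt/s) to steady-state observables:

1. The average headway between polymerases on a gene is *d* = *l*/*n*~p~
   (gene length over polymerase count), and also *d* = *v*/*a* — the
   distance one polymerase travels before the next initiation. Hence
   *v* = *a·l*/*n*~p~.
2. The polymerase count follows from the occupancy density:
   *n*~p~ = (*l*/footprint)·*d*~p~, with a 40-nt elongating footprint,
   giving the equivalent form *v* = *a*·footprint/*d*~p~. Both routes
   are algebraically identical; the test suite asserts their numerical
   agreement to machine precision.
3. The promoter activity (initiations/s, cumulative over all promoters
   feeding the gene) comes from the steady-state balance of synthesis
   and decay: the fraction of the pool surviving one second is
   0.5^1/λ^, so *a* = *n*~r~(1 − 0.5^1/λ^) with the half-life λ in
   seconds. For λ ≫ 1 s this approaches the familiar *n*~r~·ln2/λ.

The assumptions that matter:

- **Stationarity** of the mRNA pool over the measurement. The
  reporter-based robustness analysis below quantifies how much this
  assumption can be violated before rankings degrade.
- **A common platform** for mRNA level and RNAP density, so linear
  measurement bias (e.g. GC bias) cancels in the ratio.
- **A meaningful density unit**: *d*~p~ enters as "fraction of the gene
  coverable by 40-nt footprints". Arrays deliver arbitrary units, so
  speeds inherit an unknown factor; see *Scaling* below.

Genes with *d*~p~ = 0 have an undefined (not zero) speed and are
excluded; the analysis filter additionally requires a background-
corrected unscaled RNAP signal strictly above 0.5, below which the
density is measurement noise.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `footprint` | 40 | nt | elongating RNAP footprint; speeds are linear in it |
| `reference_speed` | 49.5 | nt/s | external anchor speed of the reference gene at the growth condition modeled (60 min/doubling) |
| `window`, `quantile` | 30000, 0.10 | nt, — | running-quantile background of the RNAP track; wide enough not to erode long transcription units |
| `min_rnap_signal` | 0.5 | a.u. | strict floor on unscaled corrected RNAP signal |
| `total_rnap` / `total_mrna` | 1300 / 2400 | molecules | per-cell anchors for the molecule census |
| `grid` | 1–90 by 1 | nt/s | candidate speeds for the clearance-lag fit |
| `lambda_gfp`, `dt` | 360, 840 | s | reporter-mRNA half-life and reading interval of the reporter experiment |

## Scaling and the molecule census

Raw speeds are defined up to one factor, fixed by `scale_speeds()` at a
reference gene (ranks are untouched). A second, independent check is the
census: anchoring Σ*n*~p~ at a per-cell total of transcribing RNAP fixes
the density unit, after which the absolute mRNA count per gene follows
from the speed model and sums to a per-cell mRNA total that can be
compared with physiological expectations — or vice versa with an mRNA
anchor. The census is our reconstruction of how such absolute totals can
be obtained from relative array data; it presupposes reference-scaled
speeds and is reported as both totals so the direction of anchoring is
explicit.

## Validating stationarity with reporter series

Promoter–GFP reporter experiments read fluorescence and OD every 14 min
for 54 readings. GFP is stable but its mRNA is not (half-life ≈ 6 min),
so a fraction *f* = 0.5^Δt/λ~gfp~^ ≈ 0.198 — about 20% — of each step's
fluorescence gain is inherited from the previous step.
`stationary_activity()` simply scales the OD-normalized gain by (1 − *f*);
`nonstationary_activity()` instead subtracts *f* times the lagged gain
explicitly, which at lag 1 inverts the reporter kinetics exactly.

For larger lags we keep the carryover fraction at *f* and take the
increment from the lag-th preceding reading. This emulates a sparser
time series in which fluctuations between consecutive readings are
larger, and produces the diagnostic behaviour one wants: rank agreement
with the stationary estimate decreases as the correction becomes staler.
(Decaying the carryover as 0.5^lag·Δt/λ^ instead would make the corrected
estimate converge to the raw rate — which is exactly proportional to the
stationary estimate — so the comparison would trivially improve with
lag and carry no information; the `carryover` argument exposes that
limit for completeness.) `stationarity_robustness()` reports the
per-reading Spearman correlation across promoters for each lag; on a
synthetic cohort of 1920 promoters with smooth activity drift and 5%
noise it stays above 0.98 at lag 1, reproducing the robustness the
production table relies on.

## The clearance-lag optimizer

After initiation stops, a gene's log-abundance stays flat until the last
pre-stop polymerase clears the gene — the clearance lag, distance from
the operon promoter to the gene's 3' end divided by the speed — and then
falls linearly. For each candidate speed on the grid the lag is imposed
per gene and we fit an intercept plus a slope on max(0, *t* − lag),
scoring the candidate by the mean R² across the operon's genes (ties
break toward the smaller speed; operons need ≥ 3 genes to constrain the
lag usefully).

We deliberately score the **plateau-then-line model over all
timepoints** rather than a line over only the post-lag points. The
line-only score is degenerate on clean data: any candidate at or below
the true speed selects only post-clearance points, fits them perfectly,
and scores R² = 1, so the optimum would be undefined exactly when the
data are most informative. The broken-line score is uniquely maximized
at the true lag (noise-free) because an extrapolated decay line and the
plateau level disagree at the breakpoint whenever the lag is wrong, and
it degrades gracefully under noise. Candidates that leave a gene with
fewer than two post-lag points are excluded; an optimum at the edge of
the feasible candidate range is flagged (`at_boundary`) since the truth
may lie outside the grid or beyond what the sampling window resolves.

Agreement between the model route and the optimizer route is summarized
by `zero_intercept_fit()`: slope Σ*xy*/Σ*x*², with a 95% CI from the
no-intercept standard error on *n* − 1 degrees of freedom. On noise-free
synthetic cohorts the CI encloses 1.00, with deviations bounded by the
1 nt/s grid.

**Sampling windows.** The package default decay sampling (0–480 s every
30 s) mirrors a short half-life time series. For clearance fitting of
whole cohorts the tests and the acceptance script sample every 60 s to
1800 s, so that the slowest operons considered (5 nt/s across ~7.5 kb)
clear within the window; a window that censors a gene's decay leaves its
speed unidentified from that series.

## The synthetic-data generator

The generator is the package's test bed and defines what "recovery"
means:

- **Genome**: operons of 1–6 genes (monocistronic majority, mean ~1.9),
  gene lengths log-uniform on 200–6000 nt, random strand per operon,
  non-overlapping placement, 1-based inclusive coordinates.
- **Truth**: speeds log-uniform on 1–90 nt/s (optionally one speed per
  operon), activities log-normal around 0.02 initiations/s, half-lives
  log-normal around 300 s — typical bacterial scales.
- **Observables**: the model inverted exactly (*n*~r~ = *a*/(1 − 0.5^1/λ^),
  *d*~p~ = *a*·40/*v*), then independent multiplicative log-normal noise
  with unit mean and stated CV on *n*~r~ and *d*~p~; half-lives are
  noise-free by default, treating half-life as a stable mRNA property.
  Probe tracks tile both strands every 25 nt (typical tiling density)
  with configurable background, smooth sinusoidal drift and per-probe
  noise, so the normalization stage is exercised.
- **Reporter series**: the two-compartment reporter kinetics above,
  with logistic OD growth (60-min doubling, saturating) and smooth
  per-promoter activity drift; the pool starts at the steady state of
  the initial activity.
- **Decay series**: plateau until distance/speed, then exponential decay
  with the gene's half-life.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: polymerase traffic and collisions,
supercoiling feedback, ribosome coupling, probe-specific affinity
differences, cross-hybridization, abortive initiation, and operon-
internal promoters or terminators that decouple a gene's activity from
its operon's.

## Statistical battery and downstream analyses

Codon features are computed over sense codons only (stop codons excluded
from numerator and denominator): relative frequencies of the 61 sense
codons and GC at each codon position. Wobble classes derive from an
explicit tRNA anticodon inventory — G34 also reads third-position U, U34
also reads G, A34 is treated as inosine (reading C and A in addition to
U), C34 pairs strictly — because published classifications depend on the
assumed anticodon inventory, it is an input, not a constant. Codons read
only through wobble pairing form the `strict` class; codons with both
wobble and Watson-Crick readers the `mixed` class.

All correlations are Spearman with two-sided p-values; group contrasts
use the Mann-Whitney U test; families of tests are Benjamini-Hochberg
adjusted with significance at adjusted p ≤ 0.05. Regulation-order
prediction assigns interval labels by delay rank while preserving the
observed class sizes, since calculated delays match observed intervals
only up to a scaling factor; the confusion matrix therefore has matching
margins by construction.

The random forest predicts speed from CAI, tAI, GC1, GC3, length,
z-scored mRNA level, RNAP density and the mRNA/RNAP ratio (only the
mRNA level is z-scored), with library-default forest parameters and
5-fold cross-validation stratified on speed quartiles by a seeded
shuffle. Reported are the mean out-of-fold R², the pooled RRSE
(√(Σ(y−ŷ)²/Σ(y−ȳ)²); predicting the mean gives exactly 1), and the
forest's internal importance averaged over folds. On data generated from
the speed model itself the measurement-derived features dominate the
importance ranking, as expected when speed is a function of level and
density.

## Numerical choices and degenerate inputs

- Quantile normalization resolves ties by the mean of tied ranks
  (via limma); it is idempotent on its own output.
- The running-quantile background uses a centered window in nt,
  truncated at track edges, computed over the probes present; an empty
  window passes the value through. Results are floored at 0.
- Probe-to-gene aggregation is the arithmetic mean over in-gene probes
  (median available); genes with no probe are omitted, with a warning.
- Operon delays come from annotation order, never input row order; a
  gene with undefined or zero speed makes its own and all downstream
  delays NA.
- Filters use strict inequalities (a signal of exactly 0.5 fails; a
  density of exactly 1.8% fails the nascent-share rule).
- All generators accept a seed and are bit-reproducible given it; the
  caller's RNG state is restored afterwards.

## Problem sizes

The test suite and the acceptance script run on deliberately compact
instances chosen to exercise every code path while remaining quick on a
single CPU: genomes of 25–500 genes, reporter cohorts of 150 promoters
(1920 — the full experiment size — for the headline robustness check),
clearance cohorts of 1–20 operons with 8–31 timepoints, 50-seed
Monte-Carlo repeats for the noisy-recovery checks, and random-forest
tables of 150–400 genes. Brute-force oracles (explicit O(n·w) window
subtraction, pairwise U counting, step-up adjustment, normal-equation
grid scoring) are kept at ≤ 1000-element instances.

## Known limitations

- The model is unreliable where RNAP density is very low (error
  amplification in the ratio) or speed is very low (delays conflict with
  the half-life measurement window).
- Absolute speeds inherit the reference gene's uncertainty and the
  assumed 40-nt footprint; rankings do not.
- The census interprets arbitrary units through the model and one
  external total; it is a consistency check, not a measurement.
- Half-lives are consumed as input (with explicit units — seconds or
  minutes — never guessed); the clearance fitter is a cross-check, not
  a half-life estimator.
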