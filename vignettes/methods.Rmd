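---
title: "Process-based rice yield simulation and surrogate distillation: models and methods"
author: "cropdistill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based rice yield simulation and surrogate distillation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cropdistill` chains three pieces of machinery: a daily-step
process model of irrigated rice growth and yield, a seeded synthetic
weather generator that supplies the model with multi-grid, multi-year
driving data, and a distillation pipeline that trains a small
convolutional network to reproduce the simulator's yield output and
then interrogates the trained network with gradient saliency. This
vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the package's own tests can show.

## The crop model

The model is a classical radiation-driven, phenology-indexed
formulation for irrigated rice. Crop state is summarized by the
developmental index DVI: 0 at emergence (here identified with the
May 01 planting day), 1 at heading, 2 at maturity. Each day the index
advances by a developmental rate DVR and all other processes are read
off the current DVI.

**Phenology.** Before heading, DVR responds logistically to daily mean
temperature and, once the crop passes the photoperiod-sensitivity
threshold `DVI*`, is attenuated by day length $L$:

$$
DVR =
\begin{cases}
\dfrac{1}{G_v\{1+\exp[-A(T_{mean}-T_h)]\}} & DVI \le DVI^{*} \\[1.2em]
\dfrac{1-\exp[B_p(L-L_c)]}{G_v\{1+\exp[-A(T_{mean}-T_h)]\}} & DVI > DVI^{*},\; L \le L_c \\[1.2em]
0 & DVI > DVI^{*},\; L > L_c
\end{cases}
$$

$G_v$ is the minimum number of days to heading, $T_h$ the temperature
of half-maximal rate, $L_c$ the critical day length. From heading to
maturity the rate is a saturating function of temperature above a base
$T_{cr}$, $DVR = \{1-\exp[-K_r(T_{mean}-T_{cr})]\}/G_r$, floored at
zero: the printed form goes negative below the base temperature, and
development cannot run backwards.

**Growth.** Daily dry matter gain is absorbed radiation times a
conversion efficiency, $\Delta W_t = C_s S_s$. The canopy model behind
$S_s$ is a package-authored surrogate (the classical formulation
defers its leaf-area dynamics to a reference we deliberately do not
depend on): leaf area index rises as $LAI_{max}\,DVI^{r}$ to its peak
at heading and declines linearly to a fraction `LAI_end_frac` of the
peak at maturity, and absorption follows Beer's law
$S_s = S(1-e^{-k\,LAI})$. This preserves the two properties the parent
formulation states - absorption is a function of LAI, and LAI peaks at
DVI 1 - while keeping the package self-contained. The conversion
efficiency is constant through the vegetative phase, declines smoothly
to zero over grain filling, and carries a saturating CO2 response
that equals 1 at 330 ppm and tends to $1+R_m$ at high concentration.

**Sterility and yield.** Two damage modes reduce the harvest index.
Cool-summer damage accumulates cooling degree days
$Q_t = \sum \max(0, 22 - T_{mean})$ over the panicle-sensitive window
$0.75 < DVI < 1.2$ and maps to a sterile fraction
$\gamma_L = \gamma_0 + K_q Q_t^{a}$, clamped to $[0,1]$. Heat damage
at anthesis is a fixed logistic in the mean daily maximum temperature
over $0.96 < DVI \le 1.22$:
$\gamma_H = 1/\{1+\exp[-0.853(T_H - 36.6)]\}$. The two combine as
$\gamma = \max(\gamma_L, \gamma_H)$; harvest index is
$h = h_m(1-\gamma)\{1-\exp[-K_h(DVI_{final}-1.22)]\}$, floored at 0,
and yield is $Y_G = h\,W_t$.

Three numerical conventions deserve note, all in the direction of
physiological sense where the printed formulation is ambiguous:

* the cool-sterility response is implemented with a **plus** sign
  ($\gamma_0 + K_q Q_t^a$): cooling must increase sterility, and the
  clamp to $[0,1]$ makes the response total;
* cooling-degree terms are clamped at zero (days warmer than 22 °C
  contribute nothing), the standard cooling-degree-day convention;
* $\gamma$ enters $(1-\gamma)$ as a fraction, not a percentage.

Boundary conventions: DVI is capped at exactly 2.0 on the maturity
day; heading and maturity are flagged on first crossing ($\ge$), so a
season whose index reaches exactly 2.0 on the Oct-05 deadline is kept.
The deadline is season day 158 (May 01 + 157 days, non-leap calendar).
Daily update order: DVR is computed from the start-of-day index, the
index is advanced, and growth, cooling and heat accumulation use the
updated value. If a season never enters the anthesis window, the heat
sterility term is zero - there is no anthesis to damage. After
maturity the season state is frozen.

**Cultivar parameters.** The constants ship as a versioned flat config
(`inst/extdata/cultivar_koshihikari_synthetic.txt`). The calibration
is synthetic - chosen so that a May 01 planting under the package's
default climatology heads in late July to early August, matures in
early September, and yields 5-7 t/ha with a maximum harvest index of
0.4, the behaviour expected of a Koshihikari-like temperate japonica -
not fitted to field data. No test or acceptance check depends on their
absolute values; the analytic identities hold for any admissible set.

## The synthetic weather generator

The generator emulates the *structure* of gridded Japanese
agro-meteorological data without reproducing any real series: a
latitude-graded seasonal sinusoid for daily mean temperature (annual
mean falling ~0.9 °C per degree north of 35°, seasonal amplitude
growing northward, warmest day near July 29) with AR(1) daily noise
(innovation SD 1.5 °C, persistence 0.6); a positive stochastic
offset for the daily maximum; a clear-sky seasonal radiation curve
attenuated by clamped-normal cloudiness; astronomical day length from
the sunrise-to-sunset hour-angle formula (twilight and refraction
ignored); and constant CO2 at 350 ppm (configurable, since the CO2
response makes it a live input column). Every parameter lives in
`weather_config()` / `scenario_spec()`, none in code constants.

Scenarios perturb the draws deterministically, so a scenario series
differs from its seed-matched baseline by exactly the stated deltas:
`cool_summer` subtracts `delta_T` (default 4 °C) from the mean
temperature on days 60-120, putting the panicle-sensitive window into
cooling accumulation; `heat_anthesis` adds `delta_T` (default 7 °C)
to the daily maximum on days 75-110, spanning anthesis for most
latitudes; `cold_region` lowers both temperature series by 8 °C all
season, which keeps DVI below 2 by the October 05 deadline everywhere
north of ~35°. The default scenario mixture (55% baseline, 20% cool,
20% heat, 5% cold) was chosen once so that a few-hundred-series batch
populates all three saliency cases and contains excluded seasons; the
deltas and windows were set from the physiology above, not adjusted
against test outcomes.

What the generator does **not** emulate: spatial correlation between
grid cells, humidity and precipitation (unused by the crop model),
inter-annual climate trends, typhoons, and the empirical marginal
distributions of any real station. Passing tests therefore demonstrate
that the pipeline recovers structure the simulator encodes under
plausible forcing - not that it would do so on real Grid Square data.

## Dataset construction

Each kept grid-year becomes a 184 x 5 matrix with columns in fixed
order `L, Tmean, Tmax, Ss, P`. The `Ss` column is the **incident**
daily global solar radiation from the weather record: the five columns
are meteorological drivers, and canopy-absorbed radiation is a
simulator internal the surrogate is not allowed to see. Rows strictly
after the maturity day are zeroed (vertical zero padding). Seasons
whose DVI has not reached 2.0 by October 05 are excluded before any
matrix is built.

Normalization is a per-factor z-score whose statistics come from the
training split only, computed over non-padded cells. The constant CO2
column has no variance, so the z-score is undefined; it falls back to
scale-only normalization (center 0, scale = the column's root mean
square), which maps the constant to 1. We originally tried passing the
column through unchanged at 350 ppm: the first convolution layer then
sees one input three hundred times larger than the others, its
activations saturate, and training collapses to a constant predictor
(a 25-epoch run ended with validation R² of 0.00). With the RMS
fallback the identical run converges. The fallback keeps the column's
information (its padding zeros still mark season end) at unit
magnitude.

After normalization, every cell receives independent uniform noise in
[-0.001, 0.001] - training and validation alike - and padded rows are
re-zeroed so that padding stays exactly zero. The split is 75/25 by
whole grid-year, uniformly at random; normalization-before-noise and
noise-after-padding are documented orderings, not claims about the
original workflow.

## The surrogate and its training

The network is deliberately small: a single-channel 184 x 5 input, two
3 x 3 convolutions (stride 1, zero padding 2) mapping 1 -> 32 -> 64
feature maps with ReLU activations - the padding of 2 with a 3 x 3
kernel *enlarges* each map by two rows and columns per layer, an
unusual geometry we replicate as stated - then a flatten, a dense
ReLU hidden layer (default width 64), and a linear scalar output:
6,949,377 parameters at the default sizes. Training minimizes mean
squared error with Adam (default learning rate 1e-3, batch size 128)
on internally standardized targets; losses are reported on the raw
yield scale. Weights are checkpointed at every strict improvement of
validation loss, training stops after 10 consecutive non-improving
epochs (ties count as non-improvements) or at the epoch cap, and the
best-validation-epoch weights are restored. Everything - He-normal
initialization, shuffling, noise - is seeded; a fixed corpus, config
and seed reproduce the training history exactly.

Small-batch training of this geometry proved brittle in its first
epochs: the flatten layer is enormous (108,288 inputs to the dense
layer), so its He-scaled weights (sd ~0.004) are two orders of
magnitude smaller than the first convolution's (~0.47), while Adam's
step is an absolute quantity applied uniformly. A uniform step moves
the dense layer by whole multiples of its own scale within one epoch;
the resulting output swings deactivate the ReLU layers wholesale and
the network degenerates into a constant predictor - in roughly half
of (corpus, seed) pairs under plain Adam. The principal remedy is
layer-adaptive learning rates: each tensor's rate is the configured
rate scaled by that tensor's initialization spread (second
convolution as reference, biases tied to their layer's weights),
which equalizes relative weight movement per step. Three secondary
guards remain, all seeded and deterministic: the output head is
scaled down before training when its initial predictions spread
beyond five target standard deviations (a data-dependent cap, never a
scale-up); the learning rate ramps linearly over the first three
epochs; and `distill()` discards a fit explaining less than 5% of
held-out variance and retries with a derived initialization seed (at
most four times, returning the best attempt, with a collapsed network
recognized the moment its validation predictions have zero variance).
With these in place, every (corpus, seed) pair we have rerun -
including several that previously collapsed repeatedly - trains
without restarts to validation R-squared near 0.85.

The compiled engine evaluates convolutions as im2col + GEMM in single
precision (master weights and Adam state stay in double; gradients are
exact backpropagation, verified against a double-precision reference
forward pass and finite differences in the test suite). On one CPU
core an epoch over a 2,000-grid-year corpus takes roughly 15 s.

Problem sizes for the packaged checks were fixed at: 2,000 grid-years
(40 grids x 50 years, latitudes 31-43° N), three training seeds, an
epoch cap of 20, and 500 saliency seed inputs per case. The epoch cap
interacts with patience-10 early stopping as in any small-budget
study: most runs select a best epoch in the teens.

## Saliency evaluation

"Positive saliency" is implemented as the rectified input gradient of
the scalar output, each map rescaled to maximum 1 (a zero map stays
zero). This is the simplest attribution consistent with "cells whose
increase raises the predicted yield"; guided-backprop variants could
be swapped behind the same contract, and the signed gradient is
available through `input_gradient()` for direction-of-effect readouts.
Three cases are evaluated: all kept grid-years; those whose heat-only
harvest index falls strictly below the corpus' own 10th percentile;
and the analogous cool-only subset. Thresholds are always computed on
the corpus at hand - percentile values from any particular external
dataset would be meaningless here. Seed inputs (default n = 500) are
drawn from the training split, without replacement when the subset
allows.

Profiles assign each non-padded day-row of each map the DVI its
simulation had that day, then average per factor within DVI bins of
width 0.05 (day-rows first, then bins; both choices documented, since
per-map-first averaging is an equally defensible alternative). The
window contrasts are tested with a per-map paired statistic - mean
saliency inside the window minus outside - under a seeded sign-flip
permutation test (999 permutations, two-sided).

## Known limitations

* The canopy surrogate and the cultivar calibration are package
  constructions; absolute yields are realistic but not validated
  against field data.
* The weather generator bounds what the distillation experiments can
  claim: synthetic realism is plausibility, not fidelity.
* The surrogate's accuracy is data-limited at the packaged problem
  size; validation R² near 0.9 should not be compared with what the
  same architecture attains on corpora two orders of magnitude larger.
* Humidity, precipitation, nitrogen, water balance, pests and any
  within-day process are out of scope.
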