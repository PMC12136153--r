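---
title: "From intracellular voltage traces to spectral sensitivity, inhibition labels and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From intracellular voltage traces to spectral sensitivity, inhibition labels and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsens)
```

# The problem

Sharp-electrode recordings from insect photoreceptors produce, per cell, a
stack of time-voltage traces: monochromatic flashes spanning 310-630 nm in
10 nm steps (four repeats each, isoquantal at 1.5e15 photons/cm^2/s), a
V-log(I) series of nine intensity levels spanning four log units at the
wavelength that drives the cell best, and optionally a block recorded
before, during and after a persistent 534 nm adapting LED. `specsens` turns
those traces into:

1. per-trace response features (baseline statistics, amplitude, polarity,
   onset latency, half-maximum duration);
2. a spectral sensitivity curve per cell, via Naka-Rushton inversion;
3. an estimate of the wavelength of peak sensitivity (lambda_max) by
   rhodopsin-template fitting;
4. a spectral class (UV / blue / green / redLW / broadband) and a binary
   label for long-wavelength opponent inhibition;
5. group-level inhibition proportions with binomial standard errors, and
   logit-link mixed models with a random intercept per individual animal;
6. a quantum-catch prediction of how strongly white versus yellow wing
   reflectance drives a UV receptor of any given tuning.

Because the original recordings are not distributed with the package, a
synthetic-data generator with full ground truth stands in for them; every
stage of the pipeline is validated against that ground truth.

# Trace features

**Baseline.** Mean and SD of the membrane potential over exactly the 500 ms
window ending at stimulus onset. The window never includes post-onset
samples. A linear trend (mV/s) over the same window feeds the drift QC.

**Onset latency.** The time of the first post-onset sample at which the
voltage departs from the baseline mean by more than five baseline SDs,
sustained for at least 1 ms. The debounce exists because at 10 kHz a lone
5-sigma sample occurs by chance roughly every 1.7 s of Gaussian noise; a
single rogue sample must not set a latency. For noise-free synthetic traces
the baseline SD is zero, so a floor of 0.05 mV substitutes. Latency is
reported at sample resolution (0.1 ms): interpolating between samples buys
nothing once the debounce is in place, and sample-time reporting makes
latency *differences* between conditions exact on the grid. Latency is
undefined (NA), not zero, when the threshold is never crossed.

**Amplitude and polarity.** The signed extremum of the deviation from the
baseline mean within a 500 ms post-onset window, measured on the
repeat-averaged trace after a 2 ms moving-average smoothing. The smoothing
matters: the extremum of a 5000-sample window rides on the extremum of the
sample noise, which biases every amplitude upward by roughly three noise
SDs and, propagated through the Naka-Rushton inversion, inflates the tails
of the sensitivity curve. A 2 ms boxcar is an order of magnitude shorter
than the response kinetics and removes most of the bias. Latency estimation
is deliberately *not* smoothed (smoothing drags threshold crossings
earlier). Polarity is "none" when the extremum stays within five baseline
SDs.

**Half-maximum duration.** Total time the depolarizing response stays above
half its peak, summed over all supra-threshold intervals with linear
interpolation at the crossings, so a rectangular 80 ms pulse measures
exactly 80.0 ms.

**Quality control.** A cell passes when its largest depolarizing response
is at least 30 mV (healthy photoreceptors respond to strong light with
depolarizations of at least that size), it recovers at least 80% of its
pre-LED response after the adapting LED is switched off, and its baseline
drifts by less than 10 mV/s. The drift bound is this package's own
housekeeping choice; the other two are the field's standard criteria.

# From responses to spectral sensitivity

Response amplitude compresses with intensity following the Naka-Rushton
function
$$V(I) = V_{max} \frac{I^n}{I^n + K^n},$$
with `V(K) = v_max/2` by definition. `fit_naka_rushton()` estimates
(v_max, log10 K, n) from the V-log(I) series by Levenberg-Marquardt least
squares on the log-intensity scale (starting values: 1.05x the largest
response, the interpolated half-maximum intensity, n = 1). Degenerate
series — fewer than five levels, a decreasing trend, or a maximum response
under five noise SDs — return a flagged failure object instead of a fit,
and the cell is excluded downstream.

The isoquantal spectral series is then linearized: each depolarizing mean
response V at wavelength lambda maps to the equivalent intensity
$$I_{eq}(\lambda) = K \left(\frac{V}{V_{max} - V}\right)^{1/n}$$
that would have evoked it at the V-log(I) wavelength, and sensitivity is
$S(\lambda) \propto I_{eq}(\lambda)$, peak-normalized. The proportionality
(rather than its reciprocal) is fixed by two checks the package tests
enforce: a forward-simulated cell must invert back to its generating
template, and at n = 1 the sensitivity ratio of two wavelengths must equal
the ratio of their $V/(V_{max}-V)$ odds. Responses at or above v_max are
clamped to 0.999 v_max and flagged; hyperpolarizing responses are mapped to
S = 0 and flagged separately — they reflect opponent inhibition, not opsin
absorption, and are excluded from template fitting.

# Template fitting of lambda_max

The sensitivity curve is fitted with the A1 visual-pigment alpha-band
template (`rhodopsin_absorbance()`): with $x = \lambda_{max}/\lambda$,
$$S(x) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D},$$
A = 69.7, B = 28, b = 0.922, C = -14.9, c = 1.104, D = 0.674,
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$. No beta band is
included: over the 310-630 nm measurement range of these cells the alpha
band dominates, and adding a beta band would add a free parameter the data
cannot constrain. The raw parameterization peaks up to ~0.6 nm short of its
nominal lambda_max at the short-wavelength end; since lambda_max is
operationally *defined* as the wavelength of peak sensitivity, the
grid-evaluated template is anchored (a sub-nanometre wavelength shift) so
its maximum falls exactly at lambda_max.

`fit_lambda_max()` minimizes the sum of squared deviations between the
peak-normalized measured sensitivity and the peak-normalized template at
the measurement wavelengths: a 1 nm grid scan over the search range
(default 330-650 nm, ties broken toward the smaller value) brackets the
optimum, followed by continuous refinement. The objective is evaluated on
the linear normalized scale, not log sensitivity: the noise inherited from
mV-level measurements is approximately additive on that scale, whereas log
weighting would let the near-zero tail bins dominate. Unweighted least
squares is used; the per-wavelength response variances are retained in the
features table should a user want weighted fits. Fits with r^2 below 0.5
are flagged unreliable and classified "unknown".

Validation on synthetic data: noise-free round trips (trace level) recover
lambda_max to well under 1 nm for UV, blue and green cells; with additive
Gaussian noise of SD 0.05 on the normalized sensitivity, the RMSE over 200
cells drawn uniformly from 345-404 nm is below 1 nm (the acceptance bound
is 3 nm); the distribution of estimates over a homogeneous population is
unimodal (kernel-density mode count).

# Classification

Spectral classes partition lambda_max space: UV [330, 420), blue
[420, 500), green [500, 580) with template r^2 >= 0.8, redLW >= 580 nm.
The boundaries are this package's choice — the observed clusters sit at
345-404 nm (UV), ~470 nm (blue), ~550 nm (green) and >600 nm (red-shifted),
so the cuts fall in wide empty margins. Cells whose half-maximum bandwidth
exceeds 1.5x the template bandwidth at the same lambda_max are classified
broadband regardless of lambda_max; such cells arise from opsin
co-expression and are far wider than any single pigment allows.

Long-wavelength inhibition is scored at a probe wavelength where the cell's
own opsin is essentially blind but long-wavelength neighbors respond
strongly: 530 nm for UV cells, 590 nm for blue cells. A cell is labelled
inhibited when the repeat-mean probe response is hyperpolarizing and its
magnitude exceeds five baseline SDs of the repeat-averaged trace
(equivalently, 5 sigma/sqrt(repeats) of a single trace). A t-test across
repeats would be the obvious alternative, but four repeats give too
unstable a variance estimate; the baseline-SD criterion borrows the noise
estimate from the long pre-stimulus window instead. The signed probe
response normalized by the peak amplitude is retained so that inhibition
can also enter models as a continuous covariate.

# Group inference

Inhibition proportions per group are reported as k/n with the binomial
standard error sqrt(p(1-p)/n); this reproduces the reference summaries
exactly (70.8 +/- 6.6% for 34/48, 19.2 +/- 5.5% for 10/52, 16.7 +/- 8.8%
for 3/18, 46.8 +/- 6.3% for 29/62). For the pooled blue-cell summary the
binomial SE on 67/126 gives 4.4%, not the printed 4.5%; the package
reports the binomial value.

Because several cells come from the same butterfly, group comparisons use
mixed models with a random intercept per individual: logit link
(`lme4::glmer`, Laplace approximation) for binary outcomes, identity link
(`lmerTest::lmer`, Satterthwaite t-tests) for continuous ones such as
lambda_max. The Laplace approximation rather than adaptive quadrature is
the default because the model has a single scalar random effect and modest
cluster sizes; fixed effects are tested with Wald statistics rather than
likelihood-ratio tests, matching how such contrasts are conventionally
reported. Zero-variance boundary fits are legitimate (the data often show
negligible between-individual variance) and reduce exactly to ordinary
logistic regression — a property the test suite checks numerically.
Pairwise group contrasts are refit per pair and reported with per-pair
p-values, uncorrected for multiplicity. Calibration at the study's own
sample sizes (43 cells/12 individuals vs 40/14, individual effects of SD
0.5): null type-I error of the pairwise Wald test is ~5%, and the 95% Wald
CI covers a true logit effect of 1.2 in ~95% of replicates (40 individuals
x 5 cells).

One-sample t-tests against an expected opsin tuning use Bonferroni
correction over the declared number of comparisons. Half-max durations are
compared across groups by one-way ANOVA with Tukey HSD; the compact letter
display is computed as the maximal cliques of the
"not-significantly-different" graph.

# The synthetic-data generator

`simulate_trace()` is a forward model, not a biophysical one: baseline at
the resting potential (-52.7 mV) plus Gaussian white sample noise; an
excitatory depolarization whose amplitude is
max_depol x NR(template catch x intensity), with max_depol >= 30 mV so
cells pass QC by construction; and, for inhibited cells, a hyperpolarizing
component driven by a 550 nm (green) template catch whose onset lags the
excitatory latency by 5.4 ms — the monosynaptic-delay signature the
analysis must detect. The inhibitory input acts only at wavelengths >= 500
nm: real opponent inputs also attack the short-wavelength band of the
curve, but the generator's job is to provide ground truth for the
estimator, and a short-wavelength inhibitory overlap would make the
generating lambda_max unrecoverable *in principle* rather than merely
noisy. This is a documented idealization, not a claim about the biology.

Kinetics are a difference of exponentials with a 2 ms rise and 80 ms decay.
The fast rise is a deliberate choice: the 5-sigma crossing time after
response onset scales like threshold/(amplitude x initial slope), so a slow
rise makes measured latency amplitude-dependent — with a 10 ms rise the
probe-minus-peak latency difference would drift by several tenths of a
millisecond over two log units of intensity, contaminating exactly the
quantity the generator exists to validate. With a 2 ms rise the crossing
bias stays well under one sample at all tested intensities while half-max
durations remain in the plausible tens-of-milliseconds range (~60 ms at
default settings).

The adapting-LED forward model is phenomenological: multiplicative
amplitude attenuation (green cells to 20.9% of baseline; inhibited UV/blue
cells to 75%, non-inhibited to 55% — the LED decrease is larger for cells
without inhibition), an additive resting-potential shift (+5.6 mV for green
cells; -5.6 mV for inhibited UV cells, whose tonic opponent input grows;
-1.4 mV for non-inhibited ones), a 0.6x decay-time factor (light adaptation
speeds responses, shortening half-max durations), and a configurable
post-LED recovery fraction for exercising the 80% recovery QC rule.

Wing reflectances: white wings reflect ~0.9 across 300-700 nm; yellow
wings are near zero below a sigmoidal edge at 420 nm and match white above
it. Experiments (`sim_experiment_spec()`) default to seven groups with the
UV-photoreceptor sample sizes (43/12, 40/14, 18/9, 19/9, 8/4, 30/16, 22/10
cells/individuals) and per-group inhibition probabilities equal to the
pooled observed rates (0.708 for yellow-preferring groups, 0.468 for
no-preference groups, 0.167 for the white-preferring group, 0.192 for
outgroup males and females). Ground-truth lambda_max is drawn from a
normal(375, 10) truncated to [345, 404] — the observed continuous range —
as one unimodal population per group. Seeded runs are byte-identical.

What the generator does **not** emulate: 1/f and line noise (noise is
white), electrode artifacts, intensity-dependent latency, the
phototransduction cascade, spike-like events (these cells respond with
graded potentials), light scatter between stimuli, or screening-pigment
effects in red-shifted LW cells (those cells are classified but not
mechanistically modeled). Passing tests therefore demonstrate that the
estimators are unbiased and correctly calibrated under the stated
statistical structure — not that they are robust to every artifact of real
recordings.

# Perception model

`predicted_excitation()` is a plain linear quantum-catch integral,
$E = \int R(\lambda)\,S(\lambda)\,L(\lambda)\,d\lambda$ by the trapezoidal
rule on the merged grid, with a flat illuminant unless one is supplied. No
receptor-noise color space is layered on top: the question is only how
strongly a wing drives a receptor. `excitation_sweep()` reports three
scales: the raw integral; `excitation_rel`, the integral divided by the
template's own area (the reflectance-weighted mean absorbance), which is
the right scale for comparing receptors of *different* tuning because the
raw integral grows ~26% from lambda_max 345 to 404 purely through template
bandwidth; and `excitation_norm`, scaled within each lambda_max so the
most exciting color is 1 (the contrast a single receptor sees). On
synthetic wings, the yellow:white ratio at lambda_max 355 is ~0.005 and
the relative white drive varies by well under 1% across 345-404 nm: every
UV tuning in the observed range sees essentially the same white/yellow
contrast.

# Running the pipeline

`run_pipeline()` executes the whole chain from either a simulation spec or
an on-disk trace directory, streaming cell by cell so memory stays flat,
and emits a cells table, group statistics, the perception sweep and a
provenance block (package version, seed, schema version). Reports are
reproducible from config plus seed alone. `make_fixtures()` writes a
miniature on-disk experiment (TSV per presentation, manifest and truth
CSVs) that round-trips through `read_experiment()`; its default scale uses
a coarse spectral grid that deliberately retains the 530 nm inhibition
probe. The test suite and the acceptance script size their simulations
(200 sensitivity fits, 50 latency cells, 600 null and 400 coverage GLMM
replicates, 60-100 trace-level cells) so the full run completes in a few
minutes on one core; these sizes are stated here as the package's chosen
problem sizes for validation.

# Known limitations

* The sensitivity transform requires a usable V-log(I) fit; cells whose
  series is degenerate are excluded rather than rescued with a borrowed
  exponent (the class-default n = 1 fallback is deliberately not automatic
  — a flagged exclusion is more honest than a silent imputation).
* Template fitting assumes a single alpha band; red-shifted cells with
  screening pigments are assigned a class but their curves are not modeled.
* The inhibition label is binary by thresholding; cells hovering at the
  criterion are sensitive to the noise estimate. The signed normalized
  probe amplitude is retained for continuous analyses.
* Wald inference in small groups (e.g. 8 cells / 4 individuals) is
  approximate; the calibration results above are for the larger group
  sizes.
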