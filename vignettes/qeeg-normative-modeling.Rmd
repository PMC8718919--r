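---
title: "Sex- and age-differentiated QEEG normative modeling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex- and age-differentiated QEEG normative modeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

# The model

`qeegnorm` builds normative databases of resting-state QEEG band power.
For each frequency band $b$, channel $c$ and sex stratum $s$, the natural
log of absolute power $P$ (µV²) is modeled as a smooth function of age:

$$\ln P_{i,b,c} = f_{b,c,s}(\mathrm{age}_i) + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma_{b,c,s}^2).$$

The log transform is essential: across ages, absolute power is strongly
right-skewed (approximately lognormal), and a mean fitted on the raw scale
is not a usable center. On the log scale the residuals are close to
Gaussian and homoscedastic, which is what makes the standardized index
meaningful.

$f$ is a penalized cubic B-spline (a generalized additive model in age
alone), fitted by minimizing

$$\lVert y - B\beta\rVert^2 + \lambda \lVert D\beta\rVert^2,$$

where $B$ is the B-spline basis with 10 interior knots at the age
quantiles of the training data and $D$ is a second-order
divided-difference penalty taken with respect to the Greville abscissae of
the basis. Divided (rather than plain) differences matter: with
quantile-placed, hence unequal, knots they keep the penalty null space
exactly the linear functions, so a linear age trend is reproduced at any
$\lambda$ and the fit tends to the ordinary least-squares line as
$\lambda \to \infty$. The smoothing parameter is selected per component by
generalized cross-validation, $\mathrm{GCV}(\lambda) = n\,\mathrm{RSS} /
(n - \mathrm{edf})^2$, over a fixed logarithmic grid
$10^{-3} \dots 10^{4}$.

From the fit, every continuous age yields a predicted mean
$\hat\mu(\mathrm{age})$ and a predicted SD

$$\hat\sigma_{\mathrm{pred}}(\mathrm{age}) =
  \hat\sigma\sqrt{1 + h(\mathrm{age})},$$

with $h$ the prediction leverage of the penalized fit, i.e. the half-width
of the 95% prediction interval divided by $z_{0.975} = 1.959964$. The
leverage-inclusive form was chosen deliberately (the alternative — residual
scatter only — was an open design question): it makes held-out coverage
correct even where the curve itself is uncertain, at the price of a
slightly inflated SD near the age boundaries. The standardized index is
then $z = (\ln P - \hat\mu)/\hat\sigma_{\mathrm{pred}}$, and for normative
subjects of the model's population $z \approx N(0,1)$.

Sex stratification is done by fitting the identical procedure per sex
(`sex_mode = "male"` / `"female"`); the pooled model (`"pooled"`) runs the
same procedure on both sexes concatenated with no sex covariate, mirroring
the comparison design between a sex-differentiated database and a
traditional age-only one.

## Why not age bands

The discarded alternative — normative means and SDs per discrete age
window — is provided as `fit_age_band_model()` because the contrast is
itself informative: a subject at age 49.9 and one at 50.1 can be
standardized against noticeably different windows, producing step
discontinuities in $z$ at window midpoints, while the spline model is
continuous in age. The baseline uses windows of half-width 5 years
(centers every 5 years, widened by 25% steps until each holds at least 30
subjects), and scores a subject against the window centered nearest their
age. The test suite asserts the discontinuity contrast directly.

# Screening rules

Normative eligibility composes four criteria per age group (infants 4–6,
children/adolescents 7–19, Adult 1 20–49, Adult 2 ≥ 50; half-open
boundaries):

* **Pre-screening**: any exclusionary history flag (head trauma, epilepsy,
  psychiatric/neurological history, …) excludes.
* **Cognitive**: one required test below the 2nd percentile, or three or
  more below the 7th. Standard scores (mean 100, SD 15) are converted to
  percentiles with the normal convention, which reproduces the printed
  anchors (70 ↔ 2%, 80 ↔ 9%, 90 ↔ 25%, 109 ↔ ~74%). The MMSE (Adult 2
  only) has no printed 2nd-percentile anchor, so it enters only the
  7th-percentile tally via its printed anchor raw 25 ↔ 7%.
* **Emotional**: infants are excluded on a behavior-checklist depression
  or anxiety percentile above 98; older subjects on any high-risk
  subdomain (state anxiety, trait anxiety, depression) or two at-risk
  subdomains. Anxiety thresholds depend on age bracket and sex; the
  printed risk bands are read as inclusive of both endpoints.
* **Behavioral**: minors require a passing expert evaluation; vacuous for
  adults.

Two printed ambiguities were resolved in favor of disjoint, total
classifications: an intelligence score of 70 is Borderline (not Extremely
Low), and a children's-depression score of 21 is Normal. "Severe" MMSE is
read as ≤ 9 so that 0–8 is not unassigned. Exhaustive integer sweeps in
the tests confirm totality and monotonicity of every classifier.

# Spectral features

Raw multichannel EEG is band-passed 1–45.5 Hz and notch-filtered
(default 60 Hz mains, configurable to 50 Hz) by zero-phase FFT-domain
multiplication with raised-cosine transitions, then re-referenced to the
common average. Recordings are cut into non-overlapping 4-s epochs;
epochs in which any channel exceeds ±100 µV are dropped (a declared
simple stand-in for subspace artifact rejection, which is out of scope).
Power spectra are Welch averaged modified periodograms (Hann taper, 2-s
segments, 50% overlap, mean detrend per segment; frequency resolution
0.5 Hz), and band power is the trapezoidal integral of the PSD over the
band, so contiguous bands sum to the integral over their union.

Band edges: delta 1–4, theta 4–8, alpha 8–12, beta 12–25, beta3 25–30,
gamma 30–45 Hz. The classical beta range is 12–30 Hz with beta3 its upper
sub-band; since the band set here must be a disjoint partition (both for
additivity and for independent per-band synthesis), the "beta" feature
covers 12–25 Hz and beta3 the remaining 25–30 Hz — their union is the
classical beta band. Absolute (not relative) power is used throughout,
because the normative model log-transforms and standardizes it; relative
power would change the meaning of the index.

# The synthetic cohort: a stated world

The generator (`sample_cohort()`) emulates the statistical structure the
pipeline assumes, with defaults fixed once:

* **Ages** uniform on 4.5–81 years (the documented cohort span; uniform
  maximizes spline support where the true histogram is unavailable).
* **Trends**: per band, an exponential-decay segment over 4.5–20 years
  joined continuously to a linear adult segment — the simplest form
  producing the three documented patterns (sharp juvenile slow-wave
  decline, steady adult alpha decrease, steady adult beta increase). The
  trend is identical across channels; channels act as replicates.
* **Noise**: iid Gaussian residuals on log power with SD 0.3 natural-log
  units (±2 SD ≈ a 3.3-fold power range, a plausible between-subject
  spread); hence lognormal absolute power.
* **Sex offset**: 0.15 log units on theta only, split symmetrically
  (female = trend + 0.075, male = trend − 0.075), so the pooled mixture
  has SD $\sqrt{\sigma^2 + \mathrm{offset}^2/4}$ — the closed form used
  by the anomaly-contrast oracle.
* **Screening scores**: drawn safely inside every normative band for
  passing subjects; a Bernoulli(0.1 by default) subset receives one
  failing feature from the rule families applicable at their age, with
  the ground-truth label retained.
* **Raw EEG** (`synthesize_eeg()`): per band, band-limited Gaussian noise
  scaled so its variance equals the target band power. Components are
  inset 0.5 Hz inside their nominal band (one bin of the default 2-s
  Welch window) because spectral estimation smears hard edges by about
  the window resolution; without the inset the synthesize→extract round
  trip loses 5–15% of edge-band power.
* **Anomalies** (`inject_anomaly()`): additive shifts on log power in a
  chosen band and channel set, expressed in units of the generator SD so
  the injected effect size is a target z.

What the generator does **not** emulate: EEG morphology (spindles,
blinks, alpha reactivity), spatial covariance between channels,
subject-level correlated residuals across cells, eyes-open/eyes-closed
reactivity, and non-Gaussian residual tails. A green calibration test
therefore establishes that the modeling machinery is correct under its own
assumptions — not that real cohorts satisfy those assumptions.

# Numerical choices and degenerate inputs

* Smoothing grid $10^{-3}\dots10^4$ (15 points); per-component
  minimizer; ties go to the smaller grid index via `which.min`.
* Ages outside the training range are **clamped** to the nearest bound
  and flagged (`age_clamped`) rather than extrapolated — validation data
  can exceed the normative span, and spline extrapolation is unreliable.
* Non-positive power yields an `NA` z-score (flagged, never silently
  zero); a zero predicted SD with a zero residual yields z = 0.
* $\lambda = 0$ with more basis functions than distinct ages raises an
  explicit error advising a positive $\lambda$.
* Model files are versioned JSON at full precision; reloading reproduces
  predictions to machine precision, and truncated or field-missing files
  raise a schema error.
* A single master seed drives every pipeline stage through fixed derived
  substreams; artifacts contain no timestamps, so identical
  configurations give byte-identical outputs.

# Validation procedures

* **Calibration**: held-out normative subjects scored against the fitted
  sex-stratified models should give pooled z mean ≈ 0 and variance ≈ 1.
* **Effectiveness analogue**: z-scores from the continuous model and the
  age-band baseline on the same held-out subjects are Pearson-correlated;
  both per band and pooled are reported (the bound of interest, r ≥ 0.7,
  mirrors the agreement expected between databases that capture the same
  normal-state trends while differing in age-regression method).
* **Accuracy analogue**: with a nonzero generative sex offset, anomalies
  injected into one sex are scored farther from zero by the sex-matched
  model than by the pooled model in the affected cells; the expected
  pooled attenuation follows the mixture closed form above.
* **Sex-difference testing**: per cell, Shapiro-Wilk (both groups) and
  Levene gate tests route to Student's t, Welch's t, or Mann-Whitney U;
  gate p-values are recorded so the routing is auditable. The
  significance map uses a display threshold of p ≤ 0.1 (an exploratory
  visualization convention, kept separate from the 0.05 gate level), and
  applies no multiple-testing correction by default (a Benjamini-Hochberg
  option exists).

# Known limitations

* **Young-edge curve accuracy.** With ages uniform over 4.5–81, only a few
  percent of subjects fall where the slow-wave trend is steepest
  (4.5–8 years). Pointwise recovery of the generative trend near that
  boundary is limited by smoothing bias and edge variance — deviations of
  the order of 0.1–0.4 log units at the extreme edge at realistic cohort
  sizes, for this package's fit and for reference GAM implementations
  alike. The acceptance suite computes this sup-norm deviation explicitly;
  interior accuracy is an order of magnitude better. Practical
  deployments should oversample the youngest ages if early-childhood norms
  matter.
* Homoscedastic residual SD per component: an age-varying SD is a
  documented non-goal; the prediction-interval leverage term only partly
  compensates where the true scatter varies with age.
* Artifact handling is amplitude-thresholding only; no ocular/myogenic
  component removal, no source-space modeling — all contrasts are at
  sensor level (or on synthetic features standing in for source ROIs).
* EDF input is not implemented (no reader available in the supported
  dependency set); recordings are read from plain CSV matrices.
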