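---
title: "Methods: ratiometric chloride-indicator analysis with clsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric chloride-indicator analysis with clsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsense)
```

## The measurement problem

Genetically encoded ratiometric chloride indicators fuse a CFP donor to a
chloride-sensitive YFP whose emission is quenched by Cl^-^. Exciting at
436 nm and 500 nm in alternation and forming the ratio

$$R = \frac{F_{436}}{F_{500}}$$

yields a quantity that rises with intracellular chloride and is insensitive
to expression level. `clsense` implements the full analysis chain for such
recordings from acute brain slices: per-wavelength background subtraction,
ratio formation, correction of a slow photoinactivation drift, exposure
normalisation, sigmoid calibration to concentration, drug-effect
quantification, clustered inference with slices as the independent units,
and reversal-potential estimation from voltage-ramp electrophysiology. A
synthetic-data generator emulates every input class with known ground
truth, so each stage is testable by exact or statistical recovery.

## Preprocessing model

### Background and ratio

Each slice recording carries exactly one background ROI (a dim region of
the field). Background is subtracted per wavelength; samples whose
backgrounds-subtracted intensity is non-positive in either channel become
flagged gaps rather than being clamped to zero — a ratio of noise residuals
is worse than a missing sample. Multiple background ROIs are rejected
rather than averaged, for determinism.

### Photoinactivation drift

Under repeated excitation the chloride-sensitive YFP accumulates in an
inactivated state, depressing $F_{500}$ and hence inflating $R$ on a
constant-chloride cell. The drift is modelled as a single saturating
exponential. Because the mechanism scales the 500 nm channel, the artifact
enters the ratio *multiplicatively*:

$$R(t) = R_{\mathrm{bio}}(t)\,\bigl(1 + d(t)\bigr),
  \qquad d(t) = \tilde D\,(1 - e^{-t/\tau}).$$

On a constant baseline $B$ this is exactly $B + A(1 - e^{-t/\tau})$ with
$A = B\tilde D$, which is what `fit_drift()` estimates (the model is linear
in $(A, B)$ given $\tau$, so $\tau$ is profiled over a log-spaced grid and
polished by one-dimensional optimisation — immune to the start-value
divergence of full Newton fits on near-flat traces).

Removal, however, is a design decision. Subtracting $A(1-e^{-t/\tau})$
removes the drift exactly on a constant trace but under-corrects any
later biological step by the factor $1 + d(t)$, biasing a step of size
$\Delta R$ by $\Delta R\, d(t)$ (several percent at the exposures used
here). `correct_drift()` therefore defaults to *gain* mode, dividing by
$1 + A(1-e^{-t/\tau})/B$, which removes a multiplicative artifact exactly
and leaves steps unbiased; the literal subtractive form remains available
(`mode = "subtract"`). Both preserve the absolute baseline.

### Masking and pooling

Samples around events are excluded from the drift fit: puff events mask
60 s before to 600 s after onset; bath events persist, so they mask from
60 s before onset to the event offset (trace end when none). Fitting
through a drug plateau would absorb the drug effect into the drift term.

Fitting scope matters more than it first appears. A per-ROI fit from a
~540 s baseline, extrapolated ~2.5 window-lengths into the response
window, carries a Jensen-type bias (the extrapolated curve is non-linear
in $\hat\tau$) of roughly $-0.4\%$ in ratio units — larger than the
standard error of a well-powered drug-effect estimate. `clsense` exploits
the physics: the inactivation time constant and the relative amplitude per
unit exposure are properties of the indicator and illumination, not of
individual somata. `preprocess_dataset()` therefore estimates $\tau$ once
from all ROIs (with per-ROI baselines profiled out), then re-estimates the
amplitude per *slice* with $\tau$ fixed. The per-slice amplitude problem
is nearly linear, hence effectively unbiased, and its errors are
independent across slices — so the cluster-robust standard errors used
downstream account for residual correction error honestly. (A fully
global amplitude would shrink the bias further but make the correction
error common to all slices and invisible to the sandwich estimator; we
deliberately do not do that.) Per-ROI and per-slice scopes remain
available via `preprocess_recording()`.

### Exposure normalisation

Steady-state ratios retain a dependence on the 500 nm exposure duration
even after drift correction in real recordings. The adjustment is an
additive linear trend in exposure, estimated per condition from
condition-level baselines across slices (never within one trace, where
exposure is constant), and maps every value to the 100 ms reference:
$R' = R - \hat\beta\,(E - 100\,\mathrm{ms})$. With a single exposure level
the adjustment is unidentifiable and errors unless the caller explicitly
opts into an identity adjustment.

## Calibration

The steady-state ratio follows a four-parameter Hill-type sigmoid in
chloride concentration $C$:

$$R(C) = R_{\max} + \frac{R_{\min} - R_{\max}}{1 + (C/K_d)^p},
\qquad
C(R) = K_d\left(\frac{R_{\min} - R}{R - R_{\max}}\right)^{1/p}.$$

Note the numerator $R_{\min} - R_{\max}$ in the forward form. Printed
versions of this equation sometimes carry a sign slip
($R_{\min} + R_{\max}$), which is mutually inconsistent with the inverse
and maps the bottom of the operating band to non-physical concentrations;
the pair above satisfies $R(0) = R_{\min}$, $R(\infty) = R_{\max}$, is
strictly increasing, and reproduces published concentration
statements: with $K_d = 108.8$ mM, $R_{\min} = 0.98$, $R_{\max} = 2.92$,
$p = 2.91$ (available as `reference_calibration()`), $R = 1.0$ maps to
22.7 mM (consistent with resting estimates "greater than 20 mM"), and
ratio increases of 0.27 from 1.05 and 0.18 from 1.20 convert to 28.7 and
14.8 mM — the published ~29 and ~15 mM figures.

`fit_calibration()` runs nonlinear least squares on a log scale for $K_d$
and $p$ (implicit positivity), with deterministic multi-start
initialisation (asymptotes from observed extremes, $K_d$ from the
concentration nearest mid-range, $p = 1$, plus jittered restarts), and
rejects fits with $p \notin (0.5, 10)$ or inverted asymptotes. The
parameter covariance comes from the numerical Jacobian at the optimum.

Two numerical caveats are documented deliberately:

* **Sensitivity blow-up near the floor.** $dC/dR \to \infty$ as
  $R \to R_{\min}^{+}$; a fixed ratio uncertainty maps to unbounded
  concentration uncertainty near the bottom of the band. Concentrations
  are a reporting layer — downstream statistics operate on $R$ itself,
  matching the design convention of such experiments.
* **Round-trip floor.** $C \mapsto R \mapsto C$ is exact to $10^{-9}$
  relative only for $C \gtrsim 0.25$ mM in double precision: below that,
  $R(C)$ collapses onto $R_{\min}$ to machine epsilon and the information
  is unrecoverable. Tests exercise $[0.5, 123]$ mM.

## Event quantification

Published analyses report "average change in R" without printing
their windows, so windows are an explicit, logged choice here — the largest
measurement-affecting convention in the package. Defaults: baseline mean
over $[-180, -10]$ s relative to onset; bath-drug response mean over
$[+600, +900]$ s (minutes-long wash-in has plateaued). Records with more
than 20% missing samples in a window are flagged low-confidence, not
dropped. Occlusion designs (a second drug applied on top of the first) are
two sequential bath events: the second event's baseline window then sits
on the first drug's plateau automatically.

Puff transients are summarised by the extremum of the
baseline-subtracted ratio after onset, located on a 5-point moving
average so the amplitude is not inflated by picking the largest noise
excursion. An extremum below 3 baseline-noise SDs is "no transient
detected" — a result, not an error. Recovery is the first sustained
(3-sample) re-entry into a band of ±10% of the amplitude around baseline.
Rising ratios report chloride influx; falling, efflux.

One estimand subtlety: with a 180 s wash-in time constant, the
$[+600, +900]$ s response window sees ~98.2% of the plateau amplitude.
`expected_window_delta()` computes this window estimand exactly from the
noiseless trajectory; recovery tests compare estimates against it, since
an unbiased pipeline recovers the estimand, not the asymptote.

## Clustered inference

ROIs within a slice share circuitry, perfusion, and optics; slices are the
independent units. `fit_gee()` implements Gaussian-identity generalized
estimating equations with an exchangeable working correlation and
cluster-robust standard errors, iterating generalized least squares with
moment estimation of the intra-cluster correlation. Inference uses the
z (normal) reference, the GEE convention.

With realistic cluster counts (10–20 slices) the classic sandwich is
liberal: simulated type-I error ~0.08–0.09 at nominal 0.05 under a null
with slice random effect SD 0.03 and ROI noise SD 0.02. The default
covariance therefore applies the Mancl–DeRouen bias correction (residuals
inflated by $(I - H_i)^{-1}$ per cluster), which brings the simulated
type-I error to ~0.06; the remaining excess is the z reference itself at
20 clusters. The uncorrected sandwich (`cov_type = "robust"`) and the
$m/(m-1)$ scaling (`"cr1"`) remain available; the implementation
reproduces statsmodels' GEE to ~10 significant digits for both the
uncorrected and bias-reduced covariances on a frozen fixture.

Drug effects measured in different buffer solutions come from disjoint
experiments, so they are compared across two independently fitted models:
$z = (\hat\beta_1 - \hat\beta_2)/\sqrt{SE_1^2 + SE_2^2}$, with
significance declared against a Bonferroni-adjusted threshold
$\alpha/n_{\text{comparisons}}$ supplied by the analysis plan (never
inferred). Paired electrophysiology summaries use the paired Student
t-test.

## Reversal-potential estimation

A 400 ms voltage ramp (~60 mV span) is delivered during a GABA puff and
again without agonist; the control sweep captures leak, and the subtracted
I–V crosses zero at the GABA~A~ reversal potential. The coarse crossing is
located on a 5-point moving average; crossings within one fit-window width
of each other are treated as a single (noise-jittered) reversal, and only
well-separated crossing clusters raise the "multiple crossings" error. A
straight line fitted within ±10 mV of the crossing (difference currents
rectify away from reversal, so a narrow window limits bias) gives the
x-intercept. No series-resistance or junction-potential correction is
applied, matching the stated acquisition convention.

Nernst utilities use CODATA constants at the 34 °C bath temperature:
$E_{Cl} = (RT/F)\ln([Cl]_{in}/[Cl]_{out})$, with `passive_cl()` as the
exact inverse. One documented discrepancy: at $V_m = -45$ mV and ~122 mM
external chloride, passive distribution gives ~22.3 mM, not the ~15 mM
sometimes quoted; the package computes from first principles and does not
match the quoted figure (the external concentration or temperature behind
it is unstated).

## The synthetic world

`simulate_dataset()` generates the stated world the tests assume:

* **Baselines** in the published 1.0–1.3 operating band: day 1.15, night
  1.12 (a +0.03 day-over-night offset; AVP and VIP baselines equal, since
  no baseline difference between the populations was found).
* **Drug effects in ratio units**, routed through the inverse calibration
  to build concentration trajectories: KCC blockade +0.18 (AVP) / +0.27
  (VIP); NKCC1 blockade +0.04 (AVP) / −0.04 (VIP); bath wash-in
  $\tau = 180$ s; puff transients of amplitude 0.10 with 10 s rise and
  120 s decay. A bath step beginning while another bath drug is present is
  scaled by an occlusion factor (default 0: full occlusion).
* **Heterogeneity**: per-slice baseline offsets (SD 0.03) *and* per-slice
  drug-amplitude jitter (SD 0.03, matching the slice random-effect
  magnitude of the inference null world). Without the latter, simulated
  robust SEs are ~10× smaller than the error bars of real summary data
  and no pipeline could meet a 2-SE recovery criterion in the presence of
  any systematic term. Recovery holds across a sweep of this SD over
  {0.01, 0.03, 0.06}.
* **Photophysics**: drift divides the 500 nm channel by $1 + d(t)$
  (amplitude 5% per 100 ms exposure at saturation, $\tau = 300$ s),
  exposures cycle over {50, 100, 200} ms across slices, noise is
  shot-noise-like Gaussian ($\sigma = a + b\sqrt{I}$, ~0.5–1% of the
  ratio per sample at defaults), and per-channel backgrounds are added.
* **Determinism**: every draw descends from the master seed through
  per-(slice, ROI) substreams, so datasets are byte-reproducible and
  adding ROIs never perturbs existing ones. A truth sidecar records every
  generated parameter.

What the generator does *not* emulate — and hence what a green test does
not establish: pH sensitivity of the indicator, subcellular chloride
gradients, heterogeneity of responses across ROIs within a slice,
non-exponential bleaching, plateau drift in drug efficacy, or any
transporter kinetics. The generator encodes *reported*
phenomenology, not a biophysical model of its cause.

## Known limitations

* The drift model is a single exponential; multi-component bleaching is
  out of scope.
* Exposure adjustment assumes an additive linear trend; the underlying
  functional form is unknown.
* Published reports of this design print significance statements, not GEE
  coefficient tables, so only the *kind* of inference is reproducible,
  not its digits.
* Calibration constants are dataset-specific (the reference $K_d$ is
  well above earlier literature values); refit rather than reuse.
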