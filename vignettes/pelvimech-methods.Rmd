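---
title: "Methods: biaxial vaginal-wall biomechanics and urethral electrophysiology with a synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biaxial vaginal-wall biomechanics and urethral electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pelvimech` re-implements, as a tested and reusable pipeline, the quantitative
analysis used in rodent simulated-childbirth-injury studies: planar biaxial
tensile testing of the vaginal wall (cyclic loading at 4.6, 10, 15.7 and
21.6% strain, ten cycles per level, 100% strain/min, 30 Hz sampling),
leak-point-pressure (LPP) urodynamics with external urethral sphincter EMG,
pudendal-nerve ENG during genital brushing, and the group statistics
comparing a sham-injured arm against injury (pudendal nerve crush + vaginal
distension) treated with vehicle, mesenchymal stem cells (MSC) or a
heparan-sulfate mimetic (RGTA). Because studies of this design publish group
bar charts rather than raw traces, the package ships a synthetic cohort
generator with fully known ground truth; every estimator is validated by
parameter recovery against that truth.

## The synthetic specimen

### Material model

Each axis (x = longitudinal, y = transverse) follows an exponential
constitutive law in engineering strain $\epsilon$ (stored in %, used as a
fraction in all formulas):

$$\sigma_a(\epsilon) = A_a\left(e^{B_a \epsilon} - 1\right), \qquad
\frac{d\sigma_a}{d\epsilon} = A_a B_a e^{B_a \epsilon}.$$

This is the simplest law with the two features every measured specimen in
this preparation shows — a compliant toe region followed by a quasi-linear
stiffening region — and it has a closed-form tangent, which makes it an exact
oracle for the tangent-modulus estimator. Defaults ($A = 0.012$ MPa,
$B = 16$) give a tangent of about 6 MPa at 21.6% strain and a peak force of
about 3.3 N on a 10 × 10 × 0.9 mm specimen, comfortably inside a 5 N load
cell: magnitudes of the order reported for rat vaginal wall. No published
parameter values exist for this study design, so these are realistic
stand-ins, configurable via `tissue_mech_params()`.

### Hysteresis

The unloading limb is

$$\sigma_{unl}(\epsilon) = \eta\,\sigma_l(\epsilon) +
(1-\eta)\,\sigma_p\left(\frac{\sigma_l(\epsilon)}{\sigma_p}\right)^3,$$

with $\sigma_p$ the cycle's peak stress and $\eta \in (0,1]$ (default 0.8).
The path is continuous at the peak, decays to $\eta$ times the loading curve
over the body of the limb (so the fitted unloading slope is close to $\eta$
times the loading slope), and closes the loop at zero stress and zero
strain. An earlier design scaled the whole unloading stress by $\eta$; the
resulting stress discontinuity at the peak is unphysical and, at 30 Hz,
the sample nearest the peak can land on the unloading side and contaminate
the terminal-window tangent fit by up to tens of percent. Continuity at the
peak is what real viscoelastic tissue does, and it removes that artifact.

### Preconditioning

Cycle $c$ within a strain level is scaled by $1 - d\,r^{c-1}$ with
$d = 0.15$ (`precond_drop`) and $r = 0.5$ (`precond_rate`). The defaults
make cycle 1 about 15% softer than steady state while cycles 8–10 agree to
well under 1%, matching the observation that ten cycles suffice for
steady-state mechanics and motivating the use of the last three cycles for
analysis.

### Noise and sampling

Strain follows an ideal triangle wave (constant |strain rate|) evaluated at
the 30 Hz sample grid; additive Gaussian force noise (`noise_sd`, default
0.01 N ≈ 0.2% of the load cell full scale) is applied per load-cell sample.
Strain jitter is not simulated by default but the segmentation is tested
against it.

## The biomechanics estimators

All estimators follow the study's analysis conventions:

* **Stress**: nominal (first Piola–Kirchhoff), force over the undeformed
  cross-section thickness × width, with width defaulting to the 10 mm
  specimen edge. The effective loaded width is configurable because rake
  fixtures admit other conventions.
* **Cycle segmentation**: cycles are delimited by strain minima; valleys are
  found where smoothed strain drops below half the lowest protocol level,
  with the smoothing window and a minimum boundary separation derived from
  the protocol so jitter cannot split a valley. Peaks are assigned to the
  nearest protocol level; equidistant peaks go to the lower level.
* **Steady cycles**: the last `k_last = 3` of the ten cycles per level.
* **Mean slope**: the average of first-order least-squares fits over the
  loading and unloading limbs of a cycle, averaged over the steady cycles.
  Metrics are computed per cycle and then averaged (rather than averaging
  curves point-wise first), which is robust to sample misalignment between
  cycles.
* **Tangent modulus**: per steady cycle, the least-squares slope of the
  loading limb restricted to the last 1% strain below that cycle's observed
  peak; the level's estimate is the mean over the three cycles. The loading
  limb alone is used because the linear region is defined on loading.
* **Anisotropy index (AI)**: longitudinal tangent modulus divided by
  transverse tangent modulus, per specimen and strain level.

### What the window slope estimates

A least-squares line fitted over a strain window estimates the curve's
tangent at (approximately) the window's *center*, not its endpoint. For the
exponential material the continuous-window slope equals
$A B e^{B(\epsilon_p - w/2)}\,\frac{3}{B a^2}\left(\cosh h - \sinh h/h\right)$
($a = w/2$, $h = Ba$; `true_window_slope()`), which is within 0.1% of the
pointwise tangent at the window center but a factor $\approx e^{-Bw/2}$
below the tangent at the peak — about 8% for $B = 16$ and the 1% window.
This is a property of the estimand, not an estimator defect. Validation
therefore compares estimates against the tangent at the mean strain of the
fitted window (agreement to 0.11% at 30 Hz, improving with sample rate),
and parameter recovery scores estimates against the window-slope estimand
stored in the cohort truth. Users comparing absolute moduli across studies
should note the convention: the value labelled "21.6%" probes ~21.1%
strain. The AI is unaffected, since the factor cancels in the ratio when
both axes share $B$.

At 30 Hz and 100% strain/min the 1% window holds ~18 samples; the estimator
refuses to fit fewer than 2 points rather than extrapolate, and errors
name the specimen, axis and level.

## The electrophysiology chain

The generator renders homogeneous Poisson spike trains (1 ms dead time) as
biphasic 2 ms templates with peak-to-peak amplitudes
$\sim N(\mu_{amp}, \sigma_{amp})$ on Gaussian noise band-limited at ~500 Hz,
sampled at 10 kHz; LPP trials add a pressure channel that holds at
`p_baseline`, ramps to `p_leak` and drops at the leak. Each trace carries a
spike-free 0.4 s quiet reference window.

* **LPP** = maximum pressure near the leak marker − mean pressure over the
  baseline window. It is exactly `p_leak − p_baseline` on noise-free trials
  and invariant to constant pressure offsets.
* **Spike detection**: threshold at noise mean + `threshold_sd` × noise SD
  estimated from the quiet reference; upward crossings with a 1 ms
  refractory period; amplitude = local peak-to-peak within ±1 ms of the
  spike peak. Because the threshold is noise-relative, detection is
  invariant to global gain.
* **Default threshold 4 SD**: by Rice's formula a ~500 Hz Gaussian process
  upcrosses a 3 SD threshold at $\nu_0 e^{-4.5} \approx 3$ events/s
  ($\nu_0 \approx f_c/\sqrt{3}$), which would bias absolute firing rates by
  ~3 Hz — far beyond the Poisson sampling error of the recovery checks. At
  4 SD the false-positive rate is ~0.04 events/s while spikes (template
  peak ≈ 75 μV vs. threshold ≈ 32 μV) are still detected essentially
  without misses. 3 SD remains available via `threshold_sd`.
* **Segment metrics**: firing rate = count/duration and mean peak-to-peak
  amplitude over 1 s windows (baseline vs. stimulation: the 1 s around peak
  pressure for EUS EMG, the brushing window for ENG); outcomes are the
  stimulated-minus-baseline deltas, averaged over an animal's 3–6 LPP and
  5–10 ENG trials. Absent trials propagate as missing values, never zero.
* Band-pass (3 Hz–3 kHz) is applied only to traces marked raw; generator
  output is already band-limited.

A note on rates: a Poisson train with intensity $\lambda$ and a 1 ms dead
time realizes $\lambda/(1+\lambda\tau)$ spikes per second (38.5 Hz for
$\lambda = 40$); recovery checks compare detected rates against that
thinned expectation.

## The cohort and its presets

`cohort_config()` defaults to four arms — sham+VEH (n = 12), PNC+VD+VEH
(n = 7), PNC+VD+MSC (n = 9), PNC+VD+RGTA (n = 7), the biomechanics arm
sizes of the design — with multiplicative group factors on
$(A_x, A_y, \text{rate}_{stim}, p_{leak})$: injury 0.7 on both stiffness
axes (the 30% difference the design's power calculation assumes) and ~0.6–0.7
on function; MSC restores stiffness (1.0) but not function; RGTA restores
longitudinal stiffness only (1.0/0.7), pushing the true AI to 1/0.7 ≈ 1.43.
Between-animal variability is an independent log-normal multiplier
(mean 1, CV 10%) on those four quantities. These factors emulate the
qualitative published pattern; they are not measurements. Everything drawn
per animal is recorded in `CohortTruth` (realized parameters, pointwise
tangents, window-slope estimands, AI, LPP and rate deltas), and the whole
cohort is reproducible from one seed.

What the generator does *not* emulate: strain-dependent anisotropy growth,
viscoelastic relaxation between levels, non-Poisson burst firing, movement
artifacts, and electrode drift. Passing recovery tests therefore shows the
pipeline is correct for data matching its declared structure, not that real
recordings are this clean.

## Statistics

Per-animal means feed group summaries (mean ± SEM) and the study's tests:

* **Kruskal–Wallis** (tie-corrected, via `stats::kruskal.test`) with
  **Dunn's** pairwise z-tests on mean ranks, Bonferroni-adjusted by default
  (Holm and unadjusted available). Dunn's test is implemented in the
  package and verified against an independently coded rank formula; an
  all-identical outcome returns H = 0, p = 1 rather than an error.
* **Two-way repeated-measures ANOVA** for tangent moduli per axis:
  split-plot `aov` with group between animals and strain level within,
  no sphericity correction by default; animals missing a level are excluded
  with a warning. Pairwise group contrasts within each strain level come
  from `emmeans` and are Bonferroni-adjusted over the whole family
  (adjusted = min(1, m·p)).
* **Mixed model for AI**: `ai ~ group × level` with a per-specimen random
  intercept (`lmerTest`, Satterthwaite degrees of freedom); a singular fit
  falls back to the fixed-effects model with a warning. A random intercept
  (not slope) is used because each specimen contributes one AI per level
  and level effects are modelled as fixed.
* **Sample size**: smallest per-group n for a two-sided two-sample t-test
  (`power.t.test`) to detect a relative difference at given power.
  The assumed variance is study-specific, so `relative_sd` is required;
  a relative difference of 30% at α = 0.05, power 0.90 and relative SD 0.15
  gives the design's seven animals per group.

Calibration is checked by simulation: on null cohorts the Kruskal–Wallis
and RM-ANOVA omnibus tests reject at 5.2% (600 and 500 replicates
respectively in the acceptance run).

## Problem sizes and numerical choices

Validation runs use: single specimens for the deterministic identities;
one 35-animal cohort (12/7/9/7) for recovery; 200 one-second windows for
firing rates; 500–600 null cohorts for calibration; and 100 seeded
study-scale replicates for the qualitative pattern, which reproduce the
published directional findings (injury softens both axes, MSC restores
both, RGTA raises AI at 15.7–21.6%) in every replicate at the default
effect sizes. Degenerate inputs — zero-variance outcomes, constant AI,
zero-variance noise references, truncated protocols — return exact null
results or descriptive errors rather than NaNs, and every random quantity
is reproducible from a single integer seed.
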