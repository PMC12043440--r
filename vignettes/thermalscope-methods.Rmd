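---
title: "Methods: from oxygen traces to thermal vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to thermal vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalscope)
```

## The measurement model

Intermittent-flow respirometry alternates sealed *measure* phases, during
which a fish depletes the oxygen in its chamber, with *flush* phases that
restore air saturation. Within a measure phase the oxygen decline is
treated as linear, and its ordinary-least-squares slope (converted to
mg O₂ L⁻¹ h⁻¹ regardless of the raw sampling interval) is the primitive
observation of the whole analysis. The conversion to a mass-specific
oxygen uptake rate is

$$\dot{M}\mathrm{O}_2 \;=\; |s - s_{\text{blank}}|\,
  \frac{v_R - m}{m}\,\left(\frac{m}{0.025}\right)^{1-b}$$

with slope $s$, respirometer volume $v_R$ (L), body mass $m$ (kg), and
allometric exponent $b$. The factor $(v_R - m)$ approximates the effective
water volume (fish density ≈ 1 kg L⁻¹), and the last factor standardizes
every rate to a common 25 g body mass, so fish of different sizes are
comparable. The defaults $b = 0.72$ (RMR) and $b = 0.74$ (MMR) are the
conventional log–log regression estimates for juvenile *Oncorhynchus
mykiss*; `estimate_scaling_exponent()` re-estimates them from the data
when `scaling$estimate_from_data` is set. Background (bacterial)
respiration enters as an optional constant blank slope, default 0 — empty
chamber controls in the motivating study design are typically negligible.

Published summaries of this kind of study sometimes print rate units as
"mg O₂ kg⁻¹ L⁻¹"; the package treats the canonical unit as
mg O₂ kg⁻¹ h⁻¹ throughout and keeps the customary numeric scale (resting
rates of roughly 2–6, maxima of roughly 10–15 at these temperatures).

### Quality control

Three rules, all configurable in `default_config()` and none hard-coded in
computation paths:

* a cycle passes only with regression **R² ≥ 0.9** (the boundary value
  passes: only R² *below* 0.9 is discarded) and no anomaly flag. Anomaly
  flags can be supplied externally or raised by an optional
  Wald–Wolfowitz runs test on the regression residuals (default off),
  which catches smooth equipment artefacts that keep R² high;
* a fish is excluded from RMR analysis when **more than 25%** of its
  regressions fail (strictly more: exactly one failing cycle in four is
  retained);
* an RMR temperature bin needs **n ≥ 3** contributing cycles.

## Resting and maximum metabolism

RMR uses the record after a **240-min settling discard** (handling-stress
recovery; configurable). Because the holding treatments fluctuate
diurnally, each fish visits a range of temperatures overnight: cycle mean
temperatures are rounded to the nearest degree — half-degrees away from
zero, so 19.5 °C → 20 — and MO₂ is averaged within each bin.

MMR is the steepest **120-s** window across all post-chase measure cycles,
scanned at the raw sampling interval with an exact prefix-sum rolling
regression (ties broken by the earliest window; windows never span a
flush). Scanning *all* post-chase cycles matters: a minority of fish reach
their maximum in the second or later cycle. The implementation is checked
against an exhaustive per-window `lm()` scan in the test suite.

Aerobic scope is always per fish, never from group means:
AAS = MMR − RMR_chase and FAS = MMR / RMR_chase, where RMR_chase is the
RMR bin at the chase temperature. A missing chase bin is a hard error by
default (the design measures both rates at the same temperature); a
nearest-bin fallback within 1 °C exists behind `scope$chase_bin_fallback`.
Group FAS is the mean of per-fish ratios, which differs from the ratio of
group means — the summaries preserve that distinction.

## Thermal performance

The AAS thermal performance curve is a least-squares quadratic
$\mathrm{AAS} = c_0 + c_1 T + c_2 T^2$ on individual fish. For concave
fits, $T_{opt} = -c_1/2c_2$, and the pejus temperatures — bounds of the
region retaining ≥ 80% of peak scope — are
$T_{opt} \pm \sqrt{0.2\,\mathrm{peak}/|c_2|}$, exactly symmetric about
$T_{opt}$ with the quadratic evaluating to 0.8 × peak at both (the test
suite asserts both identities). Curvature with $|c_2| \le 10^{-6}$
(rate · °C⁻²) is treated as flat: the fit is flagged invalid and no
optimum is reported, which is the honest answer for thermally insensitive
populations rather than an arbitrarily distant vertex. Fitting individual
points (not treatment means) is deliberate: refitting from printed group
means gives visibly different coefficients.

FAS declines approximately linearly with temperature over the tested
ranges; the fitted line's crossing of FAS = 3 — the threshold commonly
taken to permit digestion with concurrent activity — defines $T_{FAS3}$.
Since the true FAS–temperature relationship (flat MMR over exponential
RMR) is convex, the linear $T_{FAS3}$ is an approximation that can land
beyond the tested span; such extrapolations are flagged and warned about,
not suppressed. A non-negative slope leaves $T_{FAS3}$ undefined with a
flag. The exponential RMR–temperature response is summarized by a
fixed-effects log-linear fit, reporting the thermal coefficient $k$ and
$Q_{10} = e^{10k}$ (mixed models with per-fish random effects are a
deliberate non-goal).

## Recovery kinetics

Post-exercise MO₂ pooled across the fish of one population × temperature
group follows a biexponential decay

$$\dot{M}\mathrm{O}_2(t) = A e^{\alpha t} + B e^{\beta t} + \mathrm{RMR},
\qquad \alpha < \beta < 0,\; A, B \ge 0,$$

with the asymptote *fixed* at the group mean RMR_chase. Estimation is
bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) initialized by curve
peeling: a log-linear fit to the tail (t ≥ 20 min) seeds the slow phase,
a log-linear fit of the fast-phase residual seeds the fast phase. Up to
five jittered restarts guard against bad starts; when one amplitude sits
on its zero bound the paired rate is unidentifiable and a nested
single-exponential fit is used instead (returned with B = 0). Phase labels
are interchangeable in the model, so fits are reordered to keep
α the faster rate. The fit demonstrably reaches the global least-squares
optimum on this problem class (checked against dense multistart in
development), but note the identifiability limitation below.

Recovery times per fish substitute only the asymptote: the group's
(A, α, B, β) are kept and RMR is replaced by the individual's RMR_chase —
the most direct reading of solving group models with individual resting
rates; whether the amplitudes should also be rescaled per fish is not
determinable from the motivating design, and we do not guess further.
Thresholds:

* **Time_AAS80**: MO₂* = RMR_chase + 0.2·AAS, i.e. the moment 80% of the
  fish's scope is available again (MMR − MO₂ = 0.8·AAS). A literal
  alternative reading, MO₂* = 0.8·AAS, is implemented behind
  `interpretation = "literal"`; it is not the default because it
  contradicts the definitional phrasing and produces implausibly ordered
  times.
* **Time_FAS3**: MO₂* = MMR/3. When MMR/3 ≤ RMR_chase the threshold is
  unreachable — warm groups genuinely contain such fish — and an explicit
  not-reached flag is returned, never a number.

The decay is strictly monotone, so the crossing is unique; it is located
by bisection on [0, 600 min] and rounded to the nearest 0.1 s.
Extrapolation beyond the measured 50–60 min record is intentional
(recovery at warm temperatures can take hours); beyond the 600-min bracket
the not-reached flag is returned.

## Habitat, CTmax, and vulnerability indices

Habitat logger series (hourly) are aggregated by calendar day (mean, min,
max, range), with the overall maximum and its timestamp, the annual range,
and the largest June–August daily range retained. An optional
low-temperature mask (default off) drops readings below a floor for
loggers that misread near freezing. CTmax — the temperature at loss of
equilibrium under 0.3 °C min⁻¹ warming — is summarized per population ×
treatment with plasticity deltas relative to the ambient treatment
(selectable via `ambient_treatments`; default: the first treatment seen).

The two indices are plain differences, with the sign convention fixed so
that positive values mean buffer:

$$\mathrm{TSM} = \mathrm{CT}_{max}^{\text{ambient}} - T_{\text{stream max}},
\qquad \mathrm{FWT} = T_{FAS3} - T_{\text{stream max}}.$$

They satisfy TSM − FWT = CTmax − T_FAS3 identically, which the tests
verify row by row on the bundled reference table.

## What the synthetic generator emulates — and what it does not

`simulate_scenario()` generates a complete study with known truth:

* **Temperature**: sinusoidal diel cycles peaking at 16:00 (trough 04:00),
  configurable mean/amplitude, optional Gaussian logger noise. Default
  logger noise sd is 0.2 °C — no within-day noise magnitude is standard,
  so this was chosen once as a realistic logger figure and documented
  here. Real thermographs have asymmetric warming/cooling limbs and
  weather-driven day-to-day variation; heat-wave structure is *not*
  modelled, and only daily summaries are claimed realistic.
* **Physiology**: per-fish mass is log-normal (field size distributions
  are right-skewed), truncated at ±3 log-sd; RMR rises exponentially with
  temperature (default 1.8 mg O₂ kg⁻¹ h⁻¹ at 16 °C, k = 0.09 °C⁻¹,
  Q₁₀ ≈ 2.5); MMR is a temperature-flat plateau by default (12.5), with a
  mild quadratic mode to give one population an interior TPC peak;
  recovery amplitudes split each fish's true scope between a fast
  (α = −0.3 min⁻¹) and slow (β = −0.03 min⁻¹) phase. CTmax is Gaussian.
* **Traces**: measure phases decline linearly at the slope implied by the
  fish's true rate at the interpolated cycle temperature — the exact
  inverse of the MO₂ equation — with i.i.d. Gaussian O₂ noise (default sd
  0.001 mg O₂ L⁻¹, a post-smoothing optode figure chosen so that default
  plans sit comfortably above the R² cutoff). Autocorrelated sensor
  drift, chamber mixing dynamics and temperature-dependent O₂ solubility
  are *not* modelled; saturation is a constant 9 mg O₂ L⁻¹. The generator
  refuses plans that would take O₂ below 80% air saturation.
* **Post-chase record**: the depletion rate is held at
  MMR = A + B + RMR_chase for the first 2 min (a brief sustained maximum)
  before following the biexponential decay; the steepest 120-s window
  therefore recovers MMR exactly under zero noise. Real post-chase traces
  need not contain any window at exactly the instantaneous maximum, so
  field MMR estimates are window averages by nature.
* **Ground truth**: binned-RMR truth is forward-computed from the true
  rate functions over the *actual* cycle schedule (a bin mixes
  temperatures across a 1 °C range, so bin truth is the mean of true
  rates over contributing cycles, not the rate at the bin centre);
  recovery traces take their asymptote from the same truth RMR_chase.
  With all noise at zero the full pipeline then closes on every generator
  parameter to floating-point accuracy, which the acceptance suite
  asserts at ≤ 10⁻⁶ relative error. Passing closure demonstrates the
  pipeline's internal consistency; it does not validate the biological
  realism of the generator against field data.

Default problem sizes — two populations, three to four treatments each,
four fish per treatment, 20-h resting records at 10-min cycles sampled
every 15 s, six post-chase cycles, 60-day habitat series — were chosen as
the smallest design that exercises every analysis branch (multiple RMR
bins per fish, ≥ 3 chase temperatures per population, not-reached recovery
cases, contrasting TSM/FWT) while keeping a full run in seconds.

## Numerical choices

* Cycle and scaling regressions use closed-form normal equations (exact,
  and fast over thousands of cycles); `lm()` serves as the independent
  oracle in tests, never the implementation under test.
* Temperature rounding is half-away-from-zero, documented because R's
  `round()` rounds half to even.
* R² is NA for zero-variance O₂ (a degenerate cycle), which fails QC
  rather than erroring.
* The 120-s window is defined as the span from each sample to the first
  sample at least 120 s later; windows that cannot reach full span are
  not formed.
* Bisection runs to a 10⁻⁴-min bracket (≪ 0.1 s) before rounding; the
  result is invariant to widening the bracket.
* The TPC validity threshold |c₂| > 10⁻⁶ separates genuinely flat scope
  from numerically meaningless vertices.

## Known limitations

* **Fast-rate identifiability.** With MO₂ sampled every ~10 min, a fast
  phase with α ≈ −0.3 min⁻¹ has decayed to 5% by the first post-maximum
  sample: only the earliest points inform α. Under 5% multiplicative
  noise with 12 fish × 6 samples, the Cramér–Rao bound puts the relative
  standard error of α̂ near 12% — so *any* unbiased estimator misses α by
  more than 10% in roughly two-fifths of replicates. The slow rate β is
  much better determined (≈ 8% relative s.e.). Denser early sampling,
  not a different optimizer, is what would improve α. The acceptance
  script reports the empirically measured replicate success rate rather
  than asserting precision the design cannot deliver.
* Group-level recovery parameters are shared within a population ×
  temperature group by construction; between-fish kinetic variation is
  not modelled (only amplitudes vary, through each fish's scope).
* The linear FAS fit extrapolates when FAS = 3 lies beyond the tested
  temperatures; the flag should be taken seriously when the crossing sits
  near the top of the tested range.
* Statistical inference (ANOVA, mixed models, model selection) is out of
  scope; the package produces estimates, diagnostics and reports, and
  hands inference to standard tools.
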