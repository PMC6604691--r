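---
title: "Methods: Patlak-based target engagement from immuno-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Patlak-based target engagement from immuno-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopet)
```

## The problem

A therapeutic monoclonal antibody labeled with zirconium-89 can be imaged by
PET over several days. On binding its receptor the antibody is internalized
and degraded; the radiometal stays trapped in the cell, so the tumor signal
accumulates in proportion to cumulative antibody exposure. Co-administering
increasing mass doses of *unlabeled* antibody competes the tracer off the
receptor: the rate at which label is irreversibly trapped falls with dose,
and the dose at which it bottoms out is the dose that saturates the target.
That saturating dose — not a maximum tolerated dose, which antibodies rarely
reach — is what a dose-finding imaging study wants to estimate.

`immunopet` implements that analysis chain: SUV quantification, Patlak
separation of reversible and irreversible uptake, baseline normalization,
and a saturable dose-inhibition fit yielding ID50 and ID90, plus a
synthetic-study generator with known ground truth so every stage can be
verified end to end without patient data.

## Tissue model and the Patlak transformation

The tissue signal is modeled as a reversible component in equilibrium with
plasma plus an irreversibly trapped component proportional to the integral
of the plasma input function $C_p$:

$$\mathrm{SUV}(t) = A\,C_p(t) + B \int_0^t C_p(\tau)\,d\tau$$

$A$ (dimensionless) collects plasma, interstitial and reversibly bound
antibody; $B$ (1/h) is the net internalization rate. Dividing by $C_p(t)$
gives the Patlak plot,

$$\mathrm{SUV}/C_p(t) = A + B \cdot \mathrm{AUC}(t)/C_p(t),$$

a straight line in "normalized time" $x = \mathrm{AUC}(t)/C_p(t)$ fitted
here by unweighted ordinary least squares over the 2–3 available scans
(`patlak_points()`, `patlak_fit()`). Numerical choices:

* **Plasma interpolation** is log-linear (each segment an exponential),
  because antibody plasma decay is multi-exponential; linear interpolation
  is available as an option. Segment integrals use the closed form of the
  exponential interpolant, the exact limit of a fine-grid quadrature.
* **Back-extrapolation to $t=0$**: the first blood sample is held constant
  back to zero. The unmodeled infusion period contributes well under 0.1%
  of the AUC at the 48–120 h scans.
* **Equilibration cutoff**: `min_fit_time_h = 24` excludes the ~2 h scan by
  default, since the reversible compartment has not equilibrated that
  early. Set it to 0 to use all scans.
* **Negative slopes** are kept and flagged (`negative_slope`), not clamped,
  so that downstream ratio statistics are not biased upward.
* With exactly two points $r^2 = 1$ by construction; `n_points` is recorded
  so such fits can be weighed accordingly.

## Dose-inhibition model

Receptor density differs per lesion, so on-treatment slopes are expressed
as percentages of the same lesion's tracer-only baseline slope
(`normalize_to_baseline()`; a baseline against itself is 100% by
definition, and lesions with non-positive baseline slope are excluded with
a recorded reason). Pooled lesion-level ratios are fitted
(`fit_inhibition()`) to

$$R(\mathrm{dose}) = \left[1 - \frac{\mathrm{dose}}{\mathrm{dose} +
\mathrm{ID}_{50}}\right](100 - R_{nsp}) + R_{nsp},$$

where $R_{nsp}$ is the residual percentage at full saturation attributable
to nonspecific internalization (pinocytosis). The dose at which the
*specific* term is inhibited by $q$% follows analytically:
$\mathrm{dose}_q = \mathrm{ID}_{50} \cdot q/(100-q)$, so
$\mathrm{ID}_{90} = 9 \times \mathrm{ID}_{50}$ identically
(`inhibitory_dose()`).

Design choices where the design was genuinely open:

* **Pooling.** Lesion-level points are pooled across patients with equal
  weight; averaging lesions within patient first is possible upstream but
  not the default, since sparse designs (one lesion in some patients) make
  per-patient weights arbitrary.
* **$R_{nsp}$ is free by default** (bounds [0, 100]), with `fix_rnsp` to
  pin it: the nonspecific floor is a fit outcome, not an assumption.
* **Baseline anchors.** Each patient's baseline study contributes a point
  (tracer-only dose, 100%), mirroring plots in which baseline studies are
  normalized to 100%.
* **Self-normalization of the model.** The tracer itself carries antibody
  mass (8 mg ≈ 0.11 mg/kg at 75 kg), so the baseline sits at a small
  nonzero dose and observed ratios are $100\,R(d)/R(d_{base})$, not
  $R(d)$. When the baseline dose is known (it always is in the pipeline),
  the fitted prediction is normalized to it in exactly the same way. This
  makes the estimator consistent with the ratio definition — noise-free
  data are recovered to machine precision — and places patients with a
  heavier baseline (e.g. 24 mg) on their own correct footing. Fitting the
  raw curve is available by passing `baseline_dose = NULL` with a
  column-free ratio table.
* **Initialization**: ID50 starts at the median nonzero dose and
  $R_{nsp}$ at the minimum observed ratio (clipped to [0, 100]) — robust
  and scale-aware. Fitting uses bounded Gauss–Newton (`nls`, port
  algorithm) with a bounded L-BFGS-B fallback on the SSE surface; a flat
  ratio vector short-circuits to a `non_identifiable_flat` flag rather
  than a silent answer.

## SUV quantification

`suv_from_activity()` normalizes activity concentration by injected
activity per gram at an assumed tissue density of 1 g/mL (the standard
convention). `suv_peak()` uses the common 1 mL sphere maximum-mean
definition — the sphere volume is configurable because vendor software
rarely documents its choice — with centers restricted to the mask and a
flagged fallback to the mask mean for lesions smaller than the sphere.
Lesions under 2 cm are excluded by `filter_lesions()` (inclusive
threshold) to avoid partial-volume bias. Table summaries exclude
below-limit-of-quantification (`BLQ`) and not-assessed (`NA`) cells and
round half-up to one decimal, the convention under which 15.66 prints as
15.7. `hscore()` implements the 0–300 immunohistochemistry score
$1 w + 2 m + 3 s$ with validation of the percentage composition.

## Noncompartmental PK

`nca()` reports Cmax and Tmax from the observed maximum (first occurrence
on ties) and AUClast by the linear trapezoid (log-down optional), with an
optional fixed window end so AUC(0–48 h) can be reported regardless of
later samples; no extrapolation to infinity. `labeled_unlabeled_ratio()`
converts the radioactivity channel to a mass concentration as
`SUV × administered mass (mg) / body weight (kg)` (µg/mL at unit density)
and summarizes the per-timepoint ratio to the immunoassay channel — near
1 with small spread when the label traces the drug.

## What the synthetic generator emulates — and what it does not

`study_config()` / `generate_study()` state a 6-patient world modeled on a
two-administration design: 37 MBq of tracer on 8 mg of antibody at
baseline, predose levels `{0.32, 1, 30, 30, 0.5, 0}` mg/kg two weeks later
(0.32 mg/kg is a 24 mg flat dose at 75 kg; 0 is a patient whose second
study is tracer-only), scans at 2/48/120 h, blood draws at 1, 3, 6, 12,
24 h plus before each scan.

* **Plasma**: biexponential with a saturable terminal rate
  $\lambda_2(\mathrm{dose}) = \lambda_{lin} + \lambda_{tmdd}\,
  \mathrm{ID}_{50}/(\mathrm{dose}+\mathrm{ID}_{50})$ — the simplest form
  reproducing slower clearance at higher mass dose — not a mechanistic
  TMDD ODE system. Defaults ($C_0$ SUV 20, fast fraction 0.35 at 0.08/h,
  terminal 0.003–0.014/h, i.e. half-lives of roughly 2–10 days) are
  typical antibody kinetics chosen once, not tuned.
* **Lesions**: $A$ = 0.3 and baseline $B_0$ = 0.005/h with lognormal
  inter-lesion CVs of 20% and 40%. Inter-lesion variability magnitudes are
  not reported anywhere we could anchor them; these are free choices of a
  plausible order, stated here and not revisited. Realized slopes obey the
  saturation model exactly at each administration's *total* mass dose
  (tracer mass included), so the generated world satisfies its own truth.
* **Noise**: multiplicative lognormal per scan (PET SUV noise is
  approximately proportional), mean-one, default CV 10%.
* All SUVs are decay-corrected to injection time; `zr89_decay_factor()`
  exposes the 78.4 h physical half-life for raw-count views.

Not emulated: partial-volume effects, scanner reconstruction, lesion
heterogeneity within a VOI, antidrug antibodies, receptor downregulation
between administrations, and dissociation of label from antibody. A green
round-trip test therefore establishes the *estimator chain* is correct and
unbiased under the stated model — not that the model captures every
feature of clinical data.

## Degenerate inputs and tie-breaks

Extrapolation beyond the plasma support is refused rather than guessed.
Zero plasma concentration at a scan drops the point with a warning. Cmax
ties resolve to the earliest time. A monotone decreasing concentration
curve has Tmax at the first sample. All-zero NCA curves are flagged.
Under-determined inhibition fits (fewer distinct dose levels than free
parameters plus one) raise an error rather than returning a boundary
estimate.

## Known limitations

* The inhibition fit treats lesions as independent; no hierarchical
  (per-patient random effect) estimation.
* Standard errors come from the local Jacobian of the nonlinear fit and
  are unreliable near the $R_{nsp}$ bounds; they are omitted with a flag
  when not estimable.
* Stochastic recovery of ID50 from realistic two-scan Patlak slopes is
  markedly noisier than from ratio-level noise of the same CV: slope
  ratios from two-point fits amplify measurement noise, and the estimator
  median then drifts above truth in small cohorts. The Monte Carlo tests
  quantify the ratio-level spread; full-study spread is larger and is the
  main reason sparse designs report ID50 as exploratory.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config(noise_cv = 0, seed = 5)
out <- tempfile()
report <- run_pipeline(run_config(out, seed = 5, study_config = cfg))
report$engagement
#> $id50_mg_kg  2
#> $rnsp_pct    30
#> $id90_mg_kg  18
```
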