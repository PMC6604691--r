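# immunopet

Target-engagement analysis for zirconium-89 immuno-PET studies of
therapeutic antibodies.

## The problem

Monoclonal antibodies rarely reach a maximum tolerated dose, so the
therapeutic dose must be chosen by a different criterion: the mass dose
that saturates the target receptor at the tumor. Because a ⁸⁹Zr label is
trapped intracellularly after receptor-mediated internalization, serial
PET imaging of a radiolabeled antibody — once at baseline with tracer
alone, once after a predose of unlabeled antibody — measures how strongly
each added mass dose competes the tracer off its receptor, directly at
the site of action.

This package implements the full quantitative chain for such a study,
for imaging scientists and pharmacometricians:

1. **SUV quantification** — SUVmean/SUVpeak on voxel grids (1 mL
   maximum-mean sphere convention), the ≥ 2 cm lesion filter, BLQ/NA-aware
   table summaries, immunohistochemistry H-scores.
2. **Patlak kinetics** — the tissue signal is modeled as
   `SUV(t) = A·Cp(t) + B·∫₀ᵗCp(τ)dτ`; dividing by `Cp(t)` linearizes it so
   an ordinary least-squares line over the 2–3 scan time points yields the
   reversible coefficient *A* (intercept) and the net internalization rate
   *B* (slope, 1/h).
3. **Dose–inhibition modeling** — per-lesion on-treatment slopes as
   percentages of their own baseline, pooled and fitted to
   `R(dose) = [1 − dose/(dose + ID50)]·(100 − Rnsp) + Rnsp`,
   giving the half-maximal inhibitory mass dose ID50, the nonspecific
   floor Rnsp, and `ID90 = 9·ID50` (exact identity of the hyperbola).
4. **Noncompartmental PK** — Cmax/Tmax/AUClast of the unlabeled drug
   channel and the labeled/unlabeled concentration-ratio consistency
   check.
5. **Synthetic studies** — a generator with known ground truth
   (biexponential plasma with saturable clearance, lesion kinetics obeying
   the saturation model exactly, lognormal measurement noise) so the whole
   pipeline is testable without patient data.

## Worked example

```r
library(immunopet)

## a noise-free 6-patient study generated with ID50 = 2 mg/kg, Rnsp = 30%
cfg    <- study_config(noise_cv = 0, seed = 5)
report <- run_pipeline(run_config(tempdir(), seed = 5, study_config = cfg))
report$engagement
#> $id50_mg_kg  : 2
#> $rnsp_pct    : 30
#> $id90_mg_kg  : 18
#> $converged   : TRUE
#> $residual_sse: 4.14e-27
#> $n_points    : 24
```

The pipeline recovers the generating parameters to machine precision: the
estimated half-maximal inhibitory dose is 2 mg/kg, 30% of baseline
internalization persists at saturation (nonspecific uptake such as
pinocytosis), and target saturation (90% inhibition of the specific
component) needs 18 mg/kg.

On the packaged per-lesion SUVpeak table (6 patients, two administrations,
`BLQ`/`NA` cells excluded, half-up rounding to one decimal):

```r
tab <- read_lesion_table(lesion_table_fixture())
suv_table_summary(tab, "first")   # $min 1.3  $max 15.7  $n 42
suv_table_summary(tab, "second")  # $min 1.6  $max 11.2  $n 36

hscore(0, 0, 100)                 # 300 — all cells staining strongly
inhibitory_dose(2, 90)            # 18 mg/kg
```

## Command line

```sh
Rscript inst/cli/immunopet.R simulate --config cfg.json --out study/ --seed 1
Rscript inst/cli/immunopet.R patlak --plasma study/plasma.csv \
        --lesions study/lesions.csv --min-fit-time 24 --out fits.csv
Rscript inst/cli/immunopet.R engage --fits fits.csv --out engagement.json
Rscript inst/cli/immunopet.R run --out run/ --seed 1
```

(Installed copy: `system.file("cli", "immunopet.R", package = "immunopet")`.)

## Layout

- `R/` — synthetic generator, quantification, kinetics, engagement, NCA,
  pipeline.
- `inst/extdata/lesion_suvpeak_table.csv` — per-lesion SUVpeak fixture.
- `vignettes/target-engagement-methods.Rmd` — model assumptions, numerical
  choices, generator scope, limitations.
- `tests/testthat/` — unit, property and acceptance tests (independent
  oracles: closed forms, dense quadrature, brute-force search, Monte
  Carlo).
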