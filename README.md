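# cardiact

Quantification of **dual-tracer constant-infusion cardiac PET/MRI** studies
of the infarcted heart, with mid-infusion glucose suppression.

## The problem

After a myocardial infarction, FDG-PET can image the inflammatory response —
but only if glucose uptake by healthy cardiomyocytes is suppressed (fasting,
heparin, lipid infusion), and it is an open question whether that
suppression also dampens the inflammatory cells one is trying to see. A
150-min simultaneous constant infusion of FDG and Gd-DTPA lets a single
imaging session measure, in the same subject, the metabolic rate of glucose
(MRGlu) and the extracellular volume fraction (ECV, a fibrosis surrogate)
*before* (10–40 min), *during* (60–90 min) and *after* (120–150 min)
suppression that starts at 40 min.

`cardiact` implements the full quantification chain for that experiment,
for imaging scientists who want a tested, reproducible, scriptable version
of it:

* **Patlak graphical analysis** per protocol window:
  with x(t) = ∫₀ᵗ Cp dτ / Cp(t) and y(t) = Ct(t)/Cp(t), irreversible FDG
  kinetics give y = Ki·x + V′ where Ki = K₁k₃/(k₂+k₃); MRGlu = Ki·glucose/LC.
* **ECV from T1**:
  ECV = (1 − hct) · (ΔR1 myocardium)/(ΔR1 blood), with R1 = 1/T1, at 40, 90
  and 150 min (hct = 0.45 by default).
* **Histology**: Rényi-entropy thresholding (α ∈ {0.5, 1, 2}, ImageJ-style
  three-threshold combination) and integrated density for punctate
  immunofluorescence; channel-dominance percent fibrosis for trichrome
  slides; per-region summaries.
* **Volume budget**: viable-myocyte bound = 1 − ECV − fibrosis −
  fibroblasts.
* **Statistics**: paired t, Bonferroni, exact Mann–Whitney (full
  enumeration for small n), Pearson, Shapiro–Wilk normality gate.
* **Synthetic-data generators** for every input — seeded plasma/tissue
  kinetics, T1 sampling, trichrome and puncta slides with known ground
  truth, and a voxel grid emulating slow Gd penetration of the obstructed
  infarct core — so the whole pipeline is testable without animal data.

See `vignettes/cardiact-methods.Rmd` for the models, assumptions, defaults
and limitations.

## Worked example

```r
library(cardiact)

protocol <- infusion_protocol()      # 150 min, windows 10-40 / 60-90 / 120-150
total_gd_dose(protocol)
#> [1] 0.6                            # mmol/kg Gd-DTPA over the infusion

# simulate irreversible FDG kinetics and recover Ki by Patlak analysis
plasma <- simulate_plasma_curve(protocol, rate = protocol$fdg_rate,
                                vd = 150, kel = 0.015, grid = 0.5)
tissue <- simulate_tissue_fdg(plasma, fdg_kinetics(K1 = 0.1, k2 = 0.15, k3 = 0.05))
pts <- patlak_points(frame_curve(tissue, 3), frame_curve(plasma, 3))
fit_patlak(pts, c(120, 150))
#> <patlak_fit [120, 150] min: Ki = 0.025101 /min, intercept = 0.4619, r2 = 1.0000, n = 10>
# analytic Ki = K1*k3/(k2+k3) = 0.025: recovered within 0.5%

compute_ecv(1100, 500, 1600, 300)    # native/post T1 myo, native/post T1 blood
#> <ecv_result: ECV = 0.2215>

volume_budget(0.48, 0.04, 0.04)      # day-5 infarct ledger
#> <volume_budget: ECV 0.48 + fibrosis 0.04 + fibroblast 0.04 -> myocytes <= 0.44 (59% of baseline 0.75)>

percent_change(0.109, 0.027)         # infarct MRGlu decrease (printed means)
#> [1] 75
percent_change(0.083, 0.007)         # remote MRGlu decrease
#> [1] 91

mann_whitney(c(1, 2), c(3, 4))       # exact enumeration for small samples
#> <Mann-Whitney U (exact): statistic = 0, p = 0.3333, n = 2+2>
```

The numbers mean: the simulated late-window Patlak slope recovers the
programmed net influx constant; the example T1 quartet gives a healthy-range
ECV of 0.22; the day-5 ledger leaves at most 44 % of infarct volume for
viable myocytes (59 % of the healthy 75 % baseline); and the printed cohort
means correspond to 75 % (infarct) and 91 % (remote) MRGlu decreases under
integer truncation.

## End-to-end run

```sh
# full pipeline: simulate a 7-subject cohort, Patlak + ECV + histology +
# budget + statistics, deterministic report.json / report.md
Rscript inst/cli/cardiact run --out run1 --seed 7

# or stage by stage
Rscript inst/cli/cardiact simulate --out sim --seed 7
Rscript inst/cli/cardiact patlak --tissue sim/tissue_fdg_infarct.csv \
        --plasma sim/plasma_fdg.csv --glucose 5.5 --out fit.json
Rscript inst/cli/cardiact ecv --t1 sim/t1.csv --native-myo 1100 \
        --native-blood 1600 --out ecv.json
Rscript inst/cli/cardiact budget --ecv 0.48 --fibrosis 0.04 \
        --fibroblast 0.04 --out budget.json
```

(After installation the launcher is at
`system.file("cli", "cardiact", package = "cardiact")`.)

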