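# sicklevol

Linking sickle-cell physiology to brain volume: hematocrit-corrected
pCASL perfusion quantification, volumetric and oxygen-content
derivations, silent-infarct burden accounting, and per-exposure
regression families with false-discovery-rate control — plus a
synthetic cohort/ASL generator with known ground truth so the whole
chain is verifiable without clinical data.

## Who this is for

Researchers analyzing brain MRI in sickle cell disease (SCD) or other
anemias, where standard ASL quantification defaults (healthy-adult
blood T1, labeling efficiency and arrival times) are wrong, and where
the scientific questions are of the form *"is exposure X associated
with tissue volume Y after controlling for age, sex and intracranial
volume?"* across correlated exposures (disease status, hemoglobin,
CBF, arterial oxygen content, infarct burden).

## The models at the core

**Perfusion.** CBF is recovered per voxel from the single-compartment
solution of the flow-modified Bloch equation,

```
deltaM = 2 alpha M0 (f / 6000 lambda) exp(-BAT/T1b) T1t S(tau, PLD, BAT)
```

with `S` the post-bolus decay term when `PLD >= BAT` and the
during-bolus uptake term while the bolus is still arriving (white
matter, with arrival times of 1.9–2.0 s, is sampled in that regime by
both supported protocols). Blood T1 is individualized from the measured
hematocrit via `1/T1b = 0.52 Hct + 0.38`; labeling efficiency defaults
to 0.72 in SCD. The model is linear in flow, so inversion is exact, and
`deltaM/M0` is scale-invariant.

**Physiology and burden.** `CaO2 = SaO2 x Hgb x 1.37`;
`WMV = (total brain volume excl. ventricles) - GMV`; a lesion counts as
a silent cerebral infarct only if it is at least 3 mm in one plane and
visible in a second plane (the SIT-trial criterion); total burden is
log10-transformed for regression, which excludes zero-burden
participants.

**Association.** One OLS family per exposure — each outcome volume
regressed on `exposure + age + sex + icv` — with Benjamini–Hochberg
correction applied within that family only (2 outcomes in the primary
analysis, 66 structures in the regional one). A log-burden coefficient
`c` reads as `c` mL of predicted volume change per 10-fold burden
increase.

## Worked example

```r
library(sicklevol)

## quantify a noiseless synthetic study generated at a known CBF
prot <- asl_protocol("pediatric")
sim <- generate_asl_study(protocol = prot, grid = asl_grid(c(8, 8, 3)),
                          cbf_gm = 82.47, hct = 0.27, group = "SCD")
map <- quantify_cbf(sim$study, prot, sim$gm_params, sim$wm_params)
print(map)
#> CBF map: GM mean 82.47, WM mean 40.41 ml/100 g/min (0 GM / 0 WM voxels excluded)

blood_t1_from_hct(0.27)
#> [1] 1.921599

## recover a generating regression coefficient at study scale
rec <- replicate_coefficient_recovery("log10_burden", reps = 200, seed = 1)
sprintf("mean fitted coefficient %.2f (truth %.1f, MC SE %.2f)",
        rec$mean_coefficient, rec$truth, rec$mc_se)
#> [1] "mean fitted coefficient -30.61 (truth -30.2, MC SE 0.90)"

d <- decade_deficit(rec$mean_coefficient, 0.1, 1.0)
sprintf("%.1f mL predicted WMV change per 0.1 -> 1 mL burden decade (%.1f-fold)",
        d$predicted_change, d$ratio)
#> [1] "-30.6 mL predicted WMV change per 0.1 -> 1 mL burden decade (34.0-fold)"
```

The first block shows exact forward–inverse closure: quantification
returns the generating ground truth (82.47 ml/100 g/min in gray
matter; the white-matter truth defaults to 0.49× that). The second
block simulates 200 cohorts of 31 lesion-positive SCD participants
whose white-matter volumes were generated with a true log-burden
coefficient of −30.2 mL per decade, refits the family each time, and
recovers the truth within Monte-Carlo error; the predicted deficit for
a 0.1 → 1 mL burden increase is ~34 times the 0.9 mL burden change
itself.

An end-to-end run (cohort → per-participant quantification →
demographics → regression families → report JSON):

```r
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/sicklevol.R` (subcommands `simulate`, `quantify`,
`demographics`, `analyze`, `run-all`).

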