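---
title: "Methods: perfusion quantification and volumetric association models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion quantification and volumetric association models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicklevol)
```

## The problem this package addresses

Sickle cell disease (SCD) produces chronic anemia, low arterial oxygen
content, compensatory elevation of cerebral blood flow (CBF), and silent
cerebral infarcts (SCIs). Whether — and by how much — these exposures are
associated with global and regional brain-volume deficits is a question
that couples three methodological pieces:

1. **CBF quantification from pCASL** that is valid in anemia, where blood
   T1, arrival times and labeling efficiency all differ from healthy
   adults;
2. **volumetric accounting** (gray matter volume, white matter volume by
   subtraction, intracranial volume, silent-infarct burden under the
   SIT-trial lesion criterion);
3. **per-exposure regression families** relating each physiologic
   exposure to tissue volumes with age, sex and ICV as covariates and
   false-discovery-rate control within each family.

`sicklevol` implements all three, together with a synthetic cohort and
ASL-study generator with known ground truth, so the entire chain is
testable end to end without access to clinical data.

## The kinetic model

Quantification inverts a single-compartment solution of the
flow-modified Bloch equation for a pCASL experiment with label duration
$\tau$ and post-labeling delay $PLD$. Labeled arterial magnetization
decays with blood T1 ($T_{1b}$) during the transit time $BAT$, and with
tissue T1 ($T_{1t}$, 1.2 s) after arrival. With acquisition at
$t = \tau + PLD$ after label onset:

$$
\Delta M \;=\; 2\,\alpha\, M_0\, \frac{f}{6000\,\lambda}\;
e^{-BAT/T_{1b}}\; T_{1t}\; S,
\qquad
S =
\begin{cases}
\bigl(1 - e^{-\tau/T_{1t}}\bigr)\, e^{-(PLD-BAT)/T_{1t}}, & PLD \ge BAT\\[4pt]
1 - e^{-(\tau + PLD - BAT)/T_{1t}}, & BAT \le \tau + PLD
\end{cases}
$$

where $f$ is CBF in ml/100 g/min, $\lambda$ = 0.9 ml/g is the
blood–brain partition coefficient and the factor $6000\lambda$ owns the
unit conversion (one function, `.kinetic_factor()`, holds it).
$\Delta M$ is linear in both $f$ and $M_0$, so the inverse is a single
division and the ratio $\Delta M / M_0$ is invariant to global signal
scaling.

**Why the during-bolus branch exists.** White matter arrival times
(2.0 s in controls, 1.9 s in SCD) exceed both supported post-labeling
delays (1.9 s adult, 1.65 s pediatric), so white matter is routinely
sampled while the tail of the bolus is still arriving. A model
restricted to $PLD \ge BAT$ could not quantify WM CBF under either
protocol; the piecewise form above covers the regime continuously (the
two branches agree at $PLD = BAT$). Only when $\tau + PLD \le BAT$ has
no labeled blood arrived at all, and the package raises an error rather
than returning a zero-division artifact.

**Hematocrit correction.** Blood T1 is computed per participant from
the measured hematocrit using the arterial relaxivity relationship
$1/T_{1b} = 0.52\,\mathrm{Hct} + 0.38$ (s$^{-1}$). Anemia lengthens
$T_{1b}$, preserving more label through transit; ignoring this inflates
apparent CBF differences between anemic and healthy participants.
Dependence of $T_{1b}$ on blood oxygenation (arterial vs. venous differ
by roughly 0.2 s) is not modeled.

### Parameters, defaults, and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| $\alpha$ (SCD) | 0.72 | — | labeling efficiency measured at sickle-cell flow velocities |
| $\alpha$ (control) | 0.85 | — | conventional pCASL efficiency; configurable |
| $\lambda$ | 0.9 | ml/g | whole-brain partition coefficient |
| $T_{1t}$ | 1.2 | s | tissue T1 at 3 T |
| $BAT$ GM | 1.10 / 1.02 | s | control / SCD arrival times |
| $BAT$ WM | 2.00 / 1.90 | s | control / SCD; WM transit is slower |
| PLD, $\tau$ (adult) | 1.9, 1.0 | s | age-titrated protocol |
| PLD, $\tau$ (pediatric) | 1.65, 1.65 | s | faster arrival in children |
| M0 floor | 0.1 | fraction of within-mask median | excludes near-zero-M0 voxels before division |

The control labeling efficiency is the one constant with no
population-specific measurement behind it; it is exposed as an argument
and flagged here deliberately.

### Numerical choices in quantification

- **Drift removal.** A per-voxel linear trend in repeat index is
  removed with the repeat mean preserved exactly, so detrending can
  never bias the mean difference signal — it only shrinks its variance.
  Series with fewer than three repeats skip detrending (a line is not
  identifiable); `detrend_series()` itself refuses them.
- **M0 floor.** Voxels with M0 at or below 10% of the within-mask
  median are flagged invalid and excluded from tissue means; the count
  is reported. This guards the division by M0 at mask edges.
- **Negative estimates are retained.** Under zero-mean noise the
  voxelwise estimator is linear and unbiased; clipping negative values
  would bias tissue means upward. Tissue means therefore average all
  valid voxels, negatives included.
- Tissue means use GM kinetic parameters inside the GM mask and WM
  parameters inside the WM mask, as two independent inversions.

## Derived physiology and burden accounting

- $\mathrm{CaO_2} = \mathrm{SaO_2} \times \mathrm{Hgb} \times 1.37$
  (ml O2/100 g blood); SaO2 is canonically a fraction, and inputs that
  look like percentages are rejected rather than silently rescaled.
- $\mathrm{WMV} = \text{total brain volume excluding ventricles} -
  \mathrm{GMV}$.
- A candidate lesion counts as a silent infarct only if it measures at
  least 3 mm in some plane **and** was confirmed in a second imaging
  plane; the second-plane confirmation is inherently a manual
  radiological judgement and enters as a boolean flag. Burden is the sum
  of qualifying lesion volumes, in mL throughout. Its base-10 logarithm
  is undefined at zero burden, so zero-burden participants are excluded
  from log-burden regressions and the exclusion count is logged.

## Regression families and FDR control

For each exposure of interest (SCD status, hemoglobin, GM CBF, CaO2,
log10 burden) a *separate* family of ordinary-least-squares models is
fitted — one per outcome volume — each with design
`[intercept, exposure, age, sex, icv]`. The exposures are strongly
mutually correlated (they are all facets of the same disease), so
separate families quantify each one as a standalone biomarker and avoid
collinear multi-exposure models. Choices made here:

- **Sex coding**: male = 1, female = 0; coefficient signs follow.
- **ICV enters as a covariate**, never as a ratio denominator.
- **p-values** are two-sided t tests with $n - 5$ residual degrees of
  freedom.
- **Benjamini–Hochberg** step-up correction is applied *within* one
  exposure's family only (2 outcomes in the primary analysis, 66 in the
  regional analysis); families never share a correction pool, and
  fitting one family can never change another's adjusted p-values.
- **Complete cases** within each family; usable-row counts are carried
  in the results.
- The log-burden family is restricted to SCD participants with nonzero
  burden by construction.

**Decade interpretation.** Because burden enters as log10, a
coefficient $c$ means $c$ mL of predicted volume change per 10-fold
burden increase, independent of where the decade starts. For a burden
increase from 0.1 to 1 mL, the predicted deficit is $|c|$ mL against a
0.9 mL burden change — a ratio of $|c|/0.9$. The ratio depends only on
the decade, not on burden units.

## Demographics machinery

Two-group comparisons dispatch the way clinical cohort tables do:
Welch's t-test for normal continuous data (summarized mean (SD)),
Mann–Whitney U otherwise (median (IQR)), chi-squared for categorical
data, and Fisher's exact test for small cell counts. Decisions:

- Normality under `normal = "auto"` uses Shapiro–Wilk at $\alpha$ = 0.05
  per group; an explicit override pins any row.
- "Small cell counts" means any expected *or* observed cell below 5;
  degenerate tables (e.g. perfect separation with zero cells) therefore
  get the exact test even when expected counts equal 5.
- The 2×2 chi-squared uses the Yates continuity correction: verified by
  simulation, the corrected statistic tracks the exact test to well
  under 0.01 at large balanced counts, while the uncorrected one can
  differ from it by ~0.1 even at hundreds per group.
- All tests are two-sided.

## What the synthetic generator emulates — and what it does not

The generator's defaults reproduce the marginal structure of a
reference cohort of 88 SCD participants and 49 healthy controls aged
7–32: hemoglobin N(9.04, 1.37²) g/dL in SCD vs. N(13.28, 1.57²) in
controls (hematocrit via the clinical rule of three, Hct = 0.03·Hb;
real-data paths take measured hematocrit directly), SaO2 centered at
0.96 vs. 0.98 with IQR-derived spreads, GM CBF N(82.47, 17.92²) vs.
N(50.64, 8.9²) ml/100 g/min, 35% SCI prevalence among SCD participants
with exponentially distributed total burden (mean 0.3 mL — configurable;
an exponential with the observed 0.14 mL median would have mean
≈ 0.20 mL), and ICV N(1400, 120²) mL. Healthy controls never carry
lesions, mirroring the enrolment exclusion. Tissue volumes are generated
from *one* designated exposure's true coefficients (the effect table)
plus age/sex/ICV covariate effects and Gaussian residual (SD 40 mL,
consistent with observed volume SDs of 55–75 mL once covariate variance
is accounted for; the generating residual variance of the reference
analysis is unknown, so validation rests on coefficient recovery, not on
matching dispersion). Sub-threshold distractor lesions are injected so
the SIT-trial filter is genuinely exercised.

The ASL simulator evaluates the forward model on a labeled block grid
with a smooth, deterministic M0 field, i.i.d. Gaussian repeat noise and
an optional linear drift.

Deliberately **not** emulated: brain geometry, partial-volume mixing,
motion (only drift detrending is in scope), coil artifacts, spatially
correlated noise, exposure collinearity beyond what the group structure
induces, and measurement error in labs. Passing recovery tests therefore
demonstrates the correctness of the computational chain under its own
assumptions — not robustness to the full messiness of clinical images.

## Validation design and problem sizes

- **Closure**: forward simulation followed by quantification recovers
  the generating CBF field to better than 1e-9 relative error for every
  protocol dialect × group × tissue-class combination, on 8×8×3 grids.
- **Coefficient recovery**: 500 replicate cohorts of 137 (SCD status and
  hemoglobin as generating exposures) and 1000 replicate cohorts of 31
  lesion-positive SCD participants (log burden); the replicate mean of
  the fitted WMV coefficient is required to sit within 2 Monte-Carlo
  standard errors of the generating truth.
- **FDR control**: 1000 replicate null cohorts, each with the full
  66-structure family; the fraction with any BH discovery at
  $\alpha$ = 0.05 must not exceed 0.05 beyond Monte-Carlo error.
- **Oracle equivalence**: the OLS path is checked against an explicit
  normal-equations solver, Fisher against hypergeometric enumeration,
  Mann–Whitney against full rank enumeration, and BH against
  hand-computed step-up cases.
- **Power**: an injected caudate effect of −0.0053 mL per ml/100 g/min
  of GM CBF at the default regional noise (8% CV) is detected by the
  BH-corrected 66-structure family in over 80% of replicates at n = 137.

## Known limitations

- The during-bolus branch assumes plug flow without dispersion; no
  multi-delay transit-time estimation, vascular crushing or
  partial-volume correction is attempted.
- Blood T1 ignores oxygenation dependence.
- Plain OLS only: no robust, clustered or mixed-effects variants.
- ICV is an input, never estimated.
- The 66-structure roster is a configurable default; analyses with a
  different roster emit a warning (or an error in strict mode) rather
  than silently proceeding.
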