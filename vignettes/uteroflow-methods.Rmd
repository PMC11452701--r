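---
title: "Methods: personalised utero-ovarian haemodynamics and biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalised utero-ovarian haemodynamics and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`uteroflow` implements a reduced model of the maternal circulation for
studying non-invasive biomarkers of early-onset pre-eclampsia. The larger
arteries (ascending aorta down to the internal iliac / uterine path, 24
segments in the full topology) carry one-dimensional pulse-wave propagation;
every truncated systemic bed is a three-element Windkessel; each uterine
artery discharges into a utero-ovarian cascade — an ascending-uterine
resistance feeding two RC compartments that stand for the arcuate and the
combined radial+spiral beds, draining at venous pressure. A closed-loop
heart is deliberately out of scope: the aortic root receives a prescribed
periodic half-sine ejection parameterised by cardiac output and heart rate,
whose one-period integral is exactly the stroke volume `SV = CO/HR`.

The 1D equations are solved in `(A, u)` form,

$$\partial_t A + \partial_x (Au) = 0, \qquad
  \partial_t u + \partial_x\!\left(\tfrac{u^2}{2} + \tfrac{P}{\rho}\right)
  = -\frac{8\pi\mu}{\rho}\frac{u}{A},$$

with the tube law \(P = \beta(\sqrt{A} - \sqrt{A_0(x)})\) and characteristic
speed \(c = \sqrt{\beta\sqrt{A}/2\rho}\). Two numerical points deserve
emphasis because they were load-bearing during development:

* **Well-balancedness.** The `(A, Q)` conservative form is not
  well-balanced on tapered vessels — a uniform-pressure rest state
  generates spurious fluxes of the order of the taper. The `(A, u)` flux
  \(u^2/2 + P/\rho\) is exactly balanced at rest for arbitrary \(A_0(x)\),
  which is why it was chosen.
* **Characteristic boundary sources.** \(u \pm 4c\) are Riemann invariants
  only for uniform \(A_0\). With taper they drift along characteristics at
  rate \((\beta/\rho)\,d\sqrt{A_0}/dx\), which for a 25% area change over a
  few centimetres is comparable to the flow velocity itself. Omitting this
  source in the boundary extraction produces a *stable but wrong* steady
  state (interior flux decoupled from the injected flow). All boundary and
  junction couplings therefore integrate the geometric and friction sources
  along the characteristic foot.

The utero-ovarian cascade couples its compartment compliances inversely to
the distal resistance fraction (\(C \propto \varphi^{-3/2}\), referenced to
the normal bed at \(\varphi = 0.65\)). This encodes the pathophysiology the
package exists to study: deficient spiral-artery remodelling leaves narrow,
muscular — hence stiff — vessels, so a more resistive distal bed is also a
less compliant one. With a fixed compliance the diseased bed would be
*more* low-pass filtered and the arcuate pressure pulsatility would lose
its disease signal, which is backwards.

The interior scheme is Richtmyer two-step Lax–Wendroff with a weak
second-difference filter whose per-step coefficient is scaled by the local
CFL number (so the implied diffusion is independent of the time step; the
grid-convergence test would fail otherwise). Junctions impose continuity of
static pressure and flow through a damped Newton solve on the segment-end
areas; total-pressure continuity was rejected as a second-order refinement
at these velocities. Terminal Windkessels and the cascade compartments are
updated semi-implicitly; the stand-alone cascade integrator is fully
implicit in the entry flow so that the zero-compliance (purely resistive)
limit is a fixed point rather than a divergence.

The time step is taken from the CFL bound with a safety factor and
re-checked every step (violation is an error naming segment and time);
cycles repeat until the cycle-to-cycle relative L2 pressure difference over
all monitored sites falls below `tol` (default 1e-3, maximum 20 cycles).

## Personalisation ("digital twin")

The calibration loop (`calibrate()`) is a damped multiplicative fixed-point
iteration, chosen over a generic optimiser because each target has a
near-monotone one-parameter handle:

| target | handle | update |
|---|---|---|
| MAP (= DBP + PP/3 of the measured pressures) | total Windkessel resistance | ratio^0.9 |
| pulse pressure | total Windkessel compliance | secant-inverted ratio |
| PWV | global stiffness multiplier \(k_\beta\) | ratio^2 (exact: \(d\log c / d\log k_\beta = 1/2\)) |
| uterine mean velocity (per side) | cascade chain resistance | secant-inverted ratio |
| uterine RI (per side) | cascade distal fraction \(\varphi\) | secant on the odds \(\varphi/(1-\varphi)\) |

Weak-leverage handles get their local log–log sensitivity estimated by
secant and inverted (safeguarded to a factor 8 of nominal). Two secondary
handles engage only when a primary one saturates: a global vessel-area
scale when compliance stops moving the pulse pressure (the terminals are
impedance-matched, so beyond a point the root pulse is just the incident
wave \(Z_c\,Q_{max}\)), and an entry inertance on the cascade when the RI
target lies below the "resistive floor"
\((P_{2,max}-P_{2,min})/(P_{2,max}-P_{ven})\) that a purely
resistive-capacitive cascade cannot undercut. Convergence means every
relative residual (MAP, PP, PWV, per-side uterine mean velocity and RI) is
at or below `rel_tol` (default 2%); otherwise the best iterate is returned
flagged, and downstream feature assembly excludes and reports the patient.

The aortic area `A` entering the dimensionless biomarkers is the
time-average at the ascending-aorta midpoint of the converged run; the
reported systemic compliance is the sum of all compliances of the
calibrated model (1D tube-law + Windkessel + cascade), with `SV/PP` used
only as the initial guess. MAP uses the clinical one-third rule; note this estimator differs from the
waveform time-mean by several percent, so recovery experiments compare
like with like (targets vs calibration residuals).

## Biomarkers

All biomarker inputs are converted to coherent SI units, so the six
Buckingham-Pi groups are dimensionless by construction:
\(\pi_1 = R_{ut}/R_{periph}\), \(\pi_2 = SV^2/A^3\),
\(\pi_3 = CO\,R_{periph}/P_{syst}\), \(\pi_4 = C_{syst}P_{syst}/A^{3/2}\),
\(\pi_5 = R_{periph}\,A\,PWV/P_{syst}\), \(\pi_6 = \Delta P_{pulse}/P_{syst}\).
A seventh dimensionless term is sometimes listed alongside these but has
no published definition; the pipeline deliberately omits it rather than
guess. The waveform indices are
\(PPI = (P_{max}-P_{min})/P_{mean}\) (pressure pulsatility, the package's
analogue of a Doppler index on the predicted downstream pressures),
\(RI = (V_{max}-V_{min})/V_{max}\) and \(PI = (V_{max}-V_{min})/V_{mean}\)
(the standard Doppler definition). Means are time-averages over the final periodic cycle on its
uniform grid; the `PPI` denominator could equally be the mid-range
\((P_{max}+P_{min})/2\); the time-average was chosen and is used
consistently. The analysis side defaults to the right, with the left
computed for symmetry checks.

## Synthetic cohort: the stated world

The generator emulates the published two-group summary table (12 "NPE" vs
9 "PE" records) with independent truncated normals per parameter per group
— gestational age, parity, BMI, SBP, DBP, HR, CO, PWV, age, weight, PI, RI
— using the published means/SDs. Decisions where the source is silent:

* **Truncation bounds** are physiological envelopes placed at least ~2 SD
  from the group means (truncation bias on means/SDs under 1–2%, verified
  by test). Uterine RI is bounded to (0.28, 0.92): mid-gestation uterine RI
  below ~0.3 is not observed clinically, and the reduced cascade has a
  floor near that value.
* **SBP–DBP coupling.** The marginals-only design is exposed (set
  `bp_correlation = 0`), but the default draws the pair through a Gaussian
  copula with correlation 0.6. Independent draws produce pulse pressures
  down to ~1 mmHg — records no measurement could yield and for which the
  haemodynamic model has no solution. This is a deliberate deviation from
  the identity-correlation default, made for physical realism, not to pass
  a test.
* **Peak systolic velocity** (not in the published table): 65 ± 15 cm/s,
  literature-typical at mid-gestation; `D = S(1 - RI)` so each record's RI
  is exact by construction. Left/right sides couple through a copula with
  correlation 0.9 — a stated guess, not inferred from the source.
* **Waveform template**: half-sine systolic rise to S, exponential
  diastolic decay rescaled to close the period exactly at D. Only S, D and
  the derived indices enter the analysis.
* The PE group differs through its published distributions (higher RI/PI,
  SBP, CO, PWV; lower HR) plus an optional uterine-resistance multiplier
  (`effect_config$r_ut_multiplier`, default 1.5) used in forward,
  non-calibrated what-if runs.

What a green synthetic-cohort test does **not** establish: the generator
has no measurement-error model, no within-patient covariance beyond the two
copulas, and no outcome variables; reproducing any specific clinical cohort's
accuracies is therefore out of reach by construction, and the acceptance
checks are directional (computational indices beat systemic blood
pressures) rather than numerical reproductions.

## Classification suite

Welch's two-sided t-test is used for the per-feature p-values (a deliberate default; the power calculation separately uses the one-tailed design it emulates). Cohen's d uses the pooled SD and is reported as
an absolute value. The supervised protocol holds out one patient per class,
fits a maximum-likelihood logistic regression on the remaining 19 (with an
internal stratified 2-fold CV recorded as a sanity metric), scores the
pooled train+test predictions at probability 0.5, and averages over 5
repeats; the accuracy interval is a Wilson 95% half-width (a deliberate default). AUC is the midrank Mann–Whitney statistic on
all data. Unsupervised evaluation runs *exact* one-dimensional 2-means on
the standardized feature — in 1D every optimal partition is a sorted split,
so the WCSS minimum is found by scanning all n−1 splits (deterministic, no
initialisation sensitivity) — maps clusters to labels by majority vote
(ties: the higher-mean cluster is the disease class), and reports
confusion-matrix percentages; the decision threshold is the centroid
midpoint on the raw scale. DeLong's structural-components test compares
correlated AUCs; degenerate variance returns p = 1 with a warning. The
sample-size routine searches the smallest integer n with noncentral-t power
at least the target. No multiple-testing correction is applied, matching
the emulated analysis.

When cohorts are screened for the qualitative claim that downstream
computational indices outperform systemic blood pressures, the clinical
features (SBP/DBP) are evaluated on the *full* cohort: they are measured on
every patient and need no calibrated twin, and restricting them to
twin-converged patients would impose a selection artifact (calibration
feasibility correlates with pressure). Note also that the generating
distributions themselves give SBP a genuine standardized separation of
about 0.46, so its single-feature accuracy sits a few points above the
majority-class rate even under a perfect evaluation — "blood pressure is
an inappropriate screen" here means "20+ accuracy points behind the
utero-ovarian indices", not "exactly at chance".

## Known limitations

* The cascade velocity RI at the uterine artery cannot fall below the
  resistive floor without the inertance handle; records drawn outside the
  model's feasible envelope (extreme PP, RI) are flagged non-converged and
  excluded, which the feature table reports explicitly.
* PWV is matched through the tube-law speed at the ascending aorta rather
  than a carotid–femoral transit time.
* The default tree geometry is literature-typical configuration, not a
  measured anatomy, and the `reduced` topology (15 segments) trades wave-path detail for a
  ~3x speedup in cohort-scale batch runs.
* Network and pipeline configuration files use JSON rather than YAML (no
  YAML parser in the supported dependency set).
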