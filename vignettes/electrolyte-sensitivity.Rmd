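---
title: "Electrolyte sensitivity of human atrial electrophysiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrolyte sensitivity of human atrial electrophysiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atrialyte)
```

## The scientific problem

Patients with recent-onset atrial fibrillation (AF) frequently present with
plasma electrolyte imbalances — most often low potassium (hypokalaemia) and,
increasingly recognised, low sodium (hyponatremia). `atrialyte` implements a
multiscale in-silico framework for quantifying how clinically plausible
variations of extracellular potassium, sodium and calcium
(reference values 4.5, 140 and 1.8 mM; ranges ±1.5 mM, ±25% and ±25%)
alter human atrial electrophysiology: the single-myocyte action potential,
conduction in tissue strands and sheets, the inducibility and longevity of
re-entrant arrhythmias on fibrotic substrates, and the attribution of those
endpoint changes back to individual electrolytes and membrane currents.

No patient data enters the pipeline: a synthetic-substrate generator emulates
the statistical structure of an LGE-MRI-derived atrial cohort (image
intensity ratios, six tissue classes, fibrotic burden 21% ± 15% over 0–70%),
so the full analysis runs end-to-end from configuration alone.

## The cell model

The core is the Courtemanche–Ramirez–Nattel (CRN) human atrial myocyte model
(21 states, 12 membrane currents), extended in three ways ("CRN++"):

1. **Electrolyte parameterisation.** Every reversal potential is recomputed
   from the extracellular set the current sees
   (`E = RT/zF · ln(c_out/c_in)`), and [K+]o, [Na+]o, [Ca2+]o enter the
   INaK and INaCa carrier expressions directly.
2. **Potassium-sensitive rectifiers.** The IK1 and IKr conductances are
   multiplied by `(Ko/anchor)^exponent` (defaults: anchor 5.4 mM — the CRN
   native value — and exponent 0.5). This is the standard square-root
   conductance dependence of inward-rectifier channels on external potassium
   ("cross-over effect") and is what gives the model its marked RMP and
   late-repolarisation sensitivity to small [K+]o changes. Both constants
   are exposed in `crn_parameters()` so an alternative functional form can be
   substituted without code changes.
3. **Optional variable ECa.** The original CRN ICaL driving term is the fixed
   constant `V − 65 mV`; setting `variable_ECa = TRUE` replaces 65 mV by the
   Nernst calcium potential so that ICaL responds directly to [Ca2+]o.
   The default keeps the original formulation.

Fibrosis remodelling (`apply_fibrosis_remodelling()`) downregulates GNa by
40%, GK1 by 50% and GCaL by 50%, with apply-once semantics.

**Per-current override masks.** For current-level attribution the model can
evaluate any subset of currents with a *perturbed* electrolyte set while all
remaining currents see the *reference* set (`override_mask()`). With the
all-perturbed mask and equal sets the code path is bitwise identical to the
unmasked model. `attribution_gsa()` uses these masks to measure, e.g., how
much of the APD variance under [Na+]o variation flows specifically through
INaCa.

## Numerics

One integration scheme is used everywhere: Rush–Larsen exponential updates
for the 15 gating variables (from tabulated steady states and time constants,
0.05-mV lookup grid with linear interpolation) and forward Euler for the
membrane potential and the 5 intracellular concentrations. The default step
is 0.02 ms for single cells and strands and 0.05 ms for 2D sheets. A single
frozen path makes every trace bit-reproducible across runs and between the 0D
and tissue code. The test suite re-integrates the baseline action potential
with an adaptive stiff solver (deSolve::lsoda, rtol 1e-8) as an independent
oracle; the two agree within 1.2 ms in APD90 (0.4%), well inside the
biomarker tolerances used anywhere downstream. State layout and evaluation
order are frozen so golden numbers in the tests remain valid.

The monodomain equation `Cm ∂V/∂t = −I_ion + I_stim + ∇·(D∇V)` is solved by
operator splitting with flux-form finite differences and no-flux boundaries.
Diffusivity derives from conductivity as `D = σ/(β Cm)` with β = 1400 /cm
and Cm = 1 µF/cm². The six-region conductivity table
(`conductivity_table()`, longitudinal 0.300…0.075 S/m) was fixed once so
that the healthy baseline strand conducts at 0.68 m/s — inside the
physiological 0.6–0.8 m/s band — and fibrotic rows conduct at roughly half
that; it is declared package configuration (the source cohort's per-region
values are not public) and fully overridable. The explicit scheme is guarded
by the FTCS stability bound, checked before stepping.

**Stimuli.** Rectangular, 2 ms wide, at twice the diastolic threshold. The
threshold of the baseline myocyte at its CL-1000 limit cycle is 13.3 pA/pF
(found once by bisection, `find_diastolic_threshold()`), giving the package
default of 26.6 pA/pF; tissue stimuli use twice that to overcome the local
electrotonic load.

## Protocols and biomarkers

* **0D:** `prepace()` delivers a stimulus train (the full study conditions
  are 15 minutes at fixed cycle length; see *Problem sizes* below) and
  reports a limit-cycle residual — the max-norm relative difference between
  the states at the last two beat starts. It is reported, not enforced, since
  the protocol pre-paces for a fixed duration regardless. `ap_biomarkers()`
  measures RMP (pre-stimulus minimum), upstroke time (argmax dV/dt),
  amplitude, plateau peak (maximum V in a 10–120 ms window after the spike
  peak) and APD70/APD90 as times to 70/90% recovery of the amplitude from
  the upstroke time, with linear interpolation of the crossing.
* **Tissue maps:** LAT = argmax ∂V/∂t per node on the second of two paced
  beats 1000 ms apart; LRT = 90% recovery of the local amplitude;
  APD90 = LRT − LAT; nodes with amplitude < 40 mV are masked. Local CV is
  `1/|∇LAT|` by central differences (one-sided at edges, gradient floor
  0.5 ms/cm to mask block plateaus). Strand CV uses the two-point formula
  `0.5 cm / (LAT(0.75 cm) − LAT(0.25 cm))`, which the tests verify against a
  least-squares LAT regression to within 1%.
* **QoIs:** medians (mAPD, mCV) and 2.5–97.5 inter-percentile ranges
  (DAPD, DCV) over valid nodes — percentile method: linear interpolation
  between order statistics (quantile type 7); masked nodes are excluded
  rather than imputed — plus their relative variations against the
  substrate's baseline run.

## The synthetic substrate generator

The generator emulates what the pipeline needs from an imaging-derived
cohort, nothing more:

* a spatially correlated IIR-like field — filtered Gaussian noise (separable
  Gaussian kernel, correlation length 5 mm, a qualitative stand-in for patchy
  LGE patterns) mapped through a monotone exponential so the fraction of
  nodes above the fibrotic boundary 1.22 *exactly* equals a per-substrate
  target drawn from the cohort distribution (normal, mean 0.21, sd 0.15,
  clipped to [0, 0.70]);
* segmentation into six classes at thresholds 0.90, 1.05, 1.15, 1.22, 1.32
  (only 1.22 is anchored by the source analysis; the other four cut-points
  are declared configuration). Classes above 1.22 receive remodelled cell
  parameters and reduced conductivities;
* three stimulus boxes in normalized sheet coordinates standing in for
  universal atrial coordinates: CS-analogue (0.5–0.7 × 0.8–0.9),
  LAA-analogue (0.9–0.91 × 0.9–0.91) and roof-analogue (0.48–0.49 ×
  0.48–0.49). This is an analogy, not a UAC implementation; on coarse desk
  sheets an empty box after discretisation expands to the nearest node with
  a warning;
* a lognormal per-substrate surface-area jitter (sd 0.15) supplying the
  cohort classifier's area feature.

What passing tests on these substrates do *not* show: fidelity to real
atrial anatomy, wall-thickness effects, fibre architecture, or the true
spatial statistics of LGE enhancement — only the marginal fibrosis-burden
statistics and the region/conductivity bookkeeping are calibrated.

## Sensitivity analysis

Designs are plain Latin hypercubes (30 rows by default, one sample per
equal-probability stratum per column, via the `lhs` package) with the
reference combination appended as row 31. Inputs are treated as independent
and uniform over the stated ranges (the source analysis does not state a
weighting). Each quantity of interest gets a Gaussian-process emulator —
anisotropic squared-exponential kernel with nugget, inputs scaled to the
unit cube, hyperparameters by marginal-likelihood optimisation with seeded
restarts — and Sobol indices are estimated on the emulator mean by the
Saltelli pick-freeze scheme (Jansen estimators for S1 and ST, the
Saltelli-2002 cross-matrix estimator for closed second-order indices;
N a power of two, 1024 by default). Raw estimates are reported as-is; small
negative values are clamped to zero only inside the normalised "doughnut"
fractions, which sum to one by construction. Emulator-mediated GSA is the
default everywhere for speed; `sobol_indices()` accepts any function, so
direct simulation at reduced N is a drop-in.

## Arrhythmia induction and endpoints

Two burst protocols deliver 5 stimuli at CL 700 ms at the CS-analogue,
a 400 ms pause — anchored at the last S1 onset, a choice this package states
explicitly since the protocol phrasing is ambiguous — then 5 stimuli at
CL 160 ms at the LAA- or roof-analogue, and track the tissue for 5 s beyond
the final stimulus. The third protocol imposes a four-spiral initial state:
a 2×2 arrangement of Archimedean spiral phase fields with alternating
chirality, phases mapped to states sampled along the CL-300 limit cycle
(the phase-distribution method). The arm winding length defaults to 10 cm,
of the order of the tissue's natural wavelength CV×CL; much tighter winding
leaves no excitable gap and the pattern collapses immediately — each
quadrant is then effectively a pinwheel whose rotation period self-selects.

Episode classification (the source criteria are not public; these thresholds
are declared configuration): *induced* = any node with ≥ 3 activations after
the final stimulus at mean cycle length < 500 ms; *terminated* = induced but
quiescent (no activations, all voltages within 10 mV of the local diastolic
minimum) during the final 200 ms of the window; *dominant frequency* =
reciprocal of the mean inter-activation interval over active nodes —
activation-interval based rather than FFT, which is more robust on short
records. Runs that self-sustain after a single mapping stimulus
(`screen_single_stimulus()`) are flagged and excluded from the paced QoI
tables, with their electrolyte context retained.

## Machine-learning attribution

Binary endpoints are classified by seeded logit, random-forest or
gradient-boosting models (`train_classifier()`, random forest being the
reporting default), guarded to require at least two samples per class. The
reported score is the coefficient of determination of the predicted class
probability against the 0/1 labels — the analysis this package follows
reports "R²" without defining the target, so the probability-based reading
is used and accuracy plus AUROC are reported alongside for transparency.
Permutation importance permutes each feature column 100 times and reports
the mean ± sd score drop. Shapley values are computed *exactly* by
enumerating all feature subsets against a background sample (interventional
value function); with 3–5 features this costs at most 32 subset evaluations
per row and gives local accuracy `Σφ + base = prediction` to machine
precision for every classifier kind, random forests included.

## Problem sizes (desk and paper profiles)

`atrialyte_config(profile = )` bundles the scale knobs. The `paper` profile
encodes the full-scale study conditions: 15-minute pre-pacing trains,
30-row designs, 100 substrates, 5-s tracking. The `desk` profile, used by
the examples and the test suite, scales the same pipeline to a workstation:
40-beat pre-pacing (the limit-cycle residual at 40 beats is already ~6e-3),
1.0–6.0 cm sheets at 250–500 µm spacing, 4-row designs for structural
checks, 2.2–3 s tracking windows. The arrhythmia-induction desk sheet is
6 × 6 cm at 500 µm with conductivities scaled by 0.5 (`sigma_scale`),
representing the diffusely slowed bulk conduction of the dilated, remodelled
AF-prone atrium on which re-entry is sustainable at that size; under
hyponatraemia it sustains four-spiral re-entry for the full tracking window
at a dominant frequency of ≈ 3.3 Hz, inside the clinical AF band.

## Design choices on genuinely open points

* **0D APD measure:** APD70/APD90 as percent-repolarisation from the
  upstroke time, not from a take-off potential.
* **RMP:** the pre-stimulus minimum, not the whole-diastole minimum.
* **IK1/IKr modification:** the square-root conductance scaling described
  above; anchor and exponent are configuration.
* **Non-activated nodes** are excluded from map statistics.
* **Burst pause anchoring:** 400 ms from the last S1 onset.
* **Classifier validation:** per-substrate mode trains on the 31 rows of one
  substrate; cohort mode pools all rows with the fibrosis and area features.
* **Integration:** fixed-step Rush–Larsen everywhere (see *Numerics*) with
  an adaptive-solver oracle in the tests rather than in the product path.

## Known limitations

Fibroblast–myocyte electrotonic coupling is not modelled (the remodelling is
purely a conductance/conductivity change). The CRN calcium subsystem is
rudimentary and the INaCa current–voltage relation quasi-linear, so
calcium-mediated effects should be read qualitatively. Sheets are isotropic
2D stand-ins for 3D atrial anatomy: absolute CV maps and induction rates are
not patient-scale quantities, and the desk-profile induction results
demonstrate mechanism, not epidemiology. The GP emulator assumes smooth
QoI response over the electrolyte box; near conduction block (low [K+]o
corner) the CV response steepens and emulator-mediated indices inherit that
approximation.
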