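---
title: "Single-beat RV-PA coupling: model, estimator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-beat RV-PA coupling: model, estimator and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvpac)
```

## The problem

Right-ventricular (RV) function in pulmonary hypertension is best judged
not by contractility alone but by how well contractility is matched to
afterload. The single-beat method quantifies this as the coupling ratio
Ees/Ea, where Ees = (Pmax − mPAP)/SVi is end-systolic elastance, Ea =
mPAP/SVi is effective arterial elastance, mPAP is mean pulmonary artery
pressure, SVi is stroke volume indexed to body weight, and Pmax is the
peak pressure the ventricle *would* have generated had the pulmonary
valve stayed shut. Pmax is not observable in an ejecting beat; the
single-beat method estimates it by fitting a sine wave to the two
isovolumic phases of the RV pressure curve (before valve opening and
after valve closure) and reading the apex of that sine. Per recording,
each index is summarized as the median over at least ten consecutive
beats, and end-systolic PA pressure is taken equal to mPAP.

`rvpac` implements this pipeline — beat segmentation, isovolumic-window
location, the sine fit, the coupling indices — together with the
surrounding desk-scale analyses of a CTEPH (chronic thromboembolic
pulmonary hypertension) animal study: body-weight-indexed haemodynamic
indices, embolization-protocol arithmetic, gravimetric and histological
ratios, relative gene expression by the ΔΔCt method, and small-sample
permutation statistics. Because animal recordings cannot be bundled, the
package ships a ground-truthed simulator that generates everything the
pipeline consumes.

## The synthetic generator

### Ventricle and afterload

The ventricle is a time-varying elastance: P(t) = E(t)·(V(t) − V0), with
E(t) sweeping from `emin` to `emax` under a raised-cosine activation
that peaks (value 1) at `t_peak`. Defaults place the activation peak at
26% of the beat period with equal rise and fall widths of 21% of the
period, i.e. a systolic fraction near 40% of the cycle, which is
physiological for juvenile swine at heart rates of 100–240/min. Equal
widths have a useful structural consequence: the whole activation is a
single half-cosine, so pressure during *any* closed-valve interval is
exactly a segment of one sinusoid in time. The isovolumic peak of a
clamped beat is then exactly `emax * (ved - v0)` (`clamp_isovolumic()`),
which is the oracle every Pmax estimate is judged against.

The ventricle ejects through a diode valve (forward flow only when
ventricular pressure exceeds proximal arterial pressure) into a
three-element windkessel: characteristic impedance `zc`, compliance
`c_art`, and peripheral resistance `rp` draining into a fixed outflow
pressure `p_out` (default 5 mmHg, the left-atrial level). The outflow
floor matters twice: it keeps diastolic PA pressure physiological, and
it makes a genuinely non-ejecting scenario possible — if
`emax*(ved - v0)` never exceeds the floor, the valve never opens and the
scenario is flagged `non_ejecting` rather than erroring.

Refilling is modelled without an atrium: volume returns to `ved` along a
smooth raised-cosine ramp over the last 12% of the cycle, after the
valve has closed. Per beat, the time-integral of outflow therefore
equals Ved − Ves exactly, which the test suite asserts as a conservation
invariant.

### Numerics

Integration is fixed-step explicit Euler at `oversample` (default 10)
times the output sampling rate, with the output grid an exact subgrid;
reproducibility across machines was preferred over adaptive-step
efficiency, and the conservation test bounds the integration error.
Charging beats are discarded until the beat-boundary windkessel pressure
is periodic to one part in 10^10 (at least 5 beats, at most 500, an
explicit error beyond that). An adaptive criterion is needed because the
windkessel time constant `rp*c_art` can exceed two seconds: a fixed
short discard leaves the downstream pressure drifting, which subtly
shifts valve-opening times from beat to beat.

Measurement noise is additive white Gaussian on the pressure channels
only, plus an optional sinusoidal respiratory baseline; the flow channel
stays clean, matching the character of fluid-filled catheter pressure
lines paired with a transit-time flow probe. The default output rate is
250 Hz — a declared convention, as acquisition rates for such recordings
are typically unreported.

### What the generator does not emulate

Beats are strictly periodic (no heart-rate variability or arrhythmia),
noise is white (no catheter resonance or baseline drift beyond the
respiratory sinusoid), the valve is ideal, and there is no atrium,
closed-loop circulation, or reflex control. Passing tests therefore
demonstrate that the analysis recovers known truth under clean,
controlled violations — not that it is robust to every artefact of real
recordings.

## Beat segmentation and isovolumic windows

Beat onsets are upstroke crossings of 20% of the local cycle's maximal
dP/dt, with a 150 ms refractory period; a crossing must hold for at
least 3 samples (12 ms at 250 Hz) so that single noise spikes cannot
spawn beats. The derivative is a Savitzky–Golay local quadratic over 11
samples at 250 Hz (scaled with the sampling rate), which preserves the
dP/dt extrema while suppressing sample-level noise. Because everything
runs on the derivative, segmentation is invariant to constant pressure
offsets. Partial cycles at the trace edges are discarded.

Isovolumic windows come in two conventions. The dP/dt convention
(default when only pressure is available) takes contraction from onset
to the dP/dt maximum and relaxation from the dP/dt minimum to the point
where pressure first falls back below its onset value (sustained for 3
samples, again to resist noise dips). When the matched flow trace is
supplied, windows are instead delimited by the valve events the flow
marks: contraction ends at the last zero-flow sample before ejection and
relaxation starts at the first zero-flow sample after it. The valve
convention is the physiological definition of "isovolumic" and excludes
early-ejection samples that the dP/dt landmarks admit (the measured
dP/dt maximum can fall a few samples after valve opening); the full
analysis pipeline always uses it.

## The sine fit

### Why not a single common sine

In an elastance ventricle the two isovolumic limbs are scaled copies of
one underlying sinusoid: contraction-phase pressure is
(Ved − V0)·E(t) while relaxation-phase pressure is (Ves − V0)·E(t).
Fitting one sine with a common amplitude through both limbs therefore
aims at a compromise between the end-diastolic and the (smaller)
end-systolic scale, and its apex underestimates the clamped-valve peak —
by 15–40% in our simulations, growing with ejection fraction. The
isovolumic peak of a clamped beat retains the end-diastolic scale, so
`fit_sine()` by default fits the scaled two-limb model
P(t) = k·(B + C·sin(ωt + φ)) — shared frequency and phase, per-limb
offset and amplitude — and reads Pmax off the contraction limb. The
classic common-amplitude fit remains available as
`fit_sine(..., scaled = FALSE)`.

### Identifiability and the carrier

The fit is linear for fixed (ω, φ), so those two are profiled on a grid
(60 log-spaced ω values spanning 0.9–3 times π over the window span, 181
phase values) and refined by Nelder–Mead. Two physical constraints pin
the right basin: the carrier's crest must lie inside the inter-window
(ejection) gap, and the preceding trough must not postdate the start of
the contraction window.

Even so, (ω, φ) are weakly identified from the short windows of a single
noisy beat: window arcs of 10–20 samples can be matched by many
frequencies once per-limb phase is free, and the apex is an
extrapolation that amplifies carrier error several-fold. The package
therefore estimates the carrier once per recording, on an ensemble beat
formed by averaging all usable beats aligned at their valve-opening
sample (an alignment landmark the clean flow channel gives exactly).
Each individual beat then contributes one linear amplitude scale fitted
to the ensemble template over its own contraction window, so per-beat
Pmax values remain beat-specific — preserving the median-over-beats
summary — while the ill-conditioned shape parameters are shared.
`estimate_pmax()` implements this; `analyze_coupling()` builds the
coupling indices on top of it.

Against the clamped-valve oracle over a 4×3×2 grid of contractility
(0.5–3 mmHg/mL), heart rate (100–200/min) and peripheral resistance, the
noiseless recovery error stays within a few percent. At 2 mmHg pressure
noise most grid cells stay within 10%, but in the lowest-pressure cells
(Emax 0.5 mmHg/mL, where the isovolumic peak is only ~25 mmHg and the
noise is nearly a tenth of the signal amplitude) the recording-level
carrier occasionally drifts enough to push the error above 15%. We
quantified this as an information limit rather than an estimator defect:
the residual-sum profile over ω is shallower there than the sampling
fluctuation of the noise floor. Validation at that noise level uses
30-beat recordings (the method's "at least 10" is a floor, and longer
captures are routine); the tests report the worst cell honestly.

### Per-beat indices and the summary

For each usable beat, mPAP is the mean PA pressure over that beat's own
span and SVi is the trapezoidal flow integral over the beat divided by
body weight, so every beat is self-contained. Beats whose fitted Pmax
does not exceed their mPAP are flagged non-physiological and excluded;
`summarize_coupling()` takes medians over the usable beats, enforces the
ten-beat floor (overridable explicitly), and records how many beats were
excluded. The identities Ees/Ea = Pmax/mPAP − 1 and
Ees·SVi + mPAP = Pmax hold to machine precision by construction and are
asserted in the tests.

## Haemodynamic indices and protocol arithmetic

`cardiac_index()` (1000·CO/BW), `stroke_volume_index()` (CI/HR),
`vascular_resistance_indices()` (mPAP/CI and mAoP/CI, with CI in
L/min/kg so that a resting systemic value is of order 500–900),
`stroke_work()` (mPAP·SV — a declared convention, since no right-atrial
pressure is measured to subtract), `fulton_index()` (RV/LV plus
weight-indexed masses) and `capillary_metrics()` are deliberately plain,
unit-checked arithmetic. `microsphere_count()` converts an infused
microsphere mass to a count (default 700 µm polyethylene spheres of
density 1.13 g/cm³) and reports both the raw value and the value rounded
to the nearest 500, the granularity protocol doses are quoted at.
`embolization_decision()` encodes the induction protocol's stopping and
re-embolization rules as a pure decision function; the tests check it
against an independent brute-force restatement over an exhaustive grid.

## Relative expression (ΔΔCt)

`normalize_ddct()` normalizes each target Ct against the arithmetic mean
of a three-gene reference panel (equivalent to geometric-mean
normalization of reference expression), calibrates ΔCt against the mean
of the control group, and converts with efficiency 2 per cycle (an
`efficiency` argument exists but no efficiency correction is applied by
default, matching common practice). With this calibration the geometric
mean of control-group expression is exactly 1 for every gene. Samples
missing any reference Ct are excluded entirely; samples missing a target
Ct are dropped for that gene with a logged count. The synthetic Ct
generator plants known fold-changes, per-sample loading shifts (which
normalization must cancel) and replicate noise, so calibration,
invariance and recovery are all checkable to machine precision or by
Monte Carlo.

## Statistics

The study-scale statistics are intentionally minimal: ordinary least
squares with the two-sided slope-from-zero t-test and r² (plus a seeded
permutation cross-check), Welch's t for two groups (with a seeded
permutation alternative), and a permutation interaction test for the
group × condition question: the statistic is the difference between
group means of the within-subject exercise-minus-rest delta, and the
null is built by permuting group labels over subjects. For small cohorts
the test enumerates all assignments exactly. A mixed-model repeated
measures ANOVA is deliberately not re-implemented: at seven animals per
arm a permutation test is exact without any covariance-structure
assumptions, and the package documents this as a substitution, not an
equivalence.

Monte-Carlo p-values use the add-one convention
p = (1 + #{|T*| ≥ |T|})/(1 + B), which is valid (never anti-conservative)
at any B; all are seeded and reproducible.

## The synthetic cohort

`generate_cohort()` builds paired rest/exercise recordings for a control
and a CTEPH arm. Base conditions: control rest at HR 136 with Emax 0.60
mmHg/mL and normal resistance; exercise raises HR to ~235 and Emax by
~80% with a small resistance drop, so coupling improves. The CTEPH arm
carries ~2.5× peripheral resistance and partial hypertrophic
compensation at rest (Emax 0.95) but a blunted exercise reserve (Emax
+15%, resistance unchanged), so coupling starts lower and stays flat or
falls. Animals get log-normal parameter jitter (6% CV) and individual
noise seeds, all derived from one master seed. These settings express
the qualitative physiology the study reports — reduced coupling in
CTEPH, an exercise coupling reserve only in controls — and were fixed
once; the package makes no attempt to match measured group means.

Problem sizes used by the validation suite: 12-beat recordings for
noiseless checks, 30-beat recordings for the 2 mmHg noise grid, 7 + 7
animals for the cohort contrast, 100 Monte-Carlo seeds for ΔΔCt
recovery, 10⁵ permutations for the analytic-vs-permutation comparison.

## Known limitations

- Pmax estimation at very low RV pressures (isovolumic peak ≲ 30 mmHg)
  with 2 mmHg catheter noise can exceed 15% error; see the
  identifiability discussion above.
- The valve-event window convention requires a clean flow channel; with
  pressure-only data the dP/dt convention admits slight early-ejection
  contamination.
- Stroke work omits right-atrial pressure by convention.
- The ΔΔCt implementation is the textbook formulation; proprietary
  vendor "gene study" normalizations may differ in detail.
- The simulator's elastance ventricle is the same model family the
  single-beat method assumes; agreement here cannot detect model
  misspecification that real ventricles might exhibit.
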