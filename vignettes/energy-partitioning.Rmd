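---
title: "Energy system partitioning for cluster-set resistance exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy system partitioning for cluster-set resistance exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergopart)
```

## The problem

Cluster sets (CS) break a resistance-exercise set into small clusters of
repetitions separated by short (here 30 s) rests; traditional sets (TS)
perform all repetitions continuously. The short rests are thought to allow
partial phosphocreatine (PCr) resynthesis, preserving barbell velocity at
the cost of a different metabolic profile. Quantifying that profile
non-invasively is what the three-component PCr-La-O₂ method does: it
attributes energy turnover to the aerobic, anaerobic alactic (PCr) and
anaerobic lactic (glycolytic) pathways from breath-by-breath oxygen
uptake and blood lactate alone.

`ergopart` implements the method for intermittent exercise, together with
the velocity-loss metrics and the crossover statistics used to compare the
two set structures, and a synthetic-session generator that stands in for
measured data.

## The model and its assumptions

Post-exercise oxygen uptake is modelled as

$$\dot{V}O_2(t) = a\,e^{-t/\tau_a} + b\,e^{-t/\tau_b} + c,$$

with amplitudes $a, b \ge 0$ (L/s), time constants
$5 \le \tau_a \le 120 < \tau_b \le 1800$ s, and baseline $c \ge 0$ (L/s).
The fast component is read as PCr resynthesis, the slow component as the
lingering elevation of oxidative metabolism. The partition rests on three
modelling assumptions worth keeping explicit:

1. **Uniform repayment.** Short rests do not allow reliable curve fitting,
   so the $(a, \tau_a)$ estimated on the final 900-s recovery are re-used
   unchanged for every intra- and inter-set rest window, each window's
   local clock starting at zero. This assumes equal fast-component
   repayment after every cluster and set.
2. **Attribution of rest-window uptake.** The measured rest-window
   integrals of baseline-adjusted uptake are subtracted from the exercise
   phase, so aerobic energy reflects work periods only; the alactic credit
   uses the modelled fast component over those same windows. The slow
   component during rests is deliberately attributed to neither. A config
   switch (`rest_attribution = "modelled"`) subtracts the modelled rather
   than measured rest integrals (fast component for intra-set rests, fast
   plus slow for inter-set rests) for sensitivity analyses.
3. **Time-independent lactic estimate.** Anaerobic lactic energy is the
   baseline-to-peak lactate rise converted at
   3 mL O₂ · kg⁻¹ · mmol⁻¹ · L, regardless of when the peak occurs. The
   pre-final-set sample is quality control only and enters no formula.

Oxygen volumes convert to energy at 20.92 kJ per litre O₂. Relative
shares are each component over the three-component sum; they are
model-based indices and should be read qualitatively.

## Preprocessing choices

Breath-by-breath series are irregular; the pipeline resamples them to a
1-s grid by linear interpolation, applies a centred 10-point moving
average, and converts the declared unit (L/min, mL/min or mL/kg/min via
body mass) to litres per second.

An even-length "centred" window is ambiguous, so it is defined here as the
mean of samples $i-5 \dots i+4$ (toggle `centring = "right"` for
$i-4 \dots i+5$), shrinking at the series edges. Two consequences are
handled explicitly rather than ignored:

* **Phase.** A left-heavy window delays the smoothed curve by half a
  second. The shift is recorded on the smoothed series and the recovery
  fit compensates its time base accordingly; otherwise every fitted
  amplitude would carry a systematic $e^{\pm 0.5/\tau}$ bias.
* **Transition smear.** Around the work-to-recovery transition the window
  (and the breath interpolation) mixes rising work-phase samples into the
  first seconds of recovery. The fit therefore excludes grid points within
  `edge_guard_s` (default 10 s) of the recovery start. On noiseless
  synthetic sessions this guard is the difference between a ~10% and a
  ~0.03% error on $\tau_a$.

Negative smoothed values are clipped to zero with a warning.

## Fitting

Estimation is bounded nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`). Starting values: $c_0$ = mean of the final 120 s of the
window, $a_0 = 0.7\,(y_1 - c_0)$, $b_0 = 0.3\,(y_1 - c_0)$, time-constant
starts (30, 300) s; if the first attempt fails, a five-point multi-start
over the time-constant starts is tried. The bounds encode the
physiological fast/slow separation at 120 s. After fitting, components are
ordered so $\tau_a < \tau_b$; swapped starting values therefore yield the
identical ordered solution. Non-convergent fits are flagged and refused by
the energy operations unless forced. The default fit window is the full
900-s final recovery; fits are per session (no sharing of $c$ across a
participant's sessions, which the data cannot identify anyway).

Numerical integration of measured series uses the trapezoidal rule on the
1-s grid with linear interpolation at fractional window edges; modelled
components integrate in closed form,
$a\tau(1-e^{-D/\tau})$.

## Timeline conventions

The session clock starts at $t = 0$ at the beginning of the baseline
segment; all windows live on this clock, and the timeline (baseline, work,
intra-set rest, inter-set rest, final recovery) is contiguous by
construction. Work-segment durations are inputs — repetition tempo is not
part of the protocol definition — with 3.5 s per repetition as the
synthesis default. Rest is taken to start at the work segment's end; when
an annotation file marks the recovery start manually, that mark is
authoritative. The exercise phase runs from the `exercise_start_s` mark,
so any pre-set anticipatory rise before it is excluded by construction.

A negative lactate rise (peak below baseline) is floored at zero with a
warning by default; `negative_policy = "allow"` propagates it, which makes
near-zero lactic shares possible in cluster-set sessions — both variants
are tested.

## The synthetic generator

The generator emulates the study conditions: 4 × 6 back squats with 180-s
inter-set rests and a 900-s seated recovery, CS adding 30-s rests after
repetitions 2 and 4; a ~5.4 mL·kg⁻¹·min⁻¹ baseline
(0.0065 L/s at 72 kg); breaths every ~3 s with ±30% uniform jitter;
Gaussian noise at 5% of peak modelled uptake; a mono-exponential rise
toward the work demand (0.045 L/s above baseline, τ = 20 s) during work;
and a bi-exponential decay during every rest, re-anchored at each rest
onset from the current elevation with the fast:slow split in the
configured $a\!:\!b$ ratio (0.028:0.012, τ 35/240 s) so the modelled
uptake is continuous at transitions. Velocity fatigue accumulates 0.04
per repetition and decays with τ = 60 s during rests; lactate accumulates
0.25 mmol/L per repetition once fatigue exceeds 0.08 and clears linearly
at 0.002 mmol/L/s during rests. These values were chosen once to land in
the physiological ranges typical of heavy back-squat sessions and are not
fitted to any dataset.

The ground-truth ledger integrates the generative components in closed
form over the timeline under the same attribution rules as the analysis
(including the uniform-repayment rule, using the final-recovery fast
amplitude). Tests require the full pipeline on noiseless sessions to
reproduce truth shares within 2 percentage points and $(a, \tau_a, c)$
within 1%; the residual gap reflects on/off-kinetics overlap at segment
transitions, not estimation error.

What the generator does **not** emulate: Valsalva-driven breathing
artefacts, breath-by-breath outliers, participant-specific on-kinetics,
day-to-day variation between a participant's two sessions, or any
mechanistic PCr/glycolysis dynamics. Passing tests therefore demonstrate
correctness of the pipeline under the stated generative model, not
validity of the PCr-La-O₂ assumptions on real data. One visible
consequence: the protocol effect is far more homogeneous across synthetic
participants than across real ones, so standardized effect sizes
(paired *t*, Hedges' *g*) come out much larger than published values even
though all directions and the share magnitudes are realistic.

## Statistics

Velocity loss differences (CS − TS) use Student's paired *t*; lactate
rises use the Wilcoxon signed-rank test with an exact two-sided p obtained
by enumerating all $2^n$ sign assignments of the ranked absolute
differences for $n \le 12$ (midranks keep the enumeration exact under
ties; zero differences are dropped with a warning). Hedges' *g* for paired
data standardises the mean difference by the SD of the difference scores
with the correction $1 - 3/(4\,df - 1)$ — the variant consistent with
jointly reported *t* and *g* values at $n = 6$. Shapiro–Wilk supports the
choice between the two tests. Relative shares enter a linear mixed model
`rel_pct ~ system * protocol + (1 | participant)` with Satterthwaite
type-III tests and Holm-adjusted protocol contrasts per system; the
percentage response is used untransformed, and its compositional
non-independence (shares sum to 100) is acknowledged rather than
corrected. α = 0.05 two-sided throughout.

## Problem sizes in the test suite

The suite exercises the closed-form integrals against a Δt = 0.01 s
trapezoidal oracle (100 random triples), parameter recovery on 900-s
1 Hz recoveries (200 noisy replicates against a 20-replicate brute-force
grid-search bound), 100 seeded CS/TS session pairs for the directional
end-to-end property, and six-participant cohorts for the inferential
layer — sizes chosen to pin the numerics while keeping the default test
run in the tens of seconds.

## Known limitations

* The uniform-repayment assumption cannot be checked from the data the
  method uses; sessions with strongly drifting elevation will bias the
  alactic credit of early rests.
* $\tau_a$ is weakly identified under realistic noise (median relative
  errors near 10% at 0.003 L/s noise); single-session fast-component
  parameters should be interpreted with that uncertainty in mind.
* The lactic component inherits every caveat of converting a single
  peak-minus-baseline concentration into energy.
* Vendor export schemas vary; the readers take a column mapping and a
  declared unit rather than guessing.
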