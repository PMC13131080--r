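# ergopart

Three-component energy partitioning (the PCr-La-O₂ method) for
intermittent resistance exercise, with velocity-based training metrics and
the small-sample crossover statistics that go with them.

`ergopart` is aimed at exercise physiologists who record breath-by-breath
oxygen uptake, barbell velocity and capillary blood lactate during
resistance-exercise sessions — in particular cluster-set (CS, short
intra-set rests) versus traditional-set (TS, continuous repetitions)
protocols — and want a tested, reproducible pipeline from raw streams to
relative energy-system contributions.

## The method

Post-exercise oxygen uptake is modelled as a bi-exponential decay

$$\dot{V}O_2(t) = a\,e^{-t/\tau_a} + b\,e^{-t/\tau_b} + c$$

where $a$ and $b$ are the amplitudes of the fast and slow components,
$\tau_a < \tau_b$ their time constants, and $c$ the baseline oxygen uptake.
The three energy components of one session are then

* **aerobic** — the baseline-adjusted uptake $\max(\dot{V}O_2 - c,\,0)$
  integrated over the exercise phase, with the measured rest-window
  integrals removed so that only work periods count;
* **anaerobic alactic** — the fast component $a\,e^{-t/\tau_a}$ integrated
  in closed form, $a\tau_a(1-e^{-D/\tau_a})$, over every rest window of the
  session (the 900-s final recovery, each 180-s inter-set rest and, for CS,
  each 30-s intra-set pause), crediting phosphocreatine resynthesis;
* **anaerobic lactic** — the baseline-to-peak rise in blood lactate
  converted at 3 mL O₂ · kg⁻¹ · mmol⁻¹ · L.

Oxygen volumes become energy at 20.92 kJ per litre O₂, and the three
components are reported absolutely (kJ) and as shares of their sum (%).
Velocity loss (VL) per set is the percentage drop in mean propulsive
velocity from the fastest to the last repetition, averaged across sets.
The inference layer covers the two-condition crossover: paired *t* with
Hedges' *g* (difference-score standardisation, small-sample correction
$1-3/(4\,df-1)$), an exact Wilcoxon signed-rank test by full sign
enumeration for n ≤ 12, and a linear mixed model
`rel_pct ~ system * protocol + (1 | participant)` with Satterthwaite
type-III tests and Holm-adjusted protocol contrasts per system.

Because the package ships no measured data, a synthetic-session generator
produces complete CS/TS sessions (irregular breaths, noise, per-repetition
fatigue, protocol-dependent lactate) from a known ground-truth energy
ledger, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(ergopart)

cfg     <- synthetic_config(seed = 42)
session <- generate_session(cfg, protocol_spec("CS"))
report  <- analyze_session(session)
report
#> <session_report> S1 / CS
#> <biexp_fit> a = 0.0162 L/s (tau_a = 43.4 s), b = 0.0042 L/s (tau_b = 226.9 s), c = 0.0067 L/s
#>   rss = 0.00126 (L/s)^2 over 890 points from t = 984 s
#>   energy: aerobic 21.8 kJ (15.1%), alactic 117.1 kJ (80.8%), lactic 6.0 kJ (4.1%)
#>   session VL 12.3%, lactate rise 1.32 mmol/L, baseline 5.59 mL/kg/min
```

The fitted recovery has a fast component of 0.0162 L/s repaying over
τₐ ≈ 43 s (phosphocreatine resynthesis), a small slow component, and a
baseline equivalent to 5.6 mL·kg⁻¹·min⁻¹. For this cluster-set session
the alactic pathway dominates (80.8% of the partitioned energy), and the
session lost 12.3% of its mean propulsive velocity.

A full crossover cohort:

```r
cohort     <- generate_cohort(n_participants = 6, seed = 1)
sessions   <- analyze_cohort(cohort)
comparison <- compare_cohort(sessions)
comparison
#> VL paired t: t(5) = -31.75, p = 0.0000, g = -10.92
#> Lactate rise Wilcoxon: V = 0, p = 0.0312 (g = -4.91)
#> Energy LMM interaction: F(2, 30.0) = 18.73, p = 5.3e-06
```

Cluster sets preserve velocity (mean VL 12.5% vs 19.8%), accumulate less
lactate (rise 1.34 vs 2.92 mmol/L) and shift the partition toward the
alactic component (71.7% vs 54.3%); the system × protocol interaction of
the mixed model is the formal test of that shift. `autoplot()` on a fit,
`plot_mpv()` and `plot_energy_shares()` draw the standard figures.

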