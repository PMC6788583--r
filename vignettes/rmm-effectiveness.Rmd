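---
title: "Estimating emission-reduction effectiveness from concentration decay traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating emission-reduction effectiveness from concentration decay traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmmeff)
```

## The problem

Workplace risk management measures (RMMs) for volatile solvents — partial
or full enclosure, local exhaust ventilation ("elephant trunk"), drum pumps
with submerged loading, drain-and-flush before maintenance — are
communicated through standard safety-data-sheet phrases, each with an
assumed efficiency. Validating those efficiencies requires measuring how
much less solvent vapour a controlled transfer releases than an
uncontrolled one. The raw observable is a concentration–time trace from a
static IR probe logging every 20 s in a fan-mixed room; the quantity of
interest is a *relative* emission reduction, so the evaluation must be
insensitive to the absolute probe reading, which shifts with equipment
placement and personnel movement.

## The one-box model and the extrapolated concentration

The room is treated as a single well-mixed box of volume $V$ with
air-exchange rate $\lambda$ (ACH, h⁻¹) and ambient background $B$:

$$\frac{dC}{dt} = S\,\mathbf{1}_{[t_\mathrm{start},\,t_\mathrm{end}]}(t)
  \;-\; \lambda\,(C - B),$$

where $S$ is the emission source expressed directly as a
concentration-equivalent rate (ppm min⁻¹ delivered to the mixed volume).
This parameterisation deliberately bypasses evaporation physics: no
absolute source strengths or probe-capture efficiencies are available for
the experiments being emulated, and the analysis needs only the decay
structure. During the source-on phase the solution rises toward a plateau,
$B + (S/\lambda)(1 - e^{-\lambda \Delta t})$; after source-off it relaxes
exponentially to background.

The post-transfer limb, background-subtracted, is $y_0 e^{-kt}$ with $t$ in
minutes from the end of the transfer. The intercept $y_0$ — the
**extrapolated concentration** (EEC for ethanol) — approximates the
hypothetical mean room concentration the activity built up, and is far more
reproducible across replicates than any direct probe statistic. Crucially,
$60k$ must equal the room's independently known air-exchange rate; this is
the physical constraint that disciplines the fit.

### Assumptions

* Perfect mixing (a fan ran continuously in the experiments this emulates);
  no near-field/far-field structure.
* First-order ventilation loss at a constant, known rate
  ($\approx 1$ h⁻¹ ventilation off, $11 \pm 1$ h⁻¹ on).
* Constant source rate while the transfer runs; nothing after it ends.
* The probe adds multiplicative (relative) noise.

## EEC estimation

`compute_eec()` chains three steps, each exported for direct use.

**Background** (`estimate_background()`): the median concentration over the
pre-event window $[0, t_\mathrm{start})$, requiring at least 10 samples.
The median is robust to the occasional movement spike; an externally
measured background can be supplied instead.

**Window selection** (`select_decay_window()`): the trendline points are
the crux of the method. Candidate windows are enumerated on the sampling
grid — start offsets 0–10 samples after the first post-event sample,
lengths from 5 samples up to every contiguous admissible point — and a
candidate is admissible only if

1. every point lies at or above the *positivity floor*
   $\max(0.1\ \mathrm{ppm},\ 1\%\ \mathrm{of\ peak\ excess})$ — the log
   transform degenerates as the signal approaches background;
2. its log-linear fit implies an air-exchange rate within `ach_tol`
   (default $\pm 1$ h⁻¹, the operating band of a ventilated room) of the
   trace's target;
3. its log-space $R^2$ is at least `min_r_squared` (default 0.9).

Among admissible candidates the longest wins; ties go to the higher $R^2$.
The $R^2$ floor deserves a note: with 20-s sampling and 5% relative noise, a
5-point window's implied ACH has a standard error near 3 h⁻¹, so the rate
constraint alone can be satisfied by chance on a trace whose true decay is
quite different. Requiring the window to actually look log-linear
suppresses those spurious matches, so a trace recorded under a
misunderstood ventilation state is reported **unfittable** (a typed
condition naming the best achieved rate) rather than silently fitted on a
lucky segment.

**Fit** (`fit_decay()`): ordinary least squares of
$\log(C - B)$ on $t$ (minutes from transfer end). `eec_ppm` is the
exponentiated intercept, `ach_fit` is $-60 \times$ slope, and the log-space
$R^2$ is retained as a quality metric. Log-linear OLS defines the reference
numbers; it is the transparent, spreadsheet-reproducible estimator the
method was designed around.

**Degenerate inputs.** If no post-event sample exceeds the background by
more than three pre-event standard deviations, the trace shows *no
observable emission* (NoE) and the EEC is reported as not determinable —
this is a result, not an error (a fully enclosed vented transfer genuinely
produces one). Empty candidate sets raise the unfittable condition.

**Drain/flush traces** are evaluated differently: their brief, small
excursions do not support a decay fit, so `mean_concentration_between()`
takes the arithmetic mean of all samples between lid opening and closing,
without background subtraction.

## Effectiveness statistics

`summarize_scenario()` reduces replicate values to mean, extrema and the
coefficient of variation (sample, $n-1$ standard deviation — required for a
replicate set such as 12, 14, 13 ppm to give CV 7.7%). At least two values
are required; the underlying study design used a minimum of three.

`emission_reduction()` computes, from unrounded summaries,

$$\mathrm{min} = \Bigl(1 - \frac{E_{H,x}}{E_{L,b}}\Bigr) \cdot 100,\quad
  \mathrm{optimal} = \Bigl(1 - \frac{E_{L,x}}{E_{H,b}}\Bigr) \cdot 100,\quad
  \mathrm{mean} = \Bigl(1 - \frac{E_{M,x}}{E_{M,b}}\Bigr) \cdot 100.$$

The ordering min ≤ mean ≤ max follows from $E_L \le E_M \le E_H$ in both
scenarios and is property-tested. Negative reductions are reported, never
clamped — a misapplied control can genuinely worsen emissions.
`incremental_reduction()` applies the same formulas with a second
controlled scenario as the denominator. Reporting precision follows the
field's tables: concentrations to integer ppm, CVs and reductions to one
decimal.

Where a published reduction cell disagrees with recomputation from the
published (rounded) replicate values, the recomputed value is authoritative
here: the original tables were evidently computed from unrounded instrument
readings that are not available. `audit_printed_reductions()` recomputes
every cell, flags the mismatches (they differ by at most 0.1 percentage
points, plus the incremental drum-pump band, whose recomputation gives
88.9–93.9% against a printed 89.6–93.2%), and logs rather than fails.

## The synthetic-data generator

`simulate_trace()` samples the closed-form piecewise solution of the
one-box balance on the 20-s grid — the closed form is the reference
implementation; a brute-force Runge–Kutta integration exists only as a test
oracle — then adds two noise components (`noise_model()`):

* multiplicative lognormal noise, `multiplicative_sd = 0.05` on the log
  scale;
* movement spikes: Poisson arrivals at `spike_rate_per_min = 0.2`, heights
  exponential with mean `spike_magnitude = 0.1` of the clean excess at
  arrival. A vapour pocket registers at the probe only while it drifts
  past, so its signature washes out on a ~30 s transit scale (or the room
  scale if faster). Letting spikes persist at the room's own ventilation
  rate would make each one mathematically indistinguishable from transfer
  vapour — every spike would back-extrapolate to ~10% of the EEC and bias
  the fit upward without bound on the number of spikes — which is neither
  what movement artefacts look like in real recordings (short peaks) nor
  compatible with their observed small effect on extrapolated values.

Identical seeds give byte-identical traces; `generate_scenario_set()`
derives per-trace seeds as `seed + 1000 * scenario_id + replicate`.

### Scenario presets and calibration

`scenario_presets()` encodes the nine study scenarios: gravity transfer
(4 min, 50 l at 12.5 l min⁻¹) with and without enclosure/extraction,
drum-pump transfer (1 min at 50 l min⁻¹), and drain/flush. Ventilation-off
scenarios run at ACH 1, ventilation-on at ACH 11. Each preset's source rate
is calibrated by inverting the rise phase (`source_rate_for_eec()`) so the
noiseless trace evaluates exactly to the scenario's published mean value —
454 ppm for the gravity baseline, scaled by each scenario's reduction
factor (e.g. 6/454 for the vented partial enclosure) — making the full
published analysis rehearsable end-to-end on synthetic data. The
full-enclosure scenario has a zero source and exercises the NoE path. The
drained-container baseline is modelled as a 5-min evaporation burst after
lid removal followed by pure ventilation decay (its published values are
decay-fit extrapolations); the flushed container uses a 10-min lid-open
window with the mean-concentration estimator — the lid-open duration is not
recorded in the study design and 10 min is this package's one-time
realistic choice. Simulated pre-event backgrounds run at 0.5 ppm with a
240-s settling window.

### What the generator does **not** emulate

Replicate-to-replicate variability in the real experiments (equipment
repositioning, pouring style, pocket formation) dominated their reported
CVs of 7.7–30%. The generator has no between-run source-strength
variability — its noise is per-sample, and a ~100-point regression averages
per-sample noise down to ~1–3% replicate CVs regardless of its magnitude.
Passing recovery tests therefore demonstrates that the estimator is
unbiased and precise under the stated noise, not that it has been exercised
at field-realistic replicate dispersion; the table-based statistics cover
the realistic-dispersion regime instead. Also outside the generator's
scope: two-zone room structure, aerosol formation under high-pressure
pumping, evaporation thermodynamics, and instrument drift.

## Validation problem sizes

The test-suite and acceptance checks run at sizes chosen to exercise every
code path while staying quick: noiseless recovery over an amplitude ×
ventilation grid (1–500 ppm × ACH 1–12, exact to 0.1% in amplitude and
10⁻⁶ h⁻¹ in rate), 100 seeded noisy replicates of the baseline (median
extrapolation error ~1%, bound 5%), a 0.05-s-step Runge–Kutta oracle
agreeing with the closed form to 0.01%, 1000 randomised replicate sets for
the ordering property, and a full nine-scenario, three-replicate pipeline
run (27 traces).

## Known limitations

* The window-enumeration rule (offsets 0–10, minimum 5 points, floor,
  $R^2 \ge 0.9$) is a documented reproducible choice; the original
  evaluation specified only that $k$ match the air-exchange rate, not which
  points formed the trendline.
* The absolute 0.1 ppm term of the positivity floor breaks exact scale
  equivariance for traces whose peak excess is below 10 ppm (the 1%-of-peak
  term dominates above that).
* The ±1 h⁻¹ tolerance is generous at ACH 1 (a 100% relative band); the
  $R^2$ floor, not the tolerance, is what rejects wrong-rate fits there.
* An optional nonlinear least-squares refinement
  (`refine_decay_fit()`) is provided for sensitivity analysis; log-linear
  OLS defines all reference numbers here.
* The upper reported CV bound (30%) cannot be reproduced from any published
  replicate set and is not targeted.
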