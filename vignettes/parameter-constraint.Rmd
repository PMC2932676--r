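---
title: "Constraining ionic conductances from populations of model myocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraining ionic conductances from populations of model myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosens)
```

## The problem

Ventricular myocyte models contain tens of free parameters — maximal ionic
conductances and ion-transport rates — that cannot all be measured in the
cell the model is meant to describe. Matching a single observable such as
action potential duration (APD) does not pin them down: drastically
different conductance combinations produce nearly identical action
potentials. The working hypothesis of this package is that parameters
*can* be constrained when the number of independent physiological outputs
considered simultaneously approaches the number of free parameters.

Two complementary machines implement that idea:

1. **Reverse regression / matrix inversion.** Randomize the parameters of a
   cell model around its published baseline, simulate a battery of standard
   electrophysiological protocols for every variant, and collect the
   results in an input matrix $X$ ($n$ trials $\times$ $p$ log scale
   factors) and an output matrix $Y$ ($n \times m$ physiological outputs).
   After Z-scoring each column, multivariable regression gives the forward
   sensitivity matrix $B$ ($p \times m$) with $\hat Y = XB \approx Y$. If
   $m = p$ and the retained outputs are linearly independent, $B$ is
   invertible and $X_\text{pred} = Y B^{-1}$ *predicts the parameters from
   the outputs*. When $m > p$, a directly fitted reverse matrix $B'$
   ($Y B' \approx X$) does the same job.
2. **Sequential Bayesian conditioning.** Estimate
   $P(\text{parameter} \in A \mid \text{outputs} \in B_1 \cap B_2 \cap
   \dots)$ empirically by intersecting the population with windows on one
   output after another and watching the per-parameter histograms narrow.

## Cell models

Three models are built in, behind one registry interface
(`model_spec()`, `baseline_parameters()`, `evaluate_derivatives()`):

* `tnnp` — the ten Tusscher–Noble–Noble–Panfilov (2004) human ventricular
  model, epicardial variant: 17 state variables and the full 16-parameter
  roster (G_Na, G_CaL, G_to, G_Kr, G_Ks, G_K1, G_pK, G_bNa, G_bCa, K_pCa,
  K_NaK, K_NCX, K_up, K_leak, K_rel1, K_rel2). The epicardial subtype is
  used because the output battery includes the spike-and-dome shape
  parameters, which presuppose a phase-1 notch.
* `lr1` — the Luo–Rudy (1991) phase-1 guinea-pig model: 8 states, 6
  conductances (G_Na, G_si, G_K, G_K1, G_Kp, G_b).
* `bernus` — a six-variable reduced human ventricular model in the style of
  Bernus et al. (2002): INa with a combined slow inactivation gate,
  instantaneous ICa activation, a transient outward current producing the
  epicardial notch, one delayed rectifier, an inward rectifier, NaK/NaCa
  pumps and a background Na conductance (8 scalable parameters, fixed
  intracellular concentrations). The published reduced model could not be
  reproduced equation-by-equation from available sources, so this is a
  re-implementation in its spirit, tuned to a human-like epicardial action
  potential (APD$_{90}$ ≈ 290 ms, V$_\text{rest}$ ≈ −86 mV); it plays the
  role of a structurally different second human model, not of a verbatim
  reproduction.

### Numerics

Gates are advanced by the Rush–Larsen exponential update
$x \leftarrow x_\infty + (x - x_\infty)e^{-\Delta t/\tau_x}$, which is
exact for frozen voltage and unconditionally stable; this matters because
the fast Na$^+$ activation gate of the `tnnp` model has
$\tau_m < 1\,\mu s$ at rest, which would force a general-purpose adaptive
solver to microsecond steps for the entire diastole. Voltage and ion
concentrations are advanced explicitly with a step chosen so the voltage
change per step stays near `dv_step` (default 0.2 mV) and the relative
Ca$^{2+}$ change per step near `cai_step` (default 2%), clamped to
[`dt_min`, `dt_max`] = [0.005, 0.25] ms (`solver_accuracy()`). The test
suite verifies that halving all four targets changes the steady-state
baseline APD by less than 0.1 ms, the accuracy the protocol battery needs.
The stimulus is a rectangular depolarizing 1-ms pulse; integration restarts
at stimulus edges so the discontinuity never crosses a step.

APD is measured from the instant of fastest upstroke to 90% repolarization
toward the pre-stimulus diastolic voltage (the level is configurable).
Beat-level summaries (APD, peak voltage, maximal upstroke velocity, Ca
transient amplitude) are extracted inside the integration loop from the
accepted steps, so threshold searches and alternans scans do not pay for
trace recording.

One known quirk is preserved deliberately: the published steady-state curve
of the `tnnp` Ca-dependent inactivation gate fCa slightly exceeds 1 at
diastolic Ca$^{2+}$, so fCa may sit a few percent above 1 at rest. All
other gates remain in [0, 1] to integration accuracy.

## The protocol battery

Each trial's output vector is produced by `compute_trial_outputs()` from a
battery of protocols (`suite_config()` holds every knob):

| stage | default | outputs fed |
|---|---|---|
| stimulation-threshold bisection (tolerance 0.1 pA/pF) | bracket 2–80 pA/pF | I_thresh |
| pacing from quiescence, BCL 1000 ms | 100 beats | APD, V_rest, V_peak, dV/dt_max, shape params, ΔCa, Ca kinetics, APD_diff, ΔCa_diff |
| 5-s pause, then one beat | 5000 ms | pause APD/ΔCa/shape |
| hypokalemia (K$^+_o$ = 3 mM) and hyperkalemia (8 mM) pacing | 20 beats each | APD and shape at altered K$^+_o$ |
| 60-s quiescence | 60 000 ms | Ca$^{2+}$, Na$^+$, K$^+$ after rest |
| slow/fast pacing pair | BCL 2000/500 ms, 30 beats | frequency adaptation (APD ratio) |
| alternans scan, descending 5-ms grid | 350→150 ms | BCL_alt (sentinel `scan_min − step` when absent) |
| S1S2 restitution | 10 S1, 10 DIs | maximum restitution slope |

Alternans is called when the final four beats at a cycle length alternate
long–short with every beat-to-beat APD difference above 1 ms; the grid and
criterion resolve the conventional 285 ms/280 ms distinction. Each
protocol's measured beat runs in an extended observation window (cycle
length + 1000 ms) so that action potentials outlasting the cycle length
still yield an APD rather than a missing value.

Two design choices deserve justification:

* **Stimulus sizing.** By default every feature protocol uses a strong
  *fixed* stimulus (52 pA/pF for 1 ms, the convention of the human model's
  source implementation) rather than a multiple of the trial's own
  threshold. A threshold-coupled stimulus looks attractive but fails its
  own purpose: the threshold is measured at normal K$^+_o$, and at
  hypokalemia the cell rests ~15 mV hyperpolarized, so variants with a low
  normal-K threshold (high G_Na) receive a pulse too weak to capture —
  roughly a third of randomized human-model trials lost capture this way.
  A fixed strong pulse captures them all; the threshold remains an output.
  The relative mode is available (`stim_mode = "relative"`).
* **Randomization spread.** Scale factors are i.i.d. lognormal with median
  1; the default standard deviation of the log factor is
  $\sigma = \log 1.2 \approx 0.1823$, the spread used in the
  regression-based sensitivity-analysis literature this method extends.
  Larger spreads (e.g. $\sigma = 0.3$) push many variants into frank
  nonlinearity (repolarization failure under hypokalemia, alternans onset),
  which an affine model cannot and should not absorb; the local-linearity
  assumption is part of the method's stated scope.

**Missing values.** A protocol that fails for one variant (loss of
excitability, integrator failure at an extreme parameter corner) masks only
its own outputs; masked entries are mean-imputed in Z-space (value 0) before
regression so that $n$ stays fixed and a masked output contributes no
signal. Trials failing more than half their outputs count as outright
failures; a failure rate above 20% aborts the population build as an
unstable configuration.

## Regression stage

`fit_population_regression()` Z-scores both matrices (storing the moments),
imputes masked entries, and fits. With `n_components = p` (the default) the
partial-least-squares solution coincides with ordinary least squares on
standardized data, and is computed directly by SVD least squares — the SVD
route also gives the minimum-norm solution under exact collinearity, which
greedy elimination encounters when outputs are duplicated. Reduced
component counts use NIPALS PLS2 (cross-checked in the tests against an
independent implementation). Per-column $R^2$ is $1 - \mathrm{SSE} /
\mathrm{SST}$ about the true column mean.

`eliminate_outputs()` removes outputs greedily: at each step the output
whose removal leaves the highest mean per-parameter reverse $R^2$ goes
(ties to the lowest index; a per-parameter-minimum criterion is available),
until $m = p$. `invert_square_regression()` then inverts the retained
square block of $B$, refusing when the reciprocal condition number falls
below $10^{-10}$ — a silent pseudo-inverse would hide exactly the linear
dependence the elimination is supposed to remove.
`predict_parameters()` maps new outputs through the stored standardizers
and back out of log space, so its result is a multiplicative factor per
parameter.

`reconstruct_condition()` packages the workflow used for disease-state
reconstruction: randomize only the $k$ parameters of interest, evaluate a
paced battery under normal, low (3 mM) and high (8 mM) extracellular
potassium (11 outputs × 3 conditions = 33 outputs), fit the reverse
regression, and predict the fold-changes of a "condition" cell from its
outputs alone. Fold-changes far outside the training spread extrapolate
poorly — reproduced deliberately in the tests, since it is a real
limitation of a local linear model.

## Bayesian stage

`sequential_constraint_analysis()` centers every window on the *best*
trial — the row whose outputs the forward regression predicts with minimal
residual — so the constrained region is guaranteed to be populated.
Percentile windows keep a fixed fraction of samples (default 10%) ranked
around the center value; relative windows keep ±5% of the value.
Histograms use 20 bins with edges fixed on each parameter's marginal, so
narrowing is comparable across conditioning stages; each histogram is
normalized to its subset. The object records the nested surviving subsets,
per-stage histograms, and per-stage standard deviations. "The conditional
probability reaches unity" corresponds to all surviving trials falling into
one parameter bin; this is reported, not asserted, because it depends on
$n$ and the window widths.

## What the tests show — and what they cannot

The statistical stages are tested against exact oracles on a synthetic
linear fixture (standard-normal inputs, a coefficient matrix with
controlled condition number, Gaussian noise): coefficient recovery, inverse
identities, greedy-vs-exhaustive elimination, closed-form truncated-normal
conditional variances. These tests validate the machinery, not the
biology: the fixture is exactly linear, whereas real (and simulated)
myocytes are only locally linear in log-conductances. The
population-level checks on the three cell models are therefore the
substantive ones, and they are stochastic: run at a stated seed and stated
sizes, with thresholds that mirror the published experiment
(most outputs predictable with forward $R^2 > 0.9$; 12 of 16 human-model
parameters recoverable with reverse $R^2 > 0.7$; background conductances
poorly identifiable; a 16-output retained set performing nearly as well as
all 32).

Problem sizes used by the automated checks: populations of 300 variants for
the human and guinea-pig models and 200 for the reduced model, with
pre-pacing shortened to 40–50 beats (convergence-checked: beat-to-beat APD
change < 0.1% well before that), 12–15 beats after potassium switches, 20
beats per rate for frequency adaptation, and a 30-s quiescence for the
guinea-pig model. These sizes are the package's reference configuration
for a desk-scale reproduction; all are single knobs in `suite_config()`.

Known limitations:

* Simulated populations vary only maximal conductances/transport rates;
  kinetic parameters, cell-to-cell coupling, beat-to-beat stochasticity of
  channel gating, and measurement noise in real experiments are all outside
  the generator, so the reported $R^2$ values are upper bounds on what the
  same battery would achieve on wet-lab data.
* The reverse map is local: fold-changes outside the training spread are
  systematically over- or under-estimated.
* The Bernus-type model is a faithful-in-spirit re-implementation, not the
  published equation set; conclusions about *that specific* model should
  not be read off it.
* Drug-block and voltage-clamp outputs are deliberately absent from the
  batteries.
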