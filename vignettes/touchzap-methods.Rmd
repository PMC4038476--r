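---
title: "Models and methods behind touchzap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind touchzap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchzap)
```

touchzap analyzes in-vivo whole-cell current-clamp recordings obtained with
the Touch-and-Zap access technique, and simulates complete recording
sessions from an electrode + cell equivalent circuit so that every analysis
stage can be validated against known ground truth. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the simulation-based tests do and do not establish about
real recordings.

## The equivalent circuit

The recording chain is modeled as two RC stages in series under current
clamp:

* an **electrode** stage with resistance $R_e$ (4–8 MΩ pipettes; defaults
  6.0 MΩ for neuron recordings, 6.4 MΩ for glia) and a fast time constant
  $\tau_e$ (default 0.15 ms). Amplifier bridge and capacitance compensation
  remove most of the electrode's resistive drop; what the analyst sees in
  the recorded voltage is the **residual bridge error** $R_b$, so the
  simulator renders the electrode term as
  $I\,R_b\,(1 - e^{-t/\tau_e})$. $\tau_e$ is only bounded in practice (a
  few hundred microseconds); we model the whole fast artifact as a single
  exponential and fold any pipette-capacitance dynamics into it.
* a **passive membrane** with input resistance $R_{in}$ and time constant
  $\tau_m$, reached through the access resistance $R_a$ after whole-cell
  entry.

For a current step $I$ starting at onset the noiseless voltage is

$$V(t) = E_{rest} + I R_b (1-e^{-t/\tau_e}) + I R_{in} (1-e^{-t/\tau_m}),$$

which `simulate_step_response()` evaluates in closed form (a unit test
cross-checks it against an independent ODE integration). Gaussian noise of
configurable RMS is added afterwards. The 10 kHz acquisition low-pass is
modeled as a 4th-order Bessel filter (`apply_acquisition_filter()`); it is
an explicit step rather than an always-on default so that unfiltered traces
keep their closed-form shape and the analytic unit tests remain exact.

Spiking neurons use a leaky integrate-and-fire overlay with a stereotyped
2 ms waveform (linear rise at a configurable maximal slope to a configurable
peak, then a linear fall to a reset). This is deliberately not a
conductance-based model: it exists to exercise spike detection,
classification and spike metrics, for which only the amplitude, peak and
upstroke slope matter.

## Session simulation

`simulate_session()` renders the approach-and-access timeline sampled by
the impedance-monitoring pulse train (10 Hz, 50% duty, 0 to −1.11 nA). The
phases are:

1. **bath** — total resistance $R_e$;
2. **touch** — a step of a few hundred kΩ (default 0.5 MΩ, i.e. ~8% of
   $R_e$) on membrane contact;
3. **sealing** — after pressure release the seal resistance grows
   exponentially toward a 2 GΩ ceiling with time constant `seal_tau`.
   Spontaneous seal formation is only characterized as taking seconds;
   the exponential-approach form and the default `seal_tau` (median 16 s,
   log-normal spread across cohorts) were chosen once so that the typical
   delay from release to electroporation lands near the reported ~2.5 s
   zap delays, and are not revisited;
4. **zap** — the instant the on-pulse voltage reaches the breakdown
   voltage $V_{bd}$ the membrane electroporates: the crossing sample keeps
   the peak hyperpolarization (this is the recorded zap voltage) and the
   resistance collapses to $R_e + R_a$ from the next sample, with the DC
   level charging toward $E_{rest}$ with $\tau_m$. Optionally a second,
   smaller zap follows after a partial-access plateau placed 100–150 mV
   less hyperpolarized than the first;
5. **reseal / suction** (TZS) and **slow-seal / suction** (TS) phases, with
   decade reductions of the pulse amplitude whenever deflections would
   exceed ~150 mV, as is done at the rig.

Electrode charging faster than two samples is folded into an effective
one-pole response with $\tau = \max(\tau_e, 2\,\Delta t)$; session logs
default to 2 kHz sampling (step-response sweeps default to 40 kHz). Times
are seconds, voltages mV, currents nA, resistances MΩ; sample intervals are
half-open $[t, t+\Delta t)$.

### Cohort generator

`simulate_cohort()` draws per-cell parameters from the recorded-population
summaries: $R_e$ 6.0 ± 0.73 / 6.4 ± 0.58 MΩ, $R_{in}$ 56 ± 31 / 90 ± 62 MΩ,
$\tau_m$ 9.8 ± 5.2 ms / 1.5 ms truncated below 5 ms, $E_{rest}$ −76 ± 7.5 /
−76 ± 13 mV, $R_a$ 35 ± 18 / 53 ± 26 MΩ, $V_{zap}$ −330 ± 53 / −350 ± 64 mV
(neurons / glia), endpoint mixes 48/40/12% and 61/24/15% for TZ/TZS/TS.
Distributions are truncated to physiological ranges, and for zap endpoints
the triple $(R_{in}, R_a, V_{bd})$ is drawn jointly so that the whole-cell
resistance after the zap is at most ~70% of the seal resistance at
breakdown: an electroporation whose "after" resistance nearly equals its
"before" resistance produces no abrupt drop and would not be read as a zap
by an experimenter either. TS cells draw a several-fold slower seal (they
are, by definition, the slow sealers whose zap attempt is abandoned).

## Passive-parameter extraction

`fit_step_response()` implements the off-line heuristic that mirrors
on-line visual bridge balancing:

1. $V_{rest}$: mean of pre-stimulus baselines, excluding windows with
   spontaneous spikes (the baseline length and the spike-rejection
   thresholds — samples 20 mV above the baseline median with slope over
   10 mV/ms — are package choices; no published values exist for them).
2. $V_{ss}$: mean over exactly $[+100, +200)$ ms after onset.
3. $V_O$: cubic polynomial over the 2 ms before onset, evaluated at onset.
4. $\tau_0$: two-pass linear regression of $\ln V'$ (with
   $V' = \pm(V_{ss} - V)$ by polarity). The first pass runs from 0.5 ms
   after onset — after most of the electrode artifact has decayed — until
   $V'$ first reaches $0.3\,|V_{ss}-V_{rest}|$; the second pass starts at
   onset $+\,0.2\,\hat\tau_0^{(1)}$ with the same stop rule.
5. $R_a$ error: the second-pass fit extrapolated to onset, minus $V_O$,
   divided by $I$. $R_{in} = ((V_{ss} - I\,\hat R_a^{err}) - V_{rest})/I$.
   (Subtracting $I\,\hat R_a^{err}$ from $V_{ss}$ or from the whole trace is
   equivalent for this steady-state formula; the steady-state adjustment is
   implemented.)
6. Per-trace results are averaged, unweighted, into cell values;
   `ra_trend()` regresses repeated $R_a$ estimates on time (OLS; the
   reported mean equals the arithmetic mean, as it must for OLS).

Numerical choices worth knowing:

* Minimum points: 10 for the log-linear fit, 8 for the cubic.
* Non-positive $V'$ samples are excluded; if more than 20% of a window is
  excluded the fit aborts.
* The stop-criterion crossing is evaluated on a 5-sample running mean of
  $V'$. With raw first-crossing semantics, mV-level noise truncates the
  regression window at an essentially random early point and inflates the
  variance of the onset extrapolation considerably; the short smoothing
  restores a deterministic window while moving the stop by less than a
  sample or two at 40 kHz, where sub-sample precision is immaterial.
* Acceptance screen: steady-state deflection within 15 mV of rest. The
  operative rule is "about ±10 mV" of membrane deflection; the screen is
  applied to the raw deflection, which still contains the bridge-error
  component ($I R_b$ can be 2 mV or more), so the default leaves headroom
  for it. Spikes during the step (slope > 10 mV/ms and 20 mV above the
  charging envelope) and sag (a smoothed overshoot beyond $V_{ss}$ of more
  than 2 mV after $3\hat\tau_0^{(1)}$) reject the trace with a named
  reason. The thresholds are package choices; the exclusions themselves
  are standard.
* Fast membranes (glia; $\tau_m$ under ~0.6 ms at the default thresholds)
  cross the stop threshold before the 0.5 ms window start. The fit then
  falls back to the first 10 samples from the window start and flags
  `fast_membrane`; such estimates are biased by the electrode artifact
  (the tests quantify the bias against a nonlinear two-exponential
  least-squares fit), which is why glial time constants deserve less
  confidence than neuronal ones.
* The single-exponential membrane model is a simplification made for
  tractability; higher-order fits are out of scope.

On noiseless two-exponential traces with $\tau_e \le 0.3$ ms and
$\tau_m \ge 5$ ms the heuristic recovers $\tau_0$ within 5%, $R_{in}$
within 2% and the bridge error within 10% (tested over 100 random
circuits), and agrees with the nonlinear two-exponential oracle within 10%
whenever $\tau_m/\tau_e \ge 20$.

## Event detection and endpoint classification

`pulse_resistance_series()` measures, per monitoring pulse, the
baseline-to-plateau deflection divided by the amplitude taken from the
command-current channel (so current step-downs are handled transparently);
the plateau is the last 25% of the on-phase. With a 10 Hz, 50% duty train
and $\tau_m \approx 10$ ms the membrane has not fully charged by the
plateau window, so whole-cell resistance reads ~1–3% below
$R_e + R_a + R_{in}$; tests carry that tolerance explicitly.

Detection thresholds live in `detection_config()`, not in code, because the
underlying phenomena are described qualitatively ("abrupt", "small
deflection", "on the order of 20%"):

* **touch**: first pulse exceeding a 10-pulse rolling median baseline by
  ≥5%, sustained 3 pulses.
* **unstable**: peak-to-peak fluctuation ≥20% of the median over the
  pre-candidate span aborts the attempt (the cardiac/movement-artifact
  rule). Per-pulse resistance noise scales as $1/\sqrt{\text{samples per
  plateau}}$, so at low rendering rates with mV-level noise this rule can
  false-trigger; noisy-session tests therefore render near the acquisition
  regime.
* **zap**: a between-pulse resistance drop of ≥25% (relative to the larger
  of the two preceding pulses) while the window reaches at least −150 mV.
  A 40% drop rule sounds natural but would miss typical first zaps of
  two-zap accesses: a second zap 100–150 mV less hyperpolarized than a
  first zap near −330 mV implies a first-event drop of only 30–45%.
  Candidates across a pulse-amplitude change are skipped (the discharge
  transient corrupts the baseline window), and candidates within 1 s of a
  previous zap are the same event. The zap voltage is the most
  hyperpolarized sample over the drop pulse and its predecessor. Up to two
  zaps are reported.
* **reseal**: post-zap resistance growth to ≥3× the post-zap level,
  sustained 1 s.
* **suction breaks** are experimenter actions: they are taken from
  annotations and accepted only when a corroborating resistance drop
  (below 0.6× the previous pulse) occurs within 0.5 s.

`classify_endpoint()` then maps the event sequence to TZ (zaps only), TZS
(zap → reseal → suction), TS (no zap; touch then suction), or FAIL with a
named reason; the zap delay $T_{zap}$ is measured from the
pressure-release annotation to the first zap.

## Classification and quality rules

A cell is a **neuron** if any current-evoked action potential reaches 50 mV
from rest, a **glial cell** if it never spikes and $\tau_0 < 5$ ms, and
**unclassified** otherwise ("no obvious fast voltage-dependent properties"
is qualitative; only these two criteria are enforced). Spike detection is a
threshold crossing at $V_{rest} + 20$ mV with a 1 ms refractory; each
spike's metrics ($dV/dt_{max}$, absolute peak) are measured from the
crossing until the voltage falls back below threshold. Firing-pattern
labels (regular-spiking, fast-spiking, bursting, chattering) follow an
external taxonomy and are stored as supplied text, never computed. The
electrode-angle depth correction is available as `corrected_depth()` and is
never applied silently.

Quality flags: initial $R_a > 50$ MΩ (`high_Ra`), any $R_a$ above 1.5× its
initial value (`Ra_drift`), resting potential straying more than 20 mV
(`Vrest_drift`), input resistance above 500 GΩ (`excluded_Rin`), and
`movement` from upstream artifact detection. Flags are monotone in
appended data.

## Cohort statistics

`l_rel()` computes the relative linear cell size
$\sqrt{1/R_{in}}$ normalized to the cell-type mean (so each type's mean is
exactly 1); `endpoint_proportions()` uses touch-step denominators
(TZ + TZS + TS); `two_proportion_z()` is the pooled-proportion z test;
`two_sample_t()` wraps the standard Student/Welch tests;
`correlations()` reports squared Pearson and Spearman coefficients with a
one-sided Fisher-z p value. Multivariate group comparisons are replaced by
per-variable pairwise tests throughout; percentages are rounded only at
presentation. Published count tables can be cross-checked against stated
percentages with `validate_cohort_counts()`, which warns on
inconsistencies instead of reconciling them silently.

## Problem sizes used in the test suite

The property suites run 100 random circuits for passive-parameter
recovery, 25 circuits against the nonlinear oracle, 200 noiseless
simulated sessions for the endpoint confusion matrix, and 91 TZ/TZS neuron
sessions for zap-voltage recovery; session logs render at 2 kHz and
step-response sweeps at 40 kHz. These sizes were chosen to exercise the
full parameter ranges while keeping a complete run in minutes.

## What the simulations do and do not show

The generator reproduces two-exponential step responses, seal-formation
envelopes, abrupt electroporation, resealing, suction breaks, stereotyped
spiking and stationary Gaussian noise. It does not emulate synaptic
background, conductance nonlinearity (sag, rectification), slow drift of
electrode properties, non-stationary cardiac/movement artifacts (only a
stationary sinusoidal resistance modulation), or visual-stimulus-driven
activity. Passing tests therefore establish that the analysis recovers the
parameters of the stated circuit model under the stated noise — not that
the heuristic is unbiased on arbitrary real traces. The known biases (fast
membranes, plateau truncation) are flagged in the outputs rather than
hidden.
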