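---
title: "Plateau dynamics with ultrafast potassium inactivation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plateau dynamics with ultrafast potassium inactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`exp2plateau` simulates the pharyngeal corpus muscle of *C. elegans* as a
single isopotential compartment in the Hodgkin–Huxley formalism. The muscle
fires plateau potentials: long depolarizations near +40 mV that drive a pump,
initiated by an EPSP from the excitatory MC motor neuron and terminated by an
IPSP from the inhibitory M3 motor neuron. The scientific focus is the
potassium current modelled on the EXP-2 channel, which *inactivates* and
*deinactivates* with ultrafast kinetics. Because the channel inactivates
nearly instantly on depolarization, it passes almost no current during the
plateau — it sits in a primed state with its activation gate `w` saturated and
its inactivation gate `h` at zero — and a brief hyperpolarization is enough to
deinactivate it and fire the repolarizing current. The voltage at which half
the channels are inactivated, `Vhalf_inact` (V~1/2~), therefore sets how deep
an inhibitory excursion must be to terminate the plateau, and is the model's
key robustness parameter.

The membrane equation is

$$C\frac{dV}{dt} = -g_L (V - V_L) - g_{CaT} m_T^2 h_T (V - V_{Ca})
  - g_K\, w\, h\, (V - V_K) - g_{CaL} m_L^2 h_L (V - V_{Ca})
  - g_E (V - V_{synE}) - g_I (V - V_{synI}).$$

The T-type (CCA-1-like) current is the fast trigger: its activation midpoint
(−45 mV) is reachable by a single EPSP, and it inactivates almost immediately
once depolarized. The L-type (EGL-19-like) current sustains the plateau; its
inactivation `hL` is slow (τ between 200 and 300 ms) and shallow (midpoint
135 mV, slope 55 mV), producing a mild relaxation of the plateau level rather
than termination. K-current activation follows
$w_\infty(V) = 0.5\,(1+\tanh((V-12)/17.4))$ with
$\tau_w(V) = 1/\cosh((V-12)/34.8)$ and the printed rate multiplier 0.04 on
$dw/dt$, giving an effective activation timescale of roughly 20 ms at plateau
voltages. K-current inactivation is
$h_\infty(V) = 0.5\,(1-\tanh((V - V_{1/2})/3))$. In the **ultrafast variant**
`h` is evaluated as $h_\infty(V)$ pointwise and carries no state; in the
**finite-τ~h~ variant** it relaxes as $dh/dt = (h_\infty(V) - h)/\tau_h$ with
a voltage-independent τ~h~ (1–20 ms in the studies here). Synaptic
conductances decay exponentially ($\tau_E = 1$ ms, $\tau_I = 2$ ms) and are
*assigned* their maximal values (3.0 and 2.5 nS) at spike times.

All quantities use mV, ms, nS, pF and pA, so $dV/dt = I/C$ holds without
conversion factors.

## Membrane capacitance

The capacitance only scales the voltage timescale — the regime structure of
the model depends on conductance ratios — so it is calibrated, not fitted:
the requirement is that the reference feeding protocol (below) yields
~250 ms commanded plateaus at a sustained level near +40 mV for every
inactivation midpoint in 10–20 mV. At `C = 2` pF (the default), a single
3 nS/1 ms EPSP reliably triggers the T-type upstroke and a single 2.5 nS/2 ms
IPSP drives the membrane deep enough (to about +10–15 mV) to deinactivate the
K current for all three midpoints. Larger values fail this calibration in
simulation: at 10 pF the EPSP integral (≈20 mV) cannot reach the T-type
threshold from rest, and at 5 pF the IPSP excursion is too sluggish to cross
the deinactivation latch of the V~1/2~ = 10 mV model, which then never
repolarizes. `C` remains a user-visible parameter.

## The stimulus and noise generator

All model input is generated internally; there is no external data.

* **Feeding schedule** (`feeding_schedule()`): EPSPs every
  `plateau_ms + isi_ms` starting at `t_first` (default 100 ms, a warm-up that
  lets initialization transients decay), each followed by an IPSP
  `plateau_ms` later. The reference protocol uses 250 ms plateaus and a
  250 ms inter-stimulus interval, matching active pumping rates.
* **Inhibitory shot noise** (`sample_noise_train()`): for every bin of width
  `bin_ms` a count $k \sim \mathrm{Poisson}(\lambda)$ of noise channel
  openings is drawn; bins with $k>0$ contribute one event of magnitude
  $k \times 0.15$ nS *added* to the inhibitory conductance (spikes assign,
  noise superposes). λ = 0.01 and 0.05 are the low- and high-intensity
  references. The bin width is not dictated by the science; the default of
  1 ms makes λ a per-millisecond rate, giving mean event gaps of 100 ms
  (λ = 0.01) and 20 ms (λ = 0.05) — a few small perturbations per plateau.
  Noise is inhibitory only: the excitatory input reverses at 0 mV, so even
  "excitatory" channel noise is hyperpolarizing at plateau voltages, and the
  inhibitory polarity is the one relevant to plateau termination.

The generator emulates stationary, uncorrelated quantal release. It does not
emulate presynaptic dynamics (depression, facilitation, graded release
gain), correlated noise across synapses, or excitatory noise — conclusions
from passing tests are about the idealized shot-noise model, not about the
full biological synapse.

## Integration

The system is stiff: at depolarized voltages the T-type inactivation and
L-type activation time constants fall below 10 µs while `hL` relaxes over
hundreds of ms. Integration uses LSODA (via **deSolve**) with a compiled
right-hand side, relative tolerance 1e-6 and absolute tolerance 1e-9
(configurable; the test suite verifies that halving the tolerances moves V by
less than 0.1 mV). Synaptic events are discontinuities at known times: the
solver is stopped and reinitialized at every event rather than stepping
across it, which is exact for conductance jumps. Equal-time events are
combined in the deterministic tie order EPSP < IPSP < NOISE (assignments
first, then additive quanta). Output is sampled on a uniform grid,
`dt_out = 0.5` ms by default, which bounds the quantization of
plateau-duration measurements below half a millisecond (crossing times are
interpolated). Long runs can be integrated in chunks (`chunk_ms`) with
results identical to a single call within solver accuracy.

## Plateau metrics

* **Detection**: maximal intervals with V ≥ −30 mV (midway between rest and
  plateau) lasting ≥ 5 ms; edges by linear interpolation; segments reaching
  the trace end are open-ended and excluded from duration statistics.
* **Regimes**: `unending` (an open-ended segment spanning ≥ 2 stimulus
  periods), `two_level` (a closed segment dwelling ≥ 50 ms in each of two
  voltage bands ≥ 20 mV apart, found as modes of a 2 mV dwell histogram),
  `physiological` (most segments end within 25 ms of a scheduled IPSP, with
  peaks ≥ 20 mV), `low_amplitude` (activity above rest that never qualifies),
  `quiescent`. All thresholds are configurable (`regime_thresholds()`).
* **Wedge depth**: slow K inactivation produces a transient "wedge"
  hyperpolarization after the initial peak, from the overlap of `w` rising
  and `h` still high. It is measured as initial peak minus the first local
  minimum that is followed by ≥ 1 mV of recovery; when inactivation is so
  slow that the wedge drops the cell onto a sustained lower level with no
  recovery, a fast flat drop of ≥ 20 mV counts instead. The slow L-type
  relaxation (a few mV, no recovery) is thereby excluded. On noiseless
  reference runs the measured depths are 0 (ultrafast and τ~h~ = 1 ms),
  ≈ 4 mV (5 ms), ≈ 10 mV (10 ms) and ≈ 30 mV (20 ms, the two-level drop).

## The computational studies

`run_conductance_sweep()` maps the $\bar g_K \times \bar g_{CaL}$ plane
(0–10 × 0–7.5 nS) under the noiseless protocol. At $\bar g_K = 9$ nS the
regime traverses `low_amplitude` → `physiological` → `unending` as
$\bar g_{CaL}$ grows, and $\bar g_K = 0$ (the K-channel loss-of-function
analog) is `unending`. For the τ~h~ = 20 ms variant, cells around
$\bar g_K \approx 4$–5, $\bar g_{CaL} \approx 3$ nS produce genuine two-level
plateaus (upper band ≈ 29–30 mV, lower band ≈ 4–6 mV, durations of 750 ms and
beyond).

`run_noise_robustness()` and `run_timescale_robustness()` run the reference
protocol under noise for each V~1/2~ (ultrafast) or τ~h~ (finite variant,
V~1/2~ = 15 mV), pooling closed plateau durations over seeds and comparing
each noisy condition against its noiseless reference with a two-tailed
Mann–Whitney U test. The z score uses midranks and the tie-corrected
variance — the noiseless reference durations are nearly all identical, so the
tie correction is load-bearing; the tests verify it equals the exact
permutation variance. No continuity correction is applied, so results are
deterministic. The effect size is $|z|/\sqrt{N}$ with $N$ the combined size
of both samples (the convention is exposed should a user prefer counting only
one sample). `run_timescale_interaction()` sweeps τ~h~ (0.5–10 ms) against
the inhibitory synaptic time constant (1–5 ms), which sets the duration of
individual noise events, at a fixed λ (default 0.05 — the intensity for this
study is configurable and documented in the output manifest).

A single base seed expands to per-condition seeds as
`(seed mod 1e6) * 2000 + index`, so adding conditions never reshuffles
existing ones and derived seeds stay below 2^31.

**Problem sizes.** The full studies run 1,000 s of model time per condition;
the test suite and the acceptance script use 100–200 s per condition with
3 noise seeds (several hundred plateaus per condition) and a 10 × 14 coarse
sweep grid, which keeps the whole suite within a few minutes on one CPU while
leaving duration statistics with standard errors well below the effects of
interest.

## Noise sensitivity at the default parameter scale

A lone inhibitory conductance increment injected mid-plateau must reach
(`termination_threshold()`, noiseless protocol, defaults) about **0.9 nS for
V~1/2~ = 20 mV, 1.4 nS for 15 mV and 2.0 nS for 10 mV** before the
deinactivation latch trips — the mechanistic ordering that makes
depolarized midpoints fragile, and comfortably below the 2.5 nS commanded
IPSP. A single noise quantum is 0.15 nS and perturbs the plateau by only
~1–3 mV (the plateau's restoring conductance is ≈ 5 nS), so at the default
quantum the Poisson trains at λ ≤ 0.05 essentially never truncate a plateau:
noisy and noiseless duration samples coincide (mean ≈ 249.4 ms) for every
V~1/2~ and τ~h~. Entering the collapse regime requires event amplitudes of
roughly 6–13 quanta (1–2 nS) arriving as single excursions. Users can reach
it by raising `noise_quantum`, or equivalently by scaling all conductances
and `C` down together (the deterministic dynamics are exactly invariant under
$(g, C) \to (\alpha g, \alpha C)$; only the quantum's *relative* size
changes). For example, α = 0.1 with the quantum held at 0.15 nS yields
pooled mean durations near 90 ms (λ = 0.01) and 28 ms (λ = 0.05) at
V~1/2~ = 20 mV while the V~1/2~ = 10 mV model stays near 240 ms at low
noise. The package's defaults keep the printed conductance scale; the
acceptance suite reports what that scale actually produces.

## Numerical and design notes

* The resting state is found by root finding on the steady-state ionic
  current over [−80, 0] mV (most hyperpolarized root) and verified stable by
  relaxation; all simulations start there.
* In the ultrafast variant the trace's `h` column reports $h_\infty(V)$ for
  interpretability; the state carries no `h` dynamics.
* The ultrafast variant is the τ~h~ → 0 limit of the finite variant:
  at τ~h~ = 0.01 ms voltages agree within 1 mV away from plateau edges and
  durations to sub-sample precision. *At* an edge, a kinetic lag of τ~h~
  multiplies a ~300 mV/ms repolarization slope, so a pointwise voltage
  comparison there measures edge steepness rather than model disagreement.
* Noiseless plateau durations depend very weakly on V~1/2~ (249.4–249.7 ms
  across 10–20 mV): the repolarization latch engages at a V~1/2~-dependent
  voltage, shifting threshold crossings by a few tenths of a millisecond.
  The three midpoint models are identical until the IPSP arrives, not
  bitwise-identical in measured duration.
* Two-level selection for reporting: the *first* cell classified
  `two_level` in the sweep's scan order, a deterministic and
  selection-neutral rule.

## Limitations

The model is a single compartment with deterministic channel gating; noise
enters only through the inhibitory synaptic conductance. No muscle mechanics,
no pharyngeal network, no temperature or modulator dependence. The
quantal-scale sensitivity above is the dominant caveat when comparing
absolute noise-collapse statistics against recordings: the qualitative
V~1/2~ and τ~h~ orderings are robust model properties, while the noise
intensity at which collapse occurs depends on the ratio of quantum size to
total membrane conductance, which the package exposes rather than fixes.
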