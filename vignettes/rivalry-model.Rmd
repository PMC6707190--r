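---
title: "Modelling perceptual rivalry in balanced spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceptual rivalry in balanced spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalnet)
```

## The model

rivalnet simulates deterministic networks of leaky integrate-and-fire (LIF)
neurons with spike-frequency adaptation and asks whether a single circuit
can simultaneously produce *perceptual* variability (stochastic-looking
alternations between two percepts under a constant ambiguous stimulus) and
*spiking* variability (irregular, asynchronous firing as described by
balanced-state theory).

Each neuron obeys

$$\frac{dv_i}{dt} = f_i + s_i(t) - \frac{v_i}{\tau_m} - \gamma a_i(t),
  \qquad v_i < \theta,$$

with reset $v_i \to v_i - \theta$ at threshold, a synaptic input trace

$$\frac{ds_i}{dt} = -\frac{s_i}{\tau_s} +
  \sum_j w_{ij}\,\delta(t - t^j_\mathrm{spike}),$$

and an adaptation trace

$$\frac{da_i}{dt} = -\frac{a_i}{\tau_a} + \delta(t - t^i_\mathrm{spike}).$$

Parameters and units: voltages in mV, times in ms, drive $f$ and the
synaptic trace $s$ in mV ms⁻¹. Defaults are $\theta = 20$ mV,
$\tau_m = 20$ ms, $\tau_s = 2$ ms, integration step $h = 0.1$ ms. The
discrete mutual-inhibition case example uses $(\tau_a, \gamma) =
(350\,\mathrm{ms}, 0.44)$ and the continuum case example
$(650\,\mathrm{ms}, 0.013)$; the unstructured network runs without
adaptation.

### Integration scheme

The subthreshold system is advanced with a two-stage (Heun / modified
Euler) step; the exponential traces $s$ and $a$ are advanced exactly. A
threshold crossing inside a step is timed by linear interpolation between
the endpoint voltages; the reset, the $a_i \mathrel{+}= 1$ adaptation
increment and the postsynaptic increments are applied at the end of the
step, with each increment weighted by
$e^{-(t_\mathrm{end}-t^*)/\tau_s}$ so the synaptic trace at the step
boundary is first-order consistent with the interpolated spike time
(`sync_weighted = FALSE` switches to raw increments for sensitivity
checks). One reset is applied per step; the interpolation clamps the
crossing fraction into $[0, 1]$ so a pathological double crossing cannot
corrupt the spike time. Initial voltages are uniform on $[0, \theta)$ from
the run seed — the equations are deterministic, so the seed (plus any
Ornstein–Uhlenbeck drive realization) fixes the trajectory bit-for-bit.

The $\delta$-impulses in the synaptic equation are applied literally: a
spike on a synapse of weight $w$ increments $s$ by $w$, so one spike
delivers an integrated depolarization of $w\,\tau_s$ mV. We also
implemented and examined the alternative unit-area normalization
($s \mathrel{+}= w/\tau_s$); the literal reading is the package default
because it is the one whose dynamics are step-size consistent (population
rates change by far less than 5% between $h = 0.1$ and $h = 0.01$ on the
discrete case example) and asynchronous in the structured regimes, which
are the properties the model family is meant to have. See *Known
limitations* for what hangs on this choice.

## Architectures

* **Unstructured** (`build_unstructured()`): half excitatory, half
  inhibitory; every neuron receives exactly `k = 600` in-synapses from each
  class with weight $A_{XY}/\sqrt{k}$ (case amplitudes
  $A_{ee}, A_{ie}, A_{ei}, A_{ii} = 12.5, 20, 50, 50$), negative for
  inhibitory afferents. Fixed in-degree implements "received $k$
  in-synapses" exactly; sampling is without replacement per postsynaptic
  neuron.
* **Discrete mutual inhibition** (`build_discrete()`): two pools of 1000 E
  + 1000 I wired internally as unstructured networks with `k = 200`
  (amplitudes $10.5, 20, 30, 45$), plus exactly `k` long-range
  excitatory→inhibitory synapses per inhibitory neuron from the opposite
  pool ($A_{ie_{LONG}} = 30$). The pools interact *only* through these
  connections.
* **Continuum ring** (`build_continuum()`): 80% E / 20% I arranged evenly
  on a ring, Bernoulli(`p = 0.34`) wiring, weights following a von Mises
  profile $A^C e^{\kappa^C \cos(\theta_i - \theta_j)} /
  (p N 2\pi I_0(\kappa^C))$ with $N$ the postsynaptic class size. Case
  concentrations $\kappa^{ee}, \kappa^{ei}, \kappa^{ie} = 0.26, 0.93,
  0.97$. The reference parameter list repeats $\kappa^{ee}$ where
  $\kappa^{ii}$ is expected; we assign $\kappa^{ii} = 0.5$ and expose it as
  a config key. Ring angles are $2\pi\,\mathrm{rank}/N_\mathrm{class}$ per
  class; only angle differences matter.

## Drive protocols

`stimulus_drive()` delivers constant current to the excitatory neurons of
the two percept pools (for the continuum these are two stimulated arcs,
default half-width 45°, centred at 0 and $\pi$; arc width and the continuum
drive value are package conventions, with drive 5 as default to match the
discrete example's stimulus). `heterogeneous_ou_drive()` gives the two E
pools independent Ornstein–Uhlenbeck currents (mean 0.2) and the I
population one OU current (mean 0.1), stationary SD 1 and correlation time
500 ms; "SD" is the stationary standard deviation, the update is the exact
discretization $x(t+h) = \mu + (x - \mu)e^{-h/\tau} +
\sigma\sqrt{1 - e^{-2h/\tau}}\,\xi$, and negative excursions are *not*
clipped (a `clip_zero` option exists). `homogeneous_drive()` gives constant
0.2 / 0.1 to E / I; the protocol specifies only that E drive is slightly above
I, so these defaults borrow the OU means and all claims about the
homogeneous case are qualitative.

## Measures

The percept readout pools excitatory spike counts per pool in 50 ms
windows and forms $P = (u_A - u_B)/(u_A + u_B)$; windows with $P > 1/3$
are percept A, $P < -1/3$ percept B, the rest (including empty windows and
exact boundaries) "neither". A *dominance duration* is the interval between
reported percept changes: labeled runs shorter than the report threshold
(default 300 ms) and "neither" runs are absorbed into the ongoing epoch, so
the clock runs until the next reportable change (`policy = "drop"` instead
reports each maximal run's own length). First and last epochs are censored
and excluded from moments. Summary statistics are the sample mean, SD,
CV_D, adjusted Fisher–Pearson skewness (the skewness/CV_D ratio is
sensitive to the estimator, hence the explicit choice), and a
maximum-likelihood gamma fit (via `MASS::fitdistr` on mean-rescaled data).

State-conditioned spiking statistics condition on the reported percept:
pool A is *dominant* in reportable percept-A runs and *suppressed* in
reportable percept-B runs; "neither" windows and sub-threshold events
belong to no mask, and censored epochs are included (an unbroken
winner-take-all run still has well-defined dominant/suppressed states).
CV_ISI pools each neuron's interspike intervals across same-state blocks
(intervals spanning a state change are discarded; at least 3 intervals per
neuron). Fano factors and pairwise spike-count correlations use 100 ms
windows lying entirely within the masked state; `r_sc` samples 1000
within-pool E–E pairs by default, seeded. `sigma_mu_regression()` fits SD
against mean through the origin so the slope reads as an overall CV_D; a
with-intercept fit is returned alongside. `levelt_checks()` encodes the
psychophysical regularities (mean duration falling with drive;
predominance 'X' crossing; maximal alternation at equi-dominance) as sign
and ordering tests on scan summaries.

## Balanced-state theory

In the balanced state the mean input to every population sits at
threshold, giving $W\mathbf{r} + \mathbf{f} = 0$. For the discrete
architecture the pools couple only through the long-range E→I weight, so
the $4\times4$ system (populations $e_1, i_1, e_2, i_2$) has zeros at all
other cross-pool entries. `solve_balanced()` inverts the system when
well-conditioned and otherwise performs an explicit column-space test via
least squares (a symmetric coupling with asymmetric drive is thereby
reported insolvable, the theory's explanation of why the unstructured
network cannot support a global balanced state); negative rates are
reported infeasible, never clamped silently. Effective weights from the
microscopic architecture are $w_{XY} = \sqrt{k}\,A_{XY}\,\tau_s$ with rates
in spikes/ms: each of the $k$ afferents contributes $A_{XY}/\sqrt{k}$ per
spike integrated over $\tau_s$. Because the comparison with simulation is
about curve shape and regime boundaries, `compare_theory_simulation()`
fits one global scale factor on the symmetric branch and freezes it.
`sweep_mutual_inhibition()` locates the theory's singularity — the
harbinger of the symmetric-to-WTA transition — by bisection on
$\det W(w_{ie_{LONG}})$; singularity is declared at
$|\det W|/\|W\|^4 < 10^{-12}$.

## Synthetic fixtures

Every estimator is validated against generators with known truth
(`poisson_raster()`, `periodic_raster()`, `gamma_renewal_raster()`,
`alternating_two_pool_raster()`), which share the `spike_raster` container
and file format with the simulator. The alternating fixture draws epoch
durations from a gamma distribution and fills them with Poisson spiking at
dominant/suppressed rates, so the full dominance pipeline can be checked
against exact ground truth: gamma(4) epochs must recover CV_D ≈ 0.5 and
skewness/CV_D ≈ 2. The fixtures emulate state-switched Poisson statistics
only — they have no refractoriness, no cross-neuron correlations and no
escape dynamics, so passing them validates the *measurement* pipeline, not
the biological realism of the simulator.

## Problem sizes and test scaling

The test suite and the acceptance script run the full reference network
sizes (n = 4000) but scaled-down durations and grids, chosen once: 60–120 s
of biological time for single runs, 5–6-point drive scans at 20–60 s per
point, and a 600 s unstructured OU run. Quantities whose sampling error at
these sizes exceeds the stated tolerance are noted in the test
assertions themselves.

## Design choices where the model description was open

* **Initial state**: uniform random voltages avoid the spurious synchrony
  of identical initial conditions; traces start at zero; the first 2 s are
  discarded as burn-in (configurable).
* **Kernel normalization**: literal $\delta$ increments (see *Integration
  scheme*).
* **$\kappa^{ii} = 0.5$** for the continuum (duplicated-entry reading).
* **Continuum stimulus**: drive 5 to two 45°-half-width arcs.
* **Sub-threshold filtering**: absorb by default, drop as option.
* **Homogeneous drive values**: 0.2 / 0.1 (E/I), qualitative only.
* **Report-threshold robustness**: quantified as the max/min CV_D ratio
  across thresholds {150, 300, 450} ms with 1.5 as the bound used in the
  constraint report.

## Known limitations

The headline perceptual phenomenon — stochastic seconds-scale alternation
of the discrete case example at the reference parameters — does **not**
emerge under this package's integration scheme. The mechanism is sharply
parameter-sensitive: the escape of the suppressed pool requires its mean
input deficit to sit within roughly one fluctuation standard deviation of
threshold, and the two natural δ-kernel normalizations bracket this point
without hitting it. Under the literal reading the case example settles
into a permanent winner-take-all whose dominant-pool spiking statistics
are biophysical (CV_ISI ≈ 1.0, Fano ≈ 0.93, r_sc ≈ 0, rates in the 5–40 Hz
band) but whose suppressed pool is essentially silent; under the unit-area
reading the symmetric state is captured by a strongly synchronized
oscillatory attractor. Statistics conditional on alternation (dominance
duration moments, suppressed-state spiking variability, Levelt scans and
the σ–μ slope) are therefore undefined or unreproduced for the simulator's
case examples, while the measurement battery itself is fully validated on
fixtures, and the single-neuron, architectural and mean-field components
are validated against closed forms and independent oracles. The continuum
example likewise shows no winner-take-all at the package's default stimulus
conventions; its rivalry point is known to occupy a very small parameter
region. The balanced-state sweep, by contrast, reproduces the predicted
structure: rates fall with mutual inhibition (excitatory faster than
inhibitory), and the theory's singularity anticipates the
symmetric-to-asymmetric transition.
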