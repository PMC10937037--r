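---
title: "Structural conditions for oscillations: methods and design notes"
author: "oscicycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural conditions for oscillations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscicycle)
```

# The scientific question

Whether a network of interacting populations can oscillate is, in general, a
question about its weights — quantities that are rarely measurable in
biological systems. What *is* usually known is the wiring diagram and the
sign of each interaction. `oscicycle` implements a structural theory that
answers the question from signs alone, plus a minimal coupling-strength
condition, and carries the theory through three model layers of increasing
biological realism:

1. **Signed directed graphs** and the *odd inhibitory cycle rule*: a
   directed cycle can support oscillations only if it contains an odd
   number of inhibitory edges (a *negative loop*). Edges inherit their sign
   from their source node, because a neural population is excitatory or
   inhibitory as a whole.
2. **Threshold-linear networks (TLN)**: each node obeys
   `dx_i/dt = -x_i + [sum_j W_ij x_j + b_i]_+`. For a single directed cycle
   the long-term behavior is classified exactly by a handful of
   inequalities (below). Acyclic networks always converge.
3. **Delayed Wilson-Cowan rate models and a spiking basal-ganglia
   network**, which test whether the structural predictions survive
   delays, sigmoidal gains, conductance synapses and Poisson noise.

# The single-cycle classification

For a ring of `n` nodes with positive weight magnitudes `w_i` (edge
`i -> i+1`), the *inhibited* nodes `a_1 < ... < a_nI` (those whose cyclic
predecessor is inhibitory) receive constant positive input `b_{a_k}`;
excited nodes receive none. With segment products
`P_k = prod(w_i, i = a_k..a_{k+1}-1)` and input ratios
`R_k = b_{a_{k+1}}/b_{a_k}`:

* every `P_k < R_k` (weak coupling): unique globally stable fixed point —
  no oscillation regardless of parity;
* every `P_k > R_k` and `nI` even: two stable fixed points on strictly
  complementary supports (winner-take-all);
* every `P_k > R_k`, `nI` odd: the unique full-support fixed point is
  stable while the geometric mean `rho = (prod w_i)^{1/n}` stays below
  `1/cos(pi/n)`, and unstable above it. In the unstable case the bounded
  dynamics must oscillate (limit cycle, quasi-periodic, or chaotic — the
  package classifies all three as "sustained" and does not distinguish
  them).

On its full support the Jacobian is `-I + W`, with closed-form spectrum
`-1 + rho * zeta`, `zeta` the n-th roots of `(-1)^{nI}`; the leading real
part `-1 + rho*cos(pi/n)` crosses zero exactly at the coupling threshold.
`classify_regime()` evaluates the inequalities with relative tolerance
`1e-9`; a comparison within tolerance of its bound returns
`INDETERMINATE_GAP` rather than a guess, because between the weak and
strong conditions the theory is genuinely silent. Mixed segment
comparisons are likewise indeterminate.

Two boundary cases deserve a note. A purely excitatory ring (`nI = 0`) and
the two-node EI pair are out of the classification's scope; the EI pair is
still constructible because its linearization (eigenvalues
`-1 ± i*sqrt(w1 w2)`) makes it the textbook example of a negative loop
that *cannot* oscillate under threshold-linear dynamics — the threshold
is never engaged in the attracting region, so the spiral converges.
Inhibitory self-loops are counted as negative loops of length one by the
graph layer, but the cycle theory requires length at least two, so reports
flag them separately.

## Quenching by input

Injecting a constant extra input `b_extra > 0` into an excited node `i`
raises its activity above `b_extra`; the next inhibited node `a_{k+1}` is
then silenced *forever* whenever `b_extra * prod(w_j, j = i..a_{k+1}-1) >
b_{a_{k+1}}` — the cycle is structurally broken and oscillation is
impossible. This bound is *sufficient*: between it and the
guaranteed-survival zone (total propagated drive
`b_{a_k} P_k + b_extra * prod(w) < b_{a_{k+1}}`) the outcome depends on
the upstream input structure. `quench_check()` therefore probes both
decisive zones when validating predictions against simulation. (A related
subtlety: the printed source of the negative-input variant of this bound
carries a sign that is inconsistent with the positive-input branch; the
package uses the sign under which the two branches agree.)

# Numerical choices

* **TLN integrator**: forward Euler, `dt = 0.01` time units. The dynamics
  are non-smooth at the threshold, so high-order solvers buy nothing; the
  fixed points of the Euler map coincide exactly with those of the flow.
  Default initial states are drawn uniformly inside the invariant box
  `x_j in [0, b_{a_k} prod(w)]` per segment — the hypothesis under which
  the classification is proved (the bound is removable, but it is the
  honest default).
* **Trajectory classification**: quarters of the trajectory are scored by
  peak-to-trough amplitude; "sustained" requires the final quarter to
  exceed an absolute floor of `1e-3` and at least 0.9 of the previous
  quarter (the envelope has stopped decaying); "converged" requires the
  last quarter to stay within `1e-4` of the final state. A slowly decaying
  oscillation that has not yet crossed the floor is *undetermined*, never
  forced into a class.
* **Regime-versus-dynamics validation** (`regime_concordance()`):
  200 random cycles, `n` in 2..6, log-uniform weights in `[0.2, 5]`,
  inputs in `[0.5, 2]`, excluding a 2% relative band around every
  inequality boundary, where finite-horizon simulation cannot decide.
  Horizons: 400 time units for oscillatory cases (instability growth rate
  is at least `~0.02` per unit time outside the exclusion band), 250 for
  weak-coupling convergence (contraction rate at least
  `1 - cos(pi/6) ~ 0.13`, but admissible boxes can start trajectories far
  away).

# The Wilson-Cowan layer

Populations follow `tau dr_i/dt = -r_i + F(sum_j w_ij r_j(t - d_ij) +
I_i)` with `F(x) = 1/(1+exp(-a(x-theta))) - 1/(1+exp(a*theta))`,
`tau = 20` ms, `a = 3`, `theta = 1.5`, Euler step 0.01 ms, per-edge delay
buffers. Note that `F` is slightly negative for negative drive (its lower
bound is `-1/(1+exp(a*theta)) ~ -0.011`): rates are not clamped, so
"rates in [0,1)" holds only up to that offset. Frequencies are reported in
Hz via the millisecond time base.

Two design choices matter:

* **Symmetry breaking.** The homogeneous motif fixtures (e.g. the
  all-inhibitory triangle `III`) have an exact permutation symmetry, and
  the Euler map preserves it: a perfectly uniform initial state sits on
  the symmetric manifold forever and never oscillates, no matter the
  coupling. A scalar initial rate is therefore expanded to the graded
  vector `r0 + 0.01*(0:(n-1))`. This replaces a uniform-start convention
  with one that actually samples the generic basin.
* **The EII fixture's excitatory edge.** The even-inhibitory ring fixture
  uses `+15` for its single excitatory projection; a negative value there
  would make the excitatory population effectively inhibitory, turning
  the motif into an odd-inhibitory ring and contradicting its defining
  winner-take-all behavior.

The four-population basal-ganglia fixture `BG4` (D2, Arky, Proto, STN;
weights -15/+15, Proto self-inhibition -8, STN self-excitation +5 kept as
printed with a switch to zero it, delays 2 ms) contains two competing
oscillators: the Proto-STN pair (~30 Hz at moderate STN drive) and the
Proto-Arky-D2 triangle (~10 Hz at strong D2 drive). Lesion experiments
(`lesion()`) reproduce the dissociation: removing D2->Proto leaves a
narrow STN-input window of pair oscillation; removing STN output (with
Proto input raised 1 -> 4 to restore baseline) leaves the slower triangle
rhythm.

# The spiking layer

D2-SPN, FSN and STN neurons are conductance-based LIF; Proto and Arky
(external globus pallidus) are AdEx with spike-triggered adaptation. The
membrane leak drives toward the reset potential as printed in the source
equations (leak reversal = `V_reset`), which is unusual but followed;
synaptic currents are applied as `-g(V - E_rev)` so a reversal above the
membrane potential depolarizes. Alpha-function synapses
(`g(t) = J (t/tau) exp(-(t-tau)/tau)`, peak exactly `J`) are realized by
an exact two-state update; membranes advance by fixed-step RK4
(`dt = 0.1` ms) with start-of-step conductances, threshold and reset
resolved at step boundaries, and a 2 ms refractory clamp. Each neuron
receives an independent homogeneous Poisson excitatory train plus a DC
bias current. Everything is seed-deterministic, including the random
connectivity realization.

The detailed neuron/synapse tables of the source model chain are not
available, so the defaults (capacitances, conductances, reversal
potentials, 13-30 Hz-capable delays of 2-4 ms, connection probabilities
0.1-0.2, 300 neurons per population) are the package's own, adapted from
the conductance-based basal-ganglia modelling lineage, documented in
`spiking_fixture()` and explicitly non-canonical. They were chosen once so
that the motif fixtures operate in the regimes the theory predicts —
a beta-band (~14 Hz) rhythm in the inhibitory triangles and a ~23 Hz
rhythm in the reciprocal Proto-STN loop — and then frozen; the
acceptance-level claims are deliberately qualitative contrasts
(persistence versus collapse of beta power under STN inhibition), not
spectral magnitudes, precisely because the parameter tables are
reconstructions.

The STN-inhibition experiment (`stn_inhibition_experiment()`) sweeps the
STN bias current (1 to -99 pA with the triangle as dominant oscillator;
30 to -50 pA with the pair) and tracks beta-band power of the pooled
population rates (PSTH at 0.1 ms bins, analyzed at 1 kHz). The structural
prediction — an oscillator survives STN silencing if and only if its
negative loop avoids the STN — comes out as ~80% retention of Proto beta
power in triangle mode versus a collapse below 5% in pair mode.

# Spectral metrics

`welch_psd()` is a mean-detrended, Hann-windowed, 50%-overlap averaged
periodogram (segment `min(length/4, 4096)`, zero-padded fourfold), scaled
so the integrated density approximates the variance. Band power uses
half-open intervals `[lo, hi)`, which makes it exactly additive over
adjacent bands; the beta band is `[13, 30)` Hz. The source only names the
PSD method, so these settings are documented package choices.

# What the synthetic benchmarks do and do not show

All validation inputs are generated by the package itself: random cycles,
random acyclic networks, and motif fixtures with the printed parameter
tables. They establish internal consistency — that simulated dynamics obey
the structural classification under the theory's own assumptions (no
delays in the TLN layer, constant inputs, sign-pure nodes) — and
qualitative robustness in two more realistic layers. They do not calibrate
to any recorded data, do not reproduce exact published spectra (figure
frequencies were not machine-readable), and say nothing about cycles
whose segment inequalities disagree, where the theory itself is open.
The cortico-basal-ganglia graph fixture contains exactly the edges implied
by the six printed oscillation-capable loops plus the Proto
self-inhibition; a reconstructed extended variant exists but no reported
count depends on it.

# Problem sizes

The standing experiment sizes (200 cycles for concordance, 100 spectra,
50 acyclic networks, 20 quench cycles, 300 neurons per population and
2 s per grid point in the spiking experiment) are the package defaults;
they were chosen as the smallest sizes at which every qualitative result
is stable across seeds, and all are arguments that can be scaled up.
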