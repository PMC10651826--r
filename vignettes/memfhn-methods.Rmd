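---
title: "Adaptive memristive FHN networks: model, plasticity rules and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive memristive FHN networks: model, plasticity rules and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfhn)
```

`memfhn` simulates complete synchronization (CS) and phase synchronization
(PS) in time-varying directed networks of memristive FitzHugh–Nagumo (FHN)
neurons. Two adaptive processes act on top of the neuronal dynamics: a
depression-dominated spike-timing-dependent plasticity (STDP) rule that
modifies synaptic weights, and a homeostatic structural plasticity (HSP)
rule that continually swaps synapses while preserving the network's
small-world or random character. This vignette records the model, every
tunable parameter with its default, the numerical choices made where the
design was genuinely open, and the known limitations of the pipeline.

## The single neuron

Each neuron carries three state variables: membrane potential $v$, recovery
variable $w$ and magnetic flux $\phi$,

$$
\dot v = v(v-a)(1-v) - w + k_3\, v\, \rho(\phi) - I^{syn}, \qquad
\dot w = \varepsilon (v - d\, w), \qquad
\dot \phi = k_1 v - k_2 \phi + \phi_{ext},
$$

with the flux-controlled memristance $\rho(\phi) = \lambda + 3\beta_m \phi^2$
feeding the electromagnetic induction current $k_3 v \rho(\phi)$ back into
the membrane equation. Defaults (see `neuron_params()`): $a = 0.5$,
$\varepsilon = 0.025$, $d = 1$, $\lambda = 0.1$, $\beta_m = 0.02$,
$k_1 = 0.5$, $k_2 = 0.9$, $k_3 = 1$, $\phi_{ext} = 2.4$. Without the flux
feedback ($k_1 = k_2 = k_3 = 0$) the neuron is quiescent at these values;
with it, the neuron spikes periodically (regular spiking). The uncoupled
period at the defaults is 124.5 time units under RK4 with $dt = 0.01$ (the
test suite cross-checks the integrator against an independent `deSolve`-free
brute-force implementation; the uncoupled period was additionally verified
against `deSolve::ode` during development).

Spikes are defined as upward crossings of $v_{th} = 0.5$, stamped at the end
of the step in which the crossing occurs (resolution $dt$; no sub-step
interpolation — the crossing instant itself is what defines a spike here).

## Synapses

Neuron $j$ drives its postsynaptic targets through a gate $s_j \in [0,1]$
(fraction of open channels, one gate per presynaptic neuron shared by all
its outgoing synapses):

$$
\dot s_j = \frac{2(1-s_j)}{1 + e^{-v_j(t-\tau_c)/v_{shp}}} - s_j,
$$

with sharpness $v_{shp} = 0.05$ and axonal delay $\tau_c \ge 0$. The
sigmoid is evaluated in saturating form (exactly 0 or 1 for
$|v|/v_{shp} > 40$) so the exponential cannot overflow; $[0,1]$ is forward
invariant. Closed gates decay like $e^{-t}$ and are flushed to zero below
$10^{-30}$ — far below any dynamical scale — because values drifting into
denormal floating-point range would otherwise slow the integrator by an
order of magnitude without changing the dynamics.

The synaptic current onto neuron $i$ is in-degree normalized and excitatory
(reversal potential $v_{syn} = 2$ above the spiking range):

$$
I_i^{syn} = \frac{1}{k_i} \sum_j \ell_{ij}\, g_{ij}\, s_j\, (v_i - v_{syn}).
$$

A neuron with $k_i = 0$ receives zero current by definition; with the
in-degree-preserving rewiring below this case cannot arise in production
runs, but it is a defined input, not an error.

## STDP

Weights live in $[g_{min}, g_{max}] = [0.001, 0.5]$ and are initialized
from $\mathcal N(0.35, 0.01)$, truncated to the bounds by resampling (no
probability mass accumulates at the bounds; at $\sigma_0 = 0.01$ the
truncation is immaterial but defined for reproducibility). The
nearest-spike-pair modification factor is

$$
M(\Delta t) = \begin{cases}
P\, e^{-|\Delta t|/\tau_p} & \Delta t > 0 \\
-D\, e^{-|\Delta t|/\tau_d} & \Delta t < 0 \\
0 & \Delta t = 0,
\end{cases}
\qquad \Delta t = t_{post} - t_{pre},
$$

with $\tau_p = \tau_d = 2$, $D = 1.05\,P$ (depression-dominated:
$D\tau_d > P\tau_p$), and multiplicative update
$g \leftarrow \mathrm{clip}(g\,(1 + M))$. $P$ is the control parameter,
scanned over $[10^{-6}, 10^{-3}]$.

**Update schedule.** The pair rule fixes *what* changes but not *when* the
update is applied, and the two natural readings differ enormously in
effective learning rate. `stdp_params(schedule = )` implements three:

* `"spike"` — event-driven: when a neuron fires, its incoming synapses
  receive the potentiation branch and its outgoing synapses the depression
  branch, each against the partner's most recent spike ($O(k)$ work per
  spike). Over a full run of $T = 3000$ time units a neuron fires only a
  few dozen times, so with $|M| \le 1.05 \times 10^{-3}$ the mean weight
  cannot move by more than a few percent: under this schedule the weight
  landscape is essentially flat in $P$.
* `"step"` (default) — the current nearest-pair factor $1 + M$ is applied
  at every integration step (cached per edge and refreshed when either
  endpoint fires or the edge is rewired). Between partner spikes a synapse
  therefore compounds its current factor geometrically, and at
  $P = 10^{-3}$ weights polarize to the bounds within a few network
  periods. This is the only schedule that reproduces the reported weight
  phenomenology of this model class — a mean weight $G$ that falls from
  $0.35$ to order $0.1$ within one run as $P$ grows to $10^{-3}$, with a
  saturating time course — and it is therefore the package default.
* `"step_dt"` — like `"step"` but with the factor scaled to $1 + M\,dt$,
  the reading of $M$ as a rate density. It produces weight drifts
  intermediate between the other two and is retained for sensitivity
  analysis.

Coincident spikes ($\Delta t = 0$) never change a weight: all simultaneous
spikers are time-stamped before any update is applied, which keeps the
synchronized state exactly invariant under STDP. A synapse whose partner
has never fired is left untouched.

## Network and HSP

The directed Watts–Strogatz generator (`ws_network()`) starts from a ring
in which every neuron receives from its $\langle k \rangle/2$ nearest
neighbours on each side, then replaces each edge's presynaptic endpoint
with probability $\beta$ by a uniform non-self, non-duplicate source.
Every in-degree equals $\langle k \rangle$ by construction. $\beta = 1$
gives the random network; $0 < \beta < 1$ a small-world network; regular
networks ($\beta = 0$) are generated for testing but not studied.

HSP rewires existing synapses once per integration step
(`rewire_step()`, and inside the engine):

* small-world rule: a synapse between *distant* neurons (circular index
  distance $> \langle k \rangle$) is rewired to a *near* neighbour of its
  postsynaptic neuron with probability $(1-\beta) F\, dt$; a synapse
  between near neighbours is rewired to a distant neuron with probability
  $\beta F\, dt$;
* random rule: every synapse is rewired to any eligible neuron with
  probability $(1 - \langle k \rangle/(N-1)) F\, dt$.

$F \in [0, 10^2]$ is the rewiring-frequency control parameter; at
$F = 100$, $dt = 0.01$ the per-step probabilities reach 1 (they are clamped
there), so every synapse is retested each step. Design choices, each of
which the underlying description leaves open:

* the postsynaptic endpoint is always kept, so in-degrees (and the $1/k_i$
  normalization) are exactly conserved — "a nearest neighbour of one of
  the neurons" is resolved to the kept endpoint's neighbourhood;
* index distance is circular (the ring the construction starts from has no
  boundary);
* the new presynaptic endpoint is drawn uniformly from the eligible set
  (excluding self and existing sources); an empty eligible set skips the
  attempt and increments a counter;
* a rewired synapse keeps its weight, so the weight multiset is invariant
  under HSP and the effects of STDP and HSP on $G$ remain separable;
* each edge is tested at most once per step; edges created within a step
  are not retested in it.

Under the small-world rule the stationary rewired ensemble is slightly
less clustered than a fresh Watts–Strogatz draw at the same
$(N, \langle k \rangle, \beta)$ (transitivity $\approx 0.27$ against
$0.30$–$0.36$ fresh, $0.18$ random, at $N = 100$, $\langle k \rangle = 10$,
$\beta = 0.25$): rewired near-synapses sample the full
$\langle k \rangle$-neighbourhood while the original ring uses only
$\langle k \rangle / 2$ per side. The network remains unambiguously
small-world, and the test suite asserts exactly that.

## Integration protocol

`sim_config()` fixes the study protocol: classical RK4 with $dt = 0.01$,
total time $T = 3 \times 10^3$, transient $T_0 = 2.4 \times 10^3$ excluded
from every metric (STDP and HSP act from $t = 0$), $N = 100$ neurons, and
random initial conditions drawn uniformly from
$v \in [-0.5, 1.6]$, $w \in [0.1, 1]$, $\phi \in [2.45, 3.5]$; gates start
at 0 (the gate relaxes within a few time units, well inside the
transient). Delayed potentials are kept in a ring buffer of
$\tau_c/dt + 1$ vectors, pre-filled with the initial state (constant
pre-history), read once per step and held constant across the four RK4
stages — a method-of-steps approximation whose $O(dt)$ error enters the
delay term only; $\tau_c$ is rounded to a whole number of steps with a
warning. The per-step order is: integrate, detect spikes, STDP, HSP, push
the delay buffer, record. Trajectories and the mean-weight trace are
recorded every `record_stride` steps (default 10, i.e. every 0.1 time
units); the Kuramoto average uses the same grid. One master seed spawns
independent substreams for network construction, initial weights, initial
conditions and the rewiring/plasticity stream, so each component can be
frozen independently in tests.

## Observables

* `sync_error()` — CS error $E$: time average of the mean Euclidean
  distance in $(v, w, \phi)$ to neuron 1; $E = 0$ iff all trajectories
  coincide.
* `kuramoto_r()` — PS order parameter $R \in [0,1]$: time average of the
  modulus of the mean unit phasor of the interpolated spike phases
  $\Psi_i(t) = 2\pi\ell + 2\pi (t - t_i^{(\ell)}) / (t_i^{(\ell+1)} -
  t_i^{(\ell)})$. The phase is undefined outside a neuron's first and last
  spike, so the average is restricted to instants where every included
  phase is defined; neurons with fewer than two spikes in the window are
  excluded with a warning.
* `average_weight()` — $G$: time-averaged mean weight of *existing*
  synapses. Averaging over the $N\langle k \rangle$ synapses (rather than
  all $N^2$ ordered pairs) is what makes $G(0) = g_0 = 0.35$ and keeps
  $G \in [g_{min}, g_{max}]$; the $N^2$ normalization sometimes written
  for this quantity is inconsistent with those anchor values.
* `mean_isi()` — mean over neurons of the mean interspike interval.
* `basin_stability()` — Monte Carlo basin stability: the fraction of
  random initial conditions whose full-run time-averaged metrics satisfy
  $E < 10^{-1}$ (CS, $B^E$) or $R > 0.9$ (PS, $B^R$).

## The delay-entrained network period

The coupled network's period is not the uncoupled 124.5: excitatory
coupling accelerates it to $\approx 110$ at $\tau_c = 0$, and the delay
then entrains it further. Sweeping $\tau_c$ over $[0, 160]$
(`run_sweep()`, `locate_sync_bands()`) produces recurring deep-CS bands at
exactly the self-consistent delays $\tau_c \approx n \cdot
\mathrm{ISI}(\tau_c)$: if a periodic solution with period $\bar\tau$
solves the delayed system with delay $\tau_c$, it also solves it with
delay $\tau_c + n\bar\tau$. At the first nonzero band the period is
$\approx 80$ time units, which is also the asymptotic spacing between
successive bands. Band identification (`locate_sync_bands()`) delimits deep-CS
bands at $E < 10^{-2}$ — an order of magnitude below the $E < 10^{-1}$
CS precision, cleanly between the band bottoms ($E \sim 10^{-3}$) and the
near-CS shoulder ($E \gtrsim 2 \times 10^{-2}$) — and takes each band's
grid midpoint as its center, since the flat band bottoms make the
within-band argmin an unstable tie-break. The data-adaptive default
threshold is meant for exploratory profiles whose depth is not known in
advance. Quantities quoted for "the" network period therefore
refer to this delay-entrained regime; at $\tau_c = 0$ the network runs
about 35% slower.

## Scale of the shipped experiments

The acceptance script and test suite run deliberately reduced ensembles —
3–5 realizations per parameter point, a 17-point delay grid, two
basin-stability grid points at $Q = 25$ trials — chosen so the full
reproduction completes on a single CPU in well under an hour while keeping
Monte Carlo standard errors below the tolerances quoted for each quantity.
The full-resolution parameter planes (dozens of grid points × 25
realizations) are available through `run_sweep()` / `sweep_spec()` with
`realizations = 25`, and resume from per-point files via `out_dir`, but
they are overnight-scale jobs and are not exercised by the shipped suites.

## What the synthetic fixtures do and do not emulate

`make_spike_trains()`, `make_offset_trajectories()` and
`make_toy_network()` generate inputs with *known closed-form statistics*
(periodic/antiphase/Poisson trains, constant-offset trajectories, small
printable networks) so every metric and plasticity operation is testable
without simulation. They emulate the structure the metrics consume — not
real electrophysiology: no spike jitter, rate adaptation, bursting or
measurement noise. Tests passing on fixtures certify the *estimators*, not
the biological realism of the model.

## Known limitations

* The delayed term is held constant across RK4 stages; for studies needing
  higher-order delay accuracy a stage-interpolating DDE scheme would be
  required.
* Spike times have resolution $dt$; metrics that depend on sub-step spike
  timing would need event location.
* The weight dynamics at large $P$ depend on the STDP update schedule (see
  above); under the default per-step schedule the mean weight at
  $P = 10^{-3}$ also falls with the rewiring frequency $F$ (from
  $\approx 0.107$ at $F = 0$ to $\approx 0.036$ at $F = 100$, small-world),
  because constant rewiring keeps resampling the nearest-pair intervals and
  the depression-dominated factor then compounds. Reports of this model
  class in which $F$ has no visible effect on $G$ are matched at $F = 0$
  but not at large $F$.
* Basin-stability levels for CS are sensitive to the $E < 10^{-1}$
  threshold because the $E$ distribution across initial conditions is
  broad near the classification boundary.
* Heat-map-resolution parameter planes are out of scope for the shipped
  suites (desk-scale grids only).
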