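---
title: "Failure and recovery dynamics on networks: model, theory and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Failure and recovery dynamics on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(failrecov)
```

## The model

`failrecov` simulates and analyses a three-process failure–recovery model on
undirected networks. Every node is in one of three states: active (A),
internally failed (X) or externally failed (Y). Four independent exponential
clocks drive the dynamics:

* **internal failure** A → X at rate `p`, independent of the neighborhood —
  the analogue of an external field or spontaneous infection;
* **external (induced) failure** A → Y at rate `r`, active only when the node
  sits in a *critically damaged neighborhood* (CDN): at most `m` of its
  neighbors are active. This is a complex-contagion threshold rule — a single
  failed neighbor is not enough to propagate damage when `m < k - 1`;
* **recovery** X → A at rate `q` and Y → A at rate `q'`, unconditional on the
  neighborhood.

X and Y never interconvert and failed nodes cannot fail again. An active node
in a CDN therefore carries two competing clocks (total exit rate `p + r`),
and which fires first decides the failure type. We write `u_int`, `u_ext` for
the failed compartment fractions, `a = u_int + u_ext` and `z = 1 - a` for the
active fraction.

The simulator (`run_gillespie()`) is an exact, rejection-free kinetic Monte
Carlo implementation of this continuous-time Markov chain: per-node exit
rates are kept in a binary-indexed sum tree, waiting times are exponential in
the total rate, and after each event only the flipped node and its neighbors
are updated (events cost `O(log N)`). The C++ core draws from R's RNG, so a
`seed` makes entire trajectories reproducible event-for-event. Trajectories
are sampled on a uniform grid with piecewise-constant interpolation, which is
the correct reading of a jump process between events.

Two oracles validate the simulator rather than merely smoke-testing it:

* `exact_stationary()` builds the full `3^N`-state generator of the chain and
  solves for its stationary distribution — a direct dense solve up to
  `3^7` states, and uniformization (`P = I + Q/λ`) with power iteration
  beyond that, because a sparse LU of the `3^9` lattice generator suffers
  catastrophic fill-in. The test suite requires Gillespie long-run averages
  on the 3×3 periodic lattice (19,683 states) to agree with this exact vector
  within three Monte Carlo standard errors (batch-means estimator).
* Closed forms in two decoupled limits: with `r = 0` nodes are independent
  two-state units and `a* = (p/q)/(1 + p/q)`; with `m ≥ k` every node is
  permanently critical and `a* = s/(1+s)`, `s = p/q + r/q'`.

## Mean-field theory

Under perfect mixing, neighbors are independently failed with probability
`a`, so the CDN probability of a degree-`k` node is the binomial tail

$$E_k(a) = \sum_{j=0}^{\min(m,k)} \binom{k}{j} (1-a)^j a^{k-j}
        = P[\mathrm{Bin}(k, 1-a) \le m],$$

averaged over the degree distribution `f_k` (`cdn_probability()`). The
compartments evolve as

$$\dot u_{\rm int} = p(1-a) - q\,u_{\rm int}, \qquad
  \dot u_{\rm ext} = r(1-a)E(a) - q'\,u_{\rm ext},$$

where `(1-a)E(a)` is the joint probability of being active *and* critically
damaged under neighbor independence. `mf_integrate()` solves these with
deSolve's `lsoda` at `rtol = 1e-8`, `atol = 1e-10` — the system is stiff near
saddle-node points.

Stationary states depend only on the effective rates `x = p/q`, `y = r/q'`
through

$$F(a) = x(1-a) + y\,(1-a)E(a) - a = 0 .$$

`stationary_states()` finds all roots by a sign-change scan on a 2000-point
grid followed by bisection polishing (for single-degree `f_k`, `F` is a
polynomial and the tests compare against `polyroot` on its exact expansion).
Stability labels come from the Jacobian of the two-compartment system and
therefore need the absolute rates `q`, `q'`; the ratio-only interface omits
labels rather than guessing them.

### Spinodals and the cusp

Writing `G(a) = (1-a)E(a)`, the saddle-node conditions `F = F' = 0` are
*linear* in `(x, y)` at fixed `a`:

$$y = \frac{1}{(1-a)G'(a) + G(a)}, \qquad x = G'(a)\,y - 1 .$$

`spinodals()` evaluates this continuation on an `a`-grid; the two branches
meet at the cusp, where additionally `F'' = y\,G''(a) = 0`, i.e. `G''(a^*) =
0`. For a single integer degree, `G''` has integer coefficients, and
`cusp_point()` first attempts an exact rational root (rational-root theorem
plus exact fraction arithmetic in the 2×2 solve). For the reference setting
`k = 4`, `m = 1` this yields the cusp in closed form,

$$a^* = \tfrac{2}{5}, \quad p/q = \tfrac{19}{81}, \quad
  r/q' = \tfrac{3125}{1296},$$

which doubles as a validation of the reconstructed binomial form of `E(a)`.
Degenerate or mixed-degree cases fall back to a numeric scan of `G''` with
residuals below `1e-12`.

One structural point that the continuation makes explicit: the high-`a`
spinodal branch reaches `p/q = 0` at a finite `y` (about 3.12 for `k = 4`,
`m = 1`). For larger `r/q'` the bistable wedge is bounded by the `p/q = 0`
axis — the high-failure phase then persists all the way down to vanishing
spontaneous failure, which root counting confirms (three stationary states at
`p/q = 0.001`, `r/q' = 5`). `hysteresis_area()` accordingly treats the
missing branch as a zero lower bound when integrating the wedge width over a
window, on a fixed-step trapezoid grid so that enlarging the window can never
shrink the area.

## Oscillations

For `q > q'` the flow admits no closed orbits; for `q' > q` a narrow
parameter regime sustains a limit cycle. `oscillation_detect()` implements
the spectral criterion: linear detrend of the last half of a uniformly
sampled series, and a periodicity call when the dominant non-zero-frequency
power exceeds 10× the median spectral power (the threshold is ours; no
numeric criterion exists in the reference setting). `no_closed_orbits_check()`
integrates from random initial states and additionally requires a late-half
amplitude above `1e-2` *and* at least four turning points before calling a
trajectory oscillatory: near the degenerate cusp with `q > q'` convergence is
only algebraic, and the spectral leakage of a slow monotone crawl would
otherwise produce false positives (measured amplitude there is below `1e-2`
with zero turning points, against an amplitude of about 0.47 for the genuine
limit cycle at the `q' = 100q` operating point).

## Network generators

* `make_square_lattice(L, periodic)` — the Euclidean baseline; periodic
  lattices are 4-regular, node ids are row-major `i*L + j` (0-based in
  files), coordinates travel with the network.
* `make_regular_random_graph(N, k, seed)` — exact k-regular simple graphs via
  igraph's configuration-model sampler.
* `make_embedded_network(spec)` — nodes on a periodic `L × L` lattice, link
  lengths drawn from the truncated geometric law `P(l) ∝ exp(-l/ζ)` on
  `{1, …, ⌊L/2⌋}`, partners chosen uniformly among nodes at rounded
  minimal-image Euclidean distance `l`. Stub matching proceeds exactly at the
  drawn length; when a stub cannot be placed, an augmenting random walk
  displaces existing edges (degree-preserving, every edge still carries a
  drawn length) before any relaxation to a nearby length is allowed. As
  `ζ → 0` this recovers the square lattice (tests require ≥ 99% unit-length
  links at `ζ = 0.05`), as `ζ → ∞` link lengths become uniform and the graph
  approaches a regular random graph. Exact k-regularity is attempted; if the
  endgame is infeasible the achieved degree sequence is reported (mean degree
  within 1% is enforced with a warning otherwise).

What the generator does *not* emulate: real embedded infrastructures have
degree heterogeneity, directed capacities and correlated link placement;
passing tests on these graphs shows topology-dependence of the dynamics, not
realism of any particular infrastructure.

## Stochastic protocols and their parameters

* **Phase switching** (`detect_switching()`): hysteresis band on `z` with
  default `(0.3, 0.7)` — the two phases at the reference operating points sit
  near `z ≈ 0.8` and `z ≈ 0.15`, so the band is comfortably inside both
  basins; dead-band excursions do not count. Bimodality is Sarle's
  coefficient (`> 5/9` indicates bimodality).
* **Hysteresis loops** (`hysteresis_loop()`): sweep `p` up then down at fixed
  `r, q, q', m`, each step inheriting the previous final configuration,
  with `t_relax = 1000` discarded and `t_measure = 400` averaged per step at
  `N = 64²` in the acceptance protocol. At a continuous transition any
  finite-time sweep leaves a small remnant gap at the step nearest the
  critical point, and its size fluctuates from run to run. The robust
  discriminator is the gap *relative to the inter-phase separation* along
  the sweep: a discontinuous transition opens the loop by (nearly) the full
  distance between the two phases, a continuous one only by a small
  fraction of it. The acceptance checks call a transition discontinuous
  when the gap exceeds half the phase separation and continuous (zero at
  sweep resolution) when it stays below a quarter of it.
* **Simulated phase diagrams** (`simulated_phase_diagram()`): two initial
  conditions per grid point — all-active, and all *externally* failed. The
  all-Y choice matters: internally failed initial states decay at the fast
  rate `q` before induced failure can establish, so they do not probe the
  failed basin at all when `q ≫ q'`. A point is bistable when the two
  stationary active fractions differ by more than three pooled standard
  errors and a minimum gap (default 0.2). The acceptance protocol uses a
  9 × 4 grid (`p/q` from 0.06 to 0.22, `r/q'` in {4, 7, 10, 13}) at
  `N = 50²` with `t_relax = 150`, `t_measure = 100`; cell counts across
  `ζ ∈ {0.1, 1, 10}` are compared with a one-cell noise slack, and the
  `ζ = 10` diagram with the random-regular diagram within three cells.

Problem sizes throughout (3×3 for the exact oracle, 50²–128² for lattice
phenomenology, 64² for hysteresis) are the package's chosen desk-scale
conditions; the qualitative statements they support are size-robust, while
full-scale (`N ≥ 250,000`) phase diagrams are out of scope.

## Known limitations

* The two-way phase-switching check at the published lattice operating point
  (`p = 0.1065`, `r = 0.95`, `q = 1`, `q' = 0.1`, `m = 1`, 50² periodic)
  does not reproduce under this rate-based three-compartment dynamics: the
  acceptance run at that exact point reports zero band crossings, with the
  simulator itself validated against the exact master equation. Dwell times
  in the metastable region depend exponentially on the distance to the
  coexistence point, so a percent-level offset in `p` — whether from a
  different model variant behind the reference implementation or from tuning
  on a particular realization — freezes the dynamics in one phase. The switching
  phenomenon itself is real in this implementation at nearby `p`.
* The initial X/Y composition of partially failed initial conditions is not
  specified by the model; defaults are all-X (`"all-failed"`), with
  `"all-failed-ext"` provided and used where the failed basin must be probed.
* The explicit Lyapunov function behind the no-closed-orbit statement for
  `q > q'` (with constants `α = (q - q')/p`, `β = 1`) is not reconstructed
  here; the claim is checked numerically instead.
* Mean-field statements are exact only under perfect mixing; on lattices the
  bistable region is strongly shifted and narrowed, which is precisely the
  phenomenon the embedded-network comparison quantifies.
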