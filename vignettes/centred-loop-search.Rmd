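---
title: "Centred-loop search: model, noise scheme and trajectory analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centred-loop search: model, noise scheme and trajectory analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antsearch)
```

## The behaviour being modelled

When a *Cataglyphis* desert ant's path integrator says "you are at the
nest" but no nest is there, the ant starts a systematic search: a sequence
of loops in varying directions that repeatedly pass back through the
presumed nest position, so that the most likely location is sampled most
densely while the search area slowly grows. `antsearch` simulates this
behaviour with a deliberately minimal model. The only quantities the
simulated agent uses are quantities a path-integrating insect provably has
available: the home vector $\mathbf{u}$ (distance and direction to the
origin) and the direction of its own previous step — no map, no memory of
past loops, no landmark input.

## The deterministic skeleton

Time advances in integration steps of fixed length $s$ (a model time unit,
not a physical ant step; only paths are modelled, not speeds). Let
$\gamma$ be the angle between the outward radial direction and the current
step direction. Two rules generate centred loops:

1. **Constant turning relative to the home vector.** At every step
   $\gamma \leftarrow \gamma + \beta$ with a fixed incremental angle
   $\beta$, starting from $\gamma_0 = \alpha$. Because the radial
   reference direction itself rotates as the agent moves, the realised
   turning is the combination of both rotations: the path curls into a
   loop of roughly $360^\circ/\beta$ steps.
2. **Backward asymmetry.** The radial component of each step is
   $s\{\cos\gamma - |\cos\gamma|\,b\}$ with backward factor $b < 1$.
   Inbound ($\cos\gamma = -a$) this is $-a(1+b)$: the approach to the
   origin is faster and straighter. Outbound ($+a$) it is $+a(1-b)$:
   leaving is slower and curlier. Without this term ($b = 0$) the loops
   drift away from the centre and the pattern degenerates into a
   "spinning top" that never revisits the origin; with $b$ around
   0.2–0.3 each loop re-centres.

In the Cartesian frame, with $u = |\mathbf{u}|$,
$\mathbf{e}_r = \mathbf{u}/u$ and $\mathbf{e}_\varphi$ its
$+90^\circ$ rotation, one step is

$$\Delta\mathbf{u} = s\{\cos\gamma - |\cos\gamma|\,b\}\,\mathbf{e}_r
                   + s\sin\gamma\,\mathbf{e}_\varphi .$$

The same dynamics expressed in $(r, \varphi)$ state variables are
implemented in `simulate_polar()` and serve as an independent oracle: the
package's cross-check requires the two formulations to agree to better
than $10^{-8}$ relative over $10^4$ steps (measured: $\sim 10^{-11}$).

### A numerical note on the polar formulation

The textbook first-order projections $\Delta r = s\cos\gamma$ (with the
$b$ term) and $\Delta\varphi = s\sin\gamma/r$ are exposed as
`polar_step(method = "linearised")`. They are *not* used as the oracle:
they differ from the exact vector sum at order $s^2/r$ per step (a pure
tangential step at $r = 1$, $s = 0.12$ changes $r$ by $\approx 0.007$
under vector addition and by $0$ under the linearised rule), the error
compounds over a run, and the linearised radius can even cross zero. The
oracle therefore performs the vector sum *in* polar coordinates:
$r' = \sqrt{(r + \Delta_\parallel)^2 + \Delta_\perp^2}$,
$\varphi' = \varphi + \operatorname{atan2}(\Delta_\perp,\, r +
\Delta_\parallel)$, which is algebraically the same operation as the
Cartesian update and isolates genuine implementation errors rather than
discretisation mismatch.

## Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| $\alpha$ | initial step angle $\gamma_0$ | degrees | 10 | reference value of the published sweeps |
| $\beta$ | per-step increment of $\gamma$ | degrees | 3 | gives $\sim$120-step loops; smaller $\beta$ = larger loops |
| $s$ | integration step length | length/step | 0.12 | reference sweep value; loop size grows with $s$ |
| $b$ | backward factor | — | 0.2 | returning regime; $b=0$ never returns; must be $< 1$, may be negative |
| $f$ | perturbation scale | length | 0 | noiseless by default; 0.02–0.1 in the sweeps, up to 0.6 in the fitted presets |
| $n$ | steps per perturbation block | steps | 3 | fine-tuning parameter of the noise smoothness |
| $(x_0, y_0)$ | initial position | length | (0.01, 0) | the origin itself is a coordinate singularity; see below |
| `n_steps` | run length | steps | 5000 | $\ge 10$ loops at the defaults; recordings were time-limited, a step count is a free choice |

Angles are handled in **degrees** throughout the user interface ($\alpha =
10$, $\beta = 3$ reproduce the published loop scale) and converted to
radians only inside the trigonometric evaluations; $\gamma$ is wrapped
into $[0^\circ, 360^\circ)$, which is mathematically inert. The initial
position is a free knob because the model never states one; the dynamics
contract onto a limit cycle, and the tests verify that loop maxima from
the third loop onward agree to $10^{-4}$ relative across $|u_0| \in
[0.001, 0.05]$. An exact hit of the origin raises an error (the azimuth is
undefined there); arbitrarily small positive radii are integrated through,
which the $b$ term makes a non-issue in practice.

## Random perturbations

Unsystematic path-integration error is modelled as a blockwise Gaussian
displacement. Per block of $n$ steps exactly two standard-normal numbers
$\psi_k, \psi_{k+1}$ are drawn (x-component first) forming
$\mathbf{p} = (f\psi_k, f\psi_{k+1})$, and during the block the perturbed
position is

$$\mathbf{u}' = \mathbf{u} + \sin\!\big(i\pi/(n+1)\big)\,\mathbf{p},
\qquad i = 1,\dots,n,$$

so each block is a transient excursion that swells and fades. Blocks tile
the run back to back. The envelope is evaluated at the folded index
$\min(i, n+1-i)$ — mathematically identical (supplementary angles share a
sine) but bit-exactly symmetric in floating point.

**Feedback semantics.** The source equations define $\mathbf{u}'$ but not
whether it replaces the state. The package's default
(`perturbation_mode = "transient"`) keeps the accumulated state
noiseless-additive while evaluating the step's direction vectors and the
$1/r$ turning at the perturbed $\mathbf{u}'$; the recorded and analysed
path is $\mathbf{u}'$. This choice makes the noise genuinely alter the
turning — perturbed loops grow or shrink without any change to $s$ or
$\beta$ — while honouring the transient envelope. A display-only offset
would not change loop sizes at all, contradicting the intended effect.
The alternative reading, $\mathbf{u} \leftarrow \mathbf{u}'$ permanently,
is available as `perturbation_mode = "persistent"`; it accumulates noise
like a random walk and breaks loops substantially harder (loop-maxima
coefficient of variation $\approx 0.29$ versus $\approx 0.10$ at
$f = 0.1$ on otherwise default parameters). Both modes reduce *bit
exactly* to the noiseless simulator at $f = 0$, and a fixed seed
reproduces a run bit for bit.

## Parameter schedules

To mimic searches that expand in their later stages, `beta` and `b` can
be ramped linearly in the step index (`param_schedule()`,
`simulate_scheduled()`): the value used for the step leaving the state at
time $t$ is the interpolant at $t$, so the stated start value is the
first one used. Linear-in-step is the simplest continuous ramp matching
two stated endpoints; nothing in the modelled behaviour constrains the
shape beyond monotonicity. Ramping $\beta$ from 3 to 1.8 produces
strictly increasing loop maxima; adding a $b$ ramp from 0.08 to $-0.03$
additionally produces strictly increasing loop minima (the path stops
re-centring exactly and the whole pattern lifts off the origin). The
shipped `fig7-left`/`fig7-right` presets carry these ramps; the left
variant holds $b$ constant at 0.08, the starting value of the right
variant, since no other value is stated for it.

## Trajectory analytics

* **Smoothing** (`smooth_trajectory()`): a centred moving average of five
  successive positions, applied to output only. Averaging coordinates
  cannot increase the maximum distance from the origin (convexity), but it
  *can* reduce a minimum — points on opposite sides of the origin average
  toward it — which is why loop detection operates on the smoothed series
  consistently rather than mixing raw and smoothed quantities.
* **Distance series** (`distance_series()`): $r(t)$ of the perturbed
  path, the standard comparison device between simulated and recorded
  searches.
* **Loop segmentation** (`segment_loops()`): a return to the origin is
  never exact in a sampled, noisy path, so it is operationalised as a dip
  of the smoothed $r$ below `return_threshold` (default 0.2) times the
  *running* maximum of $r$ — running, not global, so that growing
  searches still register their early returns. One event is reported per
  maximal below-threshold excursion, at the sample where $r$ is smallest.
  This "per-excursion" rule, rather than per-local-minimum with a small
  dead time, is deliberate: a noiseless return passage at the default
  parameters spends $\sim$15 steps near the origin and wiggles through
  micro-minima $\sim$7 samples apart, which a fixed 5-sample dead time
  does not suppress; counting excursions does, by construction. A
  trailing excursion cut off by the end of the series is not counted as a
  return (the path never demonstrably turned back outward), which is also
  what the closed-form check demands: $|\sin(t/20)|$ sampled on
  $0..500$ has exactly 7 zeros in $(0, 500]$ and must yield exactly 7
  loops. Loop $k$ spans from return $k-1$ (or the series start) to return
  $k$; per-loop maxima and the $r$ value at each return (the loop minima)
  are reported.

### The threshold and the $b = 0$ transient

The 0.2 threshold is validated against the noiseless regimes: at
$b = 0.2$ the simulator produces one return per loop ($\approx 41$ in
5000 steps), and at $b = 0$ returns cease — but not instantly. Started
near the origin, the $b = 0$ pattern drifts outward with relative loop
minima rising through the 0.2 line only around step 450; three transient
events (near steps 205, 326 and 446, at running-max ratios 0.121–0.197)
occur before that, robustly across initial positions in $[0.001, 0.05]$
and cross-checked by the polar oracle. A package check that expects zero
events already after step 200 therefore fails by exactly these three
transient events, and is kept failing rather than silently re-dated; after
step 500 the count is zero.

## What the synthetic world does and does not establish

Everything this package simulates *is* the model: there is no external
data, and the recorded ant searches the model was originally matched to
are not published. Green tests therefore establish internal properties —
frame equivalence, exact noiseless reduction, seed determinism, symmetry
and monotonicity of the loop regimes, and the statistical contract of the
noise — and that the nine published parameter sets produce origin-returning
searches under this implementation. They do **not** establish behavioural
goodness-of-fit to real *C. fortis* trajectories, which in the source
study was assessed visually; no statistical comparison to recorded tracks
is attempted or possible here. Real searches also contain features the
model deliberately omits: speed variation, directional (systematic)
path-integration error, landmark and olfactory guidance, and any
interaction with the preceding foraging excursion.

## Known limitations

* The per-loop statistics inherit the segmentation's threshold; loop
  counts for pathological series (e.g. noise-dominated runs such as the
  smallest-step preset, where $f \gg$ pattern scale) are best read as
  "below-threshold excursions", not biological loops.
* Schedules are linear in the step index only; no state-dependent
  (e.g. $r$-triggered) scheduling.
* The integrator is explicit first-order by definition of the model —
  the step *is* the model, not a discretisation of an ODE — so no
  higher-order scheme is applicable.
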