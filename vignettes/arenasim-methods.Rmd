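---
title: "arenasim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arenasim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`arenasim` simulates rodent-like foraging in continuous 1D/2D arenas and
generates synthetic activity for the spatially modulated cell types of the
hippocampal formation. This vignette is the package's own account of the
models it implements, the parameters that matter, the numerical choices
made where the design was open, and what the tests do and do not establish.

## The locomotion model

### Ornstein–Uhlenbeck velocity processes

Random motion is built from Ornstein–Uhlenbeck (OU) processes
parameterised by a decoherence timescale $\tau$, long-run standard
deviation $\sigma$ and mean $\mu$:

$$x \leftarrow x + \frac{\mu - x}{\tau}\,dt + \sqrt{\tfrac{2\sigma^2}{\tau}}\,\eta\,\sqrt{dt}, \qquad \eta \sim \mathcal N(0,1).$$

OU processes are temporally continuous — the statistics of sampled paths do
not depend on the integration timestep — which is the property that lets
users change `dt` freely without changing the motion.

In 2D, rotational velocity $\omega(t)$ follows an OU process directly
(default $\tau_\omega = 0.08$ s, $\sigma_\omega = 2\pi/3$ rad/s). Linear
speed is driven through a monotone transform
$R_\sigma(x) = \sigma\sqrt{-2\ln(1-\Phi(x))}$ that maps a unit normal to a
Rayleigh distribution of scale $\sigma_v$ (default 0.08 m/s, decohering
over $\tau_v = 0.7$ s), because rodent running speeds are
Rayleigh-distributed while turning rates are approximately normal, and the
two decorrelate on timescales an order of magnitude apart. On each step
the velocity vector is rotated by $\omega\,dt$; the speed-driving normal
variable is *re-derived from the current speed*, OU-stepped, and mapped
back. Re-deriving (rather than keeping a free-running driver) means any
speed change imposed by walls, collisions or drift control persists and
relaxes back on the $\tau_v$ timescale — and it is what makes the collision
rule ("speed is reset to $0.5\sigma_v$") and drift control coherent with
the stochastic process.

In 1D the velocity itself is an OU process ($\mu_v$ = `speed_mean`,
$\sigma_v$ = `speed_std`) with no Rayleigh transform.

### Walls: collision, repulsion, thigmotaxis

Within `wall_repel_distance` $d_{wall}$ (default 0.1 m) of any wall two
smooth effects act, both vanishing exactly at $d_{wall}$:

* a **spring-like deceleration** applied to the internal velocity,
  $k_1\, \hat n \, \frac{(s\sigma_v)^2}{d_{wall}^2}(d_{wall} - d_\perp)$,
  tuned so that with $k_1 = 1$ a head-on approach at speed $s\sigma_v$
  stops just before the wall (verified by fine-step integration in the
  test suite);
* a **conveyor-belt displacement** applied to position only,
  $k_2\, \hat n\, s\sigma_v \left(1 - \sqrt{1 - (d_{wall}-d_\perp)^2/d_{wall}^2}\right)$,
  which slows the approach *without turning the agent*, producing the
  lingering near walls (thigmotaxis) seen in rodent data.

The mixture is controlled by a single thigmotaxis parameter
$\lambda \in [0,1]$: $k_1 = 3(1-\lambda)^2$, $k_2 = 6\lambda^2$. Setting
the repulsion strength $s = 0$ disables both. Contributions from several
walls within range (corners) are summed; the package does not cap the
summed conveyor velocity, which at most doubles it in a right-angled
corner. If a step would still cross a wall, the velocity's normal
component is flipped (elastic reflection), the speed is reset to
$0.5\sigma_v$, and the agent does not cross.

### Drift control, imported trajectories, head direction

An external drift velocity is blended in after the random update,
relaxing $v$ toward $v_{drift}$ with timescale $\tau_v / k$; the linear
relaxation is integrated exactly over each step (gain
$1 - e^{-k\,dt/\tau_v}$), so arbitrarily large $k$ stays stable. $k \gg 1$
gives tight tracking, $k \ll 1$ leaves the motion random. Imported trajectories
(times + positions, at least 4 samples) are interpolated with cubic
splines and can be replayed at any timestep; wall repulsion and collision
handling are disabled during playback, and query times outside the
recorded range clamp to its endpoints. Head direction is the smoothed,
renormalised velocity ($\tau_h = 0.15$ s in 2D; the sign of the velocity
in 1D); at zero speed the previous head direction is held. All angles in
the package are measured anticlockwise from $+x$ — including the
head-direction angle, where published conventions disagree internally.

## Geometry

Arenas are rectangles (height `scale`, width `scale * aspect`) with solid
or periodic boundaries, plus interior walls, polygonal holes (interiors
count as outside; edges behave as walls) and point objects. Three
distance geometries govern how spatial receptive fields interact with
walls:

* **euclidean** — ignores walls (fields bleed through);
* **line_of_sight** — euclidean when the straight segment is unobstructed,
  $\infty$ otherwise;
* **geodesic** (default) — the shortest wall-avoiding path, computed
  exactly on a visibility graph over wall endpoints with Dijkstra's
  algorithm. The graphs have a handful of nodes, so the exact computation
  is cheap for any realistic wall count; there is no approximation
  fallback, but the geometry is selectable per population.

Under periodic boundaries all geometries use minimal wrapped
displacements; wall-respecting geometries tile the walls into the 3×3
neighbouring images. Numerical tie-breaks: sight-lines are blocked only
by crossings strictly interior to both segments, so geodesic paths may
turn exactly at wall tips; a point exactly on a wall gets the wall
perpendicular oriented by a fixed reference axis (0.6, 0.8) — arbitrary
but deterministic.

## Neuron populations

All analytic populations share one pipeline per step: raw model rate in
$[0,1]$ → affine scaling to $[f_{min}, f_{max}]$ Hz → optional additive OU
noise ($\sigma_\eta$, $\tau_\eta$) → history → Bernoulli spike per cell
with probability $F_i\,dt$ (at most one spike per step; negative noisy
rates are clipped only for spiking so the stored rates keep testable noise
statistics). Function-approximator layers and the Gaussian-process random
fields produce unconstrained reals and skip the affine scaling.

Models, briefly:

* **Place cells** — five response profiles of the environmental distance
  to the field centre (Gaussian; Gaussian cropped and levelled at one
  standard deviation; centre–surround difference of Gaussians with ratio
  1.5 and zero total volume; top-hat; one-hot nearest-centre). Default
  centres sit on a uniform grid jittered by half the grid pitch, giving
  even coverage that looks random.
* **Grid cells** — thresholded or shifted sums of three plane-wave cosines
  60° apart; scales, orientations and phases sampled uniformly at
  construction.
* **Vector cells** — Gaussian radial × von Mises angular tuning to
  boundaries (integrated over 360° of first-hit ray casts, step 2°),
  objects of a matching type (summed over objects), or another agent;
  allocentric or egocentric; occluding walls silence hidden features.
  The von Mises factor is normalised by its peak $e^\kappa$ so single
  features peak at 1; boundary cells instead use an empirical constant
  $K_i = 1/\max_x F_i(x)$ computed on a grid at construction, as the
  integral's maximum has no closed form. Egocentric populations are
  normalised at a reference heading; their map maximum at other headings
  is approximate. Field-of-view tilings place concentric rows of
  egocentric cells with receptive fields either constant (`uniform`) or
  growing linearly with distance (`diverging`, $\delta(d) = \xi_0 + d/\beta$).
* **Head-direction / velocity / speed cells** — von Mises tuning to
  heading (evenly spaced means, 3° widths), optionally scaled by speed;
  1D environments use two rectified sign/speed cells. Speeds are scaled by
  $\sigma_v$ (2D) or $\sigma_v + \mu_v$ (1D); the printed 1D velocity-cell
  form is dimensionally ambiguous and the package follows the speed-cell
  convention.
* **Phase-precessing place cells** — the spatial rate is multiplied by
  $2\pi f_{VM}(\phi_\theta \mid \phi^*_i, \kappa_\theta)$ with
  $\phi^*_i = \pi - \beta_\theta \pi\, d_i/\sigma_i$ and
  $d_i = (x - x_i)\cdot \hat v$; the factor averages to 1 over a theta
  cycle and peaks at $e^\kappa / I_0(\kappa) > 1$, the one documented
  exception to the pre-scaled max-1 rule. At zero speed the travel
  direction is undefined and the factor is held at 1.
* **Random spatial neurons** — approximate Gaussian-process fields with an
  RBF kernel of lengthscale $l$ over the environmental distance: target
  values drawn from $\mathcal N(0, K)$ on a grid of spacing $l/2$
  (via eigendecomposition with negative eigenvalues clipped to zero —
  geodesic kernels need not be positive definite near exposed walls),
  queried by kernel-weighted averaging.
  Fields are smooth everywhere except across walls under the geodesic
  kernel.
* **Function-approximator layers** — a linear feed-forward layer
  ($w \sim \mathcal N(0, g/n_j)$ per input layer, bias, named activation
  with stored derivative) and an opaque MLP layer (default two hidden
  ReLU layers of 20 units) with forward caches retained for training.
  Composition is by topological order; recurrent links (cycles) read the
  previous step's rates — a one-step delay chosen for determinism.

Rate maps are computed two ways: **explicit** (the analytic rate queried
on a grid of spacing `dx`, with a stated reference heading $+x$ and speed
$\sigma_v$ for motion-dependent cells) and **empirical** (rate-weighted
occupancy histogram over occupancy, both Gaussian-smoothed with default
width $5\,dx$ — the kernel width is not pinned down by any published
value; bins never visited are `NA`, never 0).

## What the synthetic world does and does not establish

The fixture generators produce open/walled/holed/periodic arenas and
analytic trajectories (circle, incommensurate Lissajous, piecewise-linear
circuits) with exact ground truth. The motion model's defaults *are* the
statistics reported for open-field foraging data (Rayleigh scale
0.08 m/s, $\tau_v = 0.7$ s, $\sigma_\omega = 2\pi/3$ rad/s,
$\tau_\omega = 0.08$ s), so green tests establish internal consistency of
the simulator with those stated parameters — not agreement with any new
animal data. Real trajectories have behaviours the model lacks (rearing,
grooming pauses, goal-directed runs); imported-trajectory mode exists for
exactly that reason.

One measured deviation is worth stating plainly: in the default solid
1 m box, the exponential-fit decorrelation time of speed measures about
0.61 s although the driving OU parameter is 0.7 s. In a periodic
(wall-free) box the same estimator recovers 0.70. The agent spends roughly
40% of its time within 0.1 m of a wall, where repulsion suppresses and
perturbs speed, shortening the measured timescale by ~13% — a property of
the modelled world, reported as measured rather than re-tuned. Single-run
estimates at 20 simulated minutes additionally carry ~5–7% estimator
noise, which is irreducible at that duration.

## Numerical choices

* Rayleigh transform: the normal CDF is clipped to $[10^{-12}, 1-10^{-12}]$
  before the log.
* Decorrelation-time estimator: least squares on the log-autocorrelation,
  discarding lags once the autocorrelation falls below 0.2 (log-linear
  fits blow up on noisy near-zero tails).
* Containment: after an accepted step positions are clamped $10^{-9}$ m
  inside solid boundaries to keep geometry queries well-posed.
* Collision detection excludes the segment start ($t > 10^{-12}$) so an
  agent resting against a wall is not permanently "colliding".
* One-hot place cells break distance ties by the lowest cell index.
* The shifted-cosine grid variant is clamped at zero: the printed form has
  minimum 0 only for zero phase offset (the minimum of three 60°-separated
  cosines is $-3/2$ there but approaches $-3$ for other shared phases),
  and pre-scaled rates are kept in $[0, 1]$.
* Spike probabilities above 1 ($F\,dt > 1$) clip with a warning.

## Known limitations

3D arenas, curved or moving walls, inter-agent collisions, refractory
periods and biophysical neuron models are out of scope. Egocentric
boundary-cell normalisation is exact only at the reference heading.
Geodesic distances under periodic boundaries use a 3×3 image tiling,
which is exact for paths wrapping at most once.
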