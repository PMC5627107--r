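---
title: "Fokker-Planck Nash games for pedestrian avoidance: models and numerics"
author: "fpnash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fokker-Planck Nash games for pedestrian avoidance: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpnash)
```

## The model

Two pedestrians move in a convex room $\Omega \subset \mathbb{R}^2$ with
reflecting walls over a horizon $[0, T]$. Each position $X^{(p)}(t)$ is a
controlled diffusion
$$ dX^{(p)} = \bigl(v^{(p)} + u^{(p)}(t)\bigr)\,dt + \sigma\,dB^{(p)}, \qquad
   X^{(p)}(0) \sim f_0^{(p)}, $$
with a constant base velocity $v^{(p)}$ pointing from the departure point
$D^{(p)}$ to the arrival point $A^{(p)}$ (by default $v = (A - D)/T$), a
purely time-dependent avoidance strategy $u^{(p)}(t)$, and Brownian dispersal
with constant $\sigma$ modelling gait variability. The position uncertainty
is carried by the probability density $f^{(p)}(x, t)$, which solves the
Fokker-Planck (forward Kolmogorov) equation
$$ \partial_t f - \tfrac{\sigma^2}{2}\Delta f + \nabla\cdot\bigl(b\,f\bigr)
   = 0, \qquad b = v + u(t), $$
with zero-flux boundary conditions $F \cdot n = 0$ matching the reflecting
barriers, and a Gaussian initial density
$\hat{C}\exp(-|x - D|^2 / w)$, $w = 0.5$, centered at the departure point.
(This is the standard isotropic form; a variant with a minus sign between
the two squared terms circulates in transcriptions but is not normalizable
off a bounded box, so the isotropic reading is used throughout.)

Each player $p$ minimizes
$$ J_p = \alpha \int_\Omega |x - A^{(p)}|^2 f^{(p)}(x, T)\,dx
   + \tfrac{\nu}{2}\|u^{(p)}\|^2_{H^1(0,T)}
   + \rho \int_0^T\!\!\int_\Omega f^{(1)} f^{(2)}\,dx\,dt , $$
a terminal benefit pulling the final density to the arrival point, an $H^1$
control cost enforcing bounded, slowly varying strategies with
$u(0) = u(T) = 0$, and a collision cost: for a small overcrowding radius
$r$, the probability that the two independent walkers are within distance
$r$ is approximately $r^2 \int f^{(1)} f^{(2)} dx$, and $\rho = C r^2$
absorbs the radius and the interaction strength. Because the interaction is
symmetric, the game is separable: minimizers of the composite functional
$$ \hat{J} = G_1(u^{(1)}) + G_2(u^{(2)}) + W(u^{(1)}, u^{(2)}) $$
(with $G_p$ the terminal-plus-control part and $W$ the shared collision
cost) are Nash equilibria — no player can improve by deviating alone. The
package therefore minimizes $\hat J$ jointly over both controls and then
*certifies* the equilibrium property directly by random unilateral
deviations (`verify_nash()`).

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\alpha$ | terminal weight | 100 | benchmark value |
| $\nu$ | control-cost weight | 1 | benchmark value |
| $\rho$ | interaction strength | 0.01 (low) / 150 or 200 (high) | per scenario |
| $\sigma$ | dispersal (length/$\sqrt{\text{time}}$) | 0.1 | see below |
| $w$ | initial-density width | 0.5 | per-axis variance $w/2$ |
| $u_a, u_b$ | control box | $\pm 5$ ($\pm 40$ short-horizon case) | bounds are inactive on long horizons |

The dispersal $\sigma$ is not fixed by the benchmark descriptions. We use
0.1 model length units (the domains are room-scale, in metres): over the
benchmark horizons this keeps the accumulated stochastic spread
($\sigma^2 T \le 0.05$) well below the initial position uncertainty
($w/2 = 0.25$), so the densities remain coherent blobs whose mean
trajectories carry the dynamics, as in the experiments the scenarios mirror.
Larger $\sigma$ progressively couples the terminal cost to the walls
through the variance term (see "Wall effects" below), which the benchmark
trajectories do not exhibit.

## Discretization

Space is a uniform cell-centered $50\times50$ tensor grid (the benchmark
resolution); all spatial integrals are midpoint sums, which pair exactly
with the finite-volume fluxes. Time uses $M = 50$ implicit steps with
controls living on the $M + 1$ nodes; each step takes the control at its
right node, and time integrals use the trapezoid rule.

**Drift-decomposed transport.** The two parts of the drift are advanced
separately:

* the constant base drift $v$ is a pure translation, applied *exactly*: the
  per-step displacement $v\,\Delta t/h$ accumulates in a fractional phase,
  integer parts move the stored field whole cells (mass crossing a wall is
  mirror-folded back inside, the discrete form of reflection), and the
  remaining fraction is rendered at output nodes by a conservative two-point
  blend, which is exact for the mean;
* diffusion and the control drift $u(t)$ use Chang-Cooper/
  Scharfetter-Gummel exponentially fitted finite-volume fluxes with
  implicit Euler and dimensional splitting. Writing
  $B(w) = w/(e^w - 1)$, the face coefficients $(D/h)B(\pm w)$ with
  $w = u h/D$ are nonnegative, so every step matrix is an M-matrix with
  unit column sums: positivity and exact unit mass hold unconditionally,
  for any control and any step size.

A monotone linear scheme that carries the *full* drift cannot avoid
$O(|b| h/2)$ of along-path numerical diffusion (the order barrier for
positive advection schemes). At the benchmark resolutions this inflates the
terminal variance severalfold (for the short-horizon diagonal crossing,
$|v| \approx 21$ and $h = 0.4$ give a numerical variance of about 6 versus
a physical 0.26), and the optimizer then exploits the artificially widened
density through the wall interaction. Decomposing the transport removes
this artifact at its source while keeping linearity, conservation,
positivity and the benchmark grid sizes.

**Discrete adjoint.** Gradients are assembled by the discretize-then-
optimize route: the backward recursion applies the exact transposes of
every forward operator (implicit sweeps, integer shifts, rendering), and
the control derivative enters through the analytic derivative
$B'(w)$ of the fitted fluxes. The resulting gradient matches central finite
differences of the cost to about $10^{-9}$ relative error (tested); the
continuous counterpart of the coupling term is
$-\int_\Omega (\partial p/\partial x_k) f\,dx$ with $p$ the adjoint state
solving the backward transport-diffusion equation with terminal data
$-\alpha|x - A|^2$. With trapezoid time quadrature of the interaction, the
discrete terminal adjoint additionally carries the endpoint weight
$-\rho(\Delta t/2) f^{(-p)}(\cdot, T)$; it equals $-\alpha V$ exactly when
$\rho = 0$.

**Optimization.** Projected gradient descent on $\hat J$ over both controls
jointly, from $u \equiv 0$: the $L^2$ gradient
$\nu u - \nu u'' - \int (\partial p/\partial x_k) f\,dx$ is lifted to its
$H^1$ representative by solving $-w'' + w = g$, $w(0) = w(T) = 0$
(a tridiagonal solve), giving smooth, endpoint-vanishing updates; steps are
chosen by Armijo backtracking (initial step 1, shrink 0.5, slope $10^{-4}$,
at most 30 backtracks) with the previous accepted step doubled as the next
trial; iteration stops when the $H^1$ norm of the smoothed gradient falls
below $10^{-5}(1 + |\hat J|)$ or after `max_iters` (default 200)
iterations. Box constraints are enforced by componentwise clipping with
pinned endpoints; accepted steps decrease $\hat J$ monotonically.

## Monte Carlo cross-validation

`simulate_ensemble()` integrates the particle dynamics by Euler-Maruyama
with coordinate-wise folding reflection (mirror the overshoot back inside,
repeated as needed — valid for arbitrary step lengths), initial positions
rejection-sampled from the initial Gaussian, and the control interpolated
linearly to the step midpoint. The midpoint choice makes the cumulative
deterministic displacement telescope to the same value the density solver
produces (both endpoints of the control are pinned to zero), so ensemble
means and density means are directly comparable: `compare_to_fp()` checks
agreement within three standard errors at every time node and also reports
cell-histogram total-variation distances.

## Wall effects, multiple equilibria, and the corridor case

The terminal benefit is an expectation, so it decomposes into a
mean-offset part and a variance part. In free space the variance is
control-independent (a time-dependent drift only translates the density)
and the optimal low-interaction strategies are essentially zero — the base
drift already reaches the target. Near a reflecting wall this decoupling
breaks: pressing the density against a wall *compresses* it, and because
folding is irreversible the compression persists, so sufficiently cheap
controls can lower the terminal variance by wall contact. Whether this
channel matters is a property of the benchmark geometry, measured in units of
the terminal spread (standard deviation $\approx 0.52$ at $\sigma = 0.1$):

* oblique crossing (walls $\ge 3.6$ sd from the arrival points) and the
  short-horizon diagonal crossing ($\ge 4$ sd): the channel is numerically
  invisible; the solver converges to (exactly) zero controls and the mean
  trajectories meet at the benchmark times;
* the 135-degree crossing (walls $\approx 2$ sd): a weak tail interaction
  adds controls of size $\approx 0.02$ and leaves the meeting time within
  one step of the benchmark value;
* the corridor case, Turnwald 1C-B2 ($[-1,1]\times[-3,3]$, arrival points
  0.5 = 1 sd from the walls, one departure density already touching a side
  wall): the channel is strong. Deep minimization of $\hat J$ sends both
  means on wall-hugging detours that compress their densities against the
  corridor sides before heading to their targets; the equilibrium mean
  trajectories then separate by over one length unit and no longer meet.
  This is a genuine (and, to our knowledge, previously unreported) feature
  of this cost functional in tight geometries, not a numerical artifact:
  the benchmark's near-straight corridor trajectories correspond to an early
  stage of the descent, before the compression valley is entered, and the
  reference meeting time for this case is reproduced by such shallow solves
  but not by the converged equilibrium. The package reports whatever the
  requested iteration budget yields, flags non-convergence, and the
  shipped tests document the discrepancy rather than masking it.

## Symmetry, saddles, and when avoidance pays

The benchmark crossings are mirror-symmetric (swap the players and reflect
an axis), and gradient descent from $u = 0$ preserves that symmetry — but
within the symmetric strategy subspace the inter-mean distance *must* cross
zero (the relative coordinate changes sign continuously), so genuine
avoidance always requires symmetry breaking. Whether a broken-symmetry
deviation is profitable is a quantitative question: the entire collision
cost available to be saved is $W = \rho\int\!\!\int f^{(1)}f^{(2)}$, while
a dodge of one blob width $s$ within the crossing window costs control
effort dominated by the $\tfrac{\nu}{2}\int |u'|^2$ term. On the short
horizon $T = 1$ of the diagonal crossing this penalty is decisive: at
$\rho = 200$ the total collision cost is $W \approx 3.6$, while the
cheapest effective speed-up/slow-down profile costs upwards of 40 (direct
evaluation in the tests). The certified equilibrium there is therefore the
*symmetric crossing* — the players accept the overlap. The only interaction
response that survives is a minute symmetric speed-up through the
encounter, which shortens the co-location window and shifts the discrete
crossing slightly off a time node; it raises the minimal inter-mean
distance only at the $10^{-5}$ scale, not to any macroscopic avoidance. On
the longer horizons the economics reverse and avoidance emerges
— quickly where the geometry is already asymmetric (the 135-degree
crossing), slowly for the most symmetric cases, where descent must first
amplify rounding-level asymmetries.

A related consequence of wall-induced non-convexity is non-uniqueness:
mirror-symmetric games (the diagonal crossing is invariant under swapping
the players and reflecting one axis) have symmetry-related equilibria, and
the computed solution inherits the symmetry only up to the optimizer's
tolerance. The tests check the symmetry property explicitly.

## Shipped problem sizes

All benchmark computations use the reference $50\times50\times50$
resolution. The shipped verification budgets are 150 projected-gradient
iterations for the low-interaction solves, 80 for the high-interaction
avoidance runs, 500 for the deep equilibrium used by the certificate of the
135-degree crossing, $10^4$ particles for the Monte Carlo cross-checks, and
an $8\times8\times8$ grid for the finite-difference gradient oracle; these
choices keep the full suite reproducible on a single CPU while leaving each
conclusion insensitive to the budget (the gradient check is
resolution-independent by construction, and the meeting times are stable
from roughly half the budgets onward).

## Known limitations

* Only two players are implemented end to end, matching the benchmark
  games; the cost and solver structure extend to more players but no such
  configuration is exercised.
* $\sigma$ is constant (no state- or time-dependent dispersal), boundaries
  are reflecting only, and controls are open-loop: both players commit to
  strategies at $t = 0$ with complete information and never react
  mid-course. Scenarios with continuous mutual observation are dynamic
  games outside this model class, and the corridor discussion above shows
  the cost functional itself can favour wall-exploiting equilibria in
  tight domains.
* The synthetic scenarios emulate the benchmark *geometry* (departures,
  arrivals, drifts, horizons), not empirical trajectory data; passing tests
  show the solver reproduces the model's predictions, not that the model
  fits any particular pedestrian recording.
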