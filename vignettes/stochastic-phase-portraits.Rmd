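---
title: "Methods: stochastic phase portraits for reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic phase portraits for reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spportraits)
```

## The model

A chemical reaction network over species $X_1,\dots,X_k$ consists of $m$
reactions with reactant stoichiometries $\sigma_{ij}$, product
stoichiometries $\rho_{ij}$ and rate constants $\mu_j$. On molecule counts
$n_i$, the dynamics is the usual continuous-time Markov jump process of the
chemical master equation: reaction $j$ fires with total rate
$N\,\nu_j(\mathbf n)$, where $N$ is the system size (reactor volume) and

$$\nu_j(\mathbf n) = \mu_j \prod_z N^{-\sigma_{zj}}
  \frac{n_z!}{(n_z - \sigma_{zj})!}$$

is the propensity: the rate constant times the combinatorial factor for the
reactant molecules to meet. Firing updates $\mathbf n \mapsto \mathbf n +
S_{\cdot j}$ with the stoichiometric matrix $S = \rho - \sigma$.

On concentrations $x_i = n_i/N$, truncating the Kramers–Moyal expansion at
second order yields the Fokker–Planck equation with drift and diffusion

$$\mathbf f(\mathbf x) = S\,\nu(\mathbf x N), \qquad
  D(\mathbf x) = S\,\mathrm{diag}(\nu)\,S^\top .$$

Writing the equation as a continuity equation
$\partial_t p = -\nabla\!\cdot\mathbf j$ splits the probability current into
a *convective* and a *diffusive* part,

$$\mathbf j = \underbrace{\boldsymbol\alpha(\mathbf x)\,p}_{\text{convective}}
  - \tfrac{1}{2N} D\,\nabla p, \qquad
  \alpha_i(\mathbf x) = f_i(\mathbf x)
  - \tfrac{1}{2N}\sum_k \partial_{x_k} D_{ik}(\mathbf x).$$

The *stochastic phase portrait* is the ordinary phase portrait of
$\dot{\mathbf x} = \boldsymbol\alpha(\mathbf x)$. At a point where both
$\nabla p = 0$ and $\mathbf j = 0$, necessarily $\boldsymbol\alpha = 0$, and
the Hessian of the stationary density is $2N p\, D^{-1} J_s$ with
$(J_s)_{ik} = \partial \alpha_i / \partial x_k$: since $D$ is positive
definite there, *stable* fixed points of $\boldsymbol\alpha$ are *favorable
states* (density maxima) and unstable ones are unfavorable (minima).
Portraits of $\boldsymbol\alpha$ therefore expose stochastic
(phenomenological) bifurcations — changes in the number, kind or position of
density extrema as rates or $N$ vary — without solving any partial
differential equation.

Two caveats are inherited from the theory and shape the package design.
First, a density maximum with $\mathbf j \neq 0$ (a *slow transient state*
on a probability ridge around a limit cycle) is not a fixed point of
$\boldsymbol\alpha$; it is indicated instead by speed minima of
$\|\boldsymbol\alpha\|$ along a detected cycle. Second, the converse
implication ($\boldsymbol\alpha=0$ at a point that is *not* an extremum)
cannot be excluded in general; fixed points therefore carry a
`favorable_candidate` flag, and confirmation is delegated to exact
stochastic simulation (`ssa_simulate()`), mirroring how the method is meant
to be used.

## Symbolic fields

Propensities of mass-action networks, written in concentrations, are
polynomials — the falling factorial becomes
$\prod_{l=0}^{\sigma-1}(x_z - l/N)$, retaining the finite-size factors such
as $x(x-1/N)$ for binary self-interaction — and rate "constants" may be
rational functions of the concentrations (e.g. the Holling type-II factor
$d/(1+Ax)$). All field quantities are therefore built once as exact R
expressions and differentiated with `stats::D`: the divergence in
$\boldsymbol\alpha$ and the Jacobians used by the root finder and classifier
are exact, not numerical. A finite-difference policy (central differences,
step $\varepsilon^{1/3}(1+|x|)$) is available for black-box fields and is
tested to agree to $10^{-6}$ relative.

Because no computer-algebra system ships with the R stack used here,
"symbolic identity" between a mechanically derived field and a hand-derived
closed form is established by randomized polynomial identity testing
(`expr_equivalent()`): agreement at 200 random points in all variables
including parameters, at $10^{-9}$ relative tolerance. For polynomial and
rational identities this is sound except on a set of vanishing probability
(Schwartz–Zippel), and it is how the flagship regression — the mechanically
derived convective field of the foraging-colony model equals
$(\epsilon - r/N)(x_2-x_1)\,(1,-1)^\top$ — is asserted.

The theory asserts a positive-definite $D$; for networks whose stoichiometric
columns do not span the species space, and on boundary faces where
propensities vanish, $D$ can be singular. The tests therefore check positive
*semi*-definiteness (eigenvalues $\ge -10^{-12}$) on domain grids, which is
the guarantee degenerate cases actually admit.

## Portrait machinery and numerical choices

* **Root finding** (`find_fixed_points()`): damped Newton with backtracking
  line search from a deterministic multistart (regular grid plus seeded
  jitter), using the exact Jacobian. Singular Jacobians fall back to an SVD
  pseudo-inverse step, which is what lets fixed-point *lines*
  (conservation-law models) converge; the classifier then reports
  `marginal/manifold` for eigenvalues with $|\mathrm{Re}\,\lambda| <
  10^{-8}\max|\lambda|$ rather than guessing stability of a structurally
  zero mode. Roots are accepted at $\|\boldsymbol\alpha\\| < 10^{-9}$ and
  merged within $10^{-6}\times$ the domain diagonal. The converged root set
  is tested to be invariant under doubling the number of starts and changing
  the seed.
* **Nullclines** (`nullclines()`): marching squares
  (`grDevices::contourLines`) on a sampled grid, default 256 points/axis.
  The contour level is shifted by $10^{-9}\max|z|$ because the contouring
  algorithm misplaces segments when the level exactly coincides with grid
  values (common here: components vanish identically on boundary faces);
  the induced polyline displacement is $O(10^{-9}/\|\nabla z\|)$.
* **Trajectories** (`integrate_trajectory()`): adaptive Dormand–Prince 5(4)
  with PI-free step control (no suitable ODE solver is guaranteed in the
  target environment). The flow is clipped to the non-negative orthant by
  projecting outward-pointing components to zero on boundary faces — this
  reproduces the mechanism by which probability "slides" along an axis into
  a boundary maximum.
* **Limit cycles** (`detect_limit_cycle()`): nearest-return analysis of the
  second half of a path; recurrence is measured against path *segments* so
  the tolerance (default $10^{-3}\times$ the segment diameter) is not
  limited by the recording density, and paths whose analysed segment has
  diameter below $10\times$ the tolerance are classified as converged, not
  periodic. The returned speed profile $\|\boldsymbol\alpha\|$ along the
  cycle marks slow-transient-state candidates at its minima.
* **Boundary maxima** (`boundary_maxima()`): on each axis of the quadrant,
  roots of the axis-parallel component of $\boldsymbol\alpha$ restricted to
  the axis (bracketing scan, then `uniroot` to $10^{-12}$), flagged
  `inflow` when the perpendicular component points into the boundary — the
  condition under which a boundary maximum of the stationary density forms.

## Bifurcation detection

Eigenvalue crossings are located by bisection on the leading nonzero real
part of $J_s$ at a fixed point that is re-polished by Newton at every
parameter value (relative tolerance $10^{-6}$ by default; the foraging-colony
crossing reproduces the closed form $r^\* = \epsilon N$ to $10^{-9}$).

The *nullcline-gap bifurcation* — the reversal of the convective flow
through the gap between the nullclines near a boundary, which creates or
destroys a boundary maximum — is defined pictorially in the source material.
The operational event function used here is this package's own
formalization: $g(N) = \alpha_\perp(x^\*(N), 0)$, the perpendicular field
component at the tracked boundary-maximum location, with $x^\*(N)$ the
*largest* axis root (this matches both documented cases, $x\approx 4$ and
$x\approx 9$). $g<0$ means inflow (boundary maximum exists), $g>0$ means
the interior is escape-proof; the critical $N^\*$ is the bisected sign
change. It is validated against the printed bracket $(50, 80)$ for the
stable-parameter predator–prey model — the computed $N^\*\approx 68$ — and
not treated as the source's own formula. For the limit-cycle parameter set
the same criterion lands near $N^\*\approx 65$–$70$; the documentation of
the original figure reads "around 65", and no attempt is made to force
closer agreement since the original criterion (visual inspection vs.
histograms) is unstated.

Nullcline detachment (the interior fixed point disappearing as the nullcline
families cease to intersect) is bisected on interior-root existence; for the
stable parameter set it occurs near $N\approx 31$, inside the documented
range $(10, 35)$, and below the gap bifurcation as expected.

## Validation layers

Predictions are cross-checked by two independent routes:

1. **Exact SSA** (`ssa_simulate()`): direct-method Gillespie sampling of the
   master equation, bitwise reproducible per seed, in pure R (~10 µs/event;
   adequate at desk scale — run lengths in the shipped tests are scaled
   down relative to "one very long run" and say so). Stationary histograms
   are *time*-weighted with half-open bins aligned to multiples of $1/N$, so
   every integer state falls in exactly one bin; modes are strict local
   maxima above a prominence threshold (default 5% of the global maximum),
   optionally after Gaussian smoothing. Histogram-argmax mode locations on
   flat density tops jitter by a bin or two between seeds; mode-location
   assertions are therefore made at a bin width comparable to the reference
   precision (~0.1–0.25 in concentration), which was checked to be stable
   across seeds.
2. **Closed-form 1D density** (`stationary_density_1d()`): in one dimension
   a closed system satisfies detailed balance, giving
   $p_\infty(x) \propto D(x)^{-1} \exp\!\big(2N \int f/D\,dx\big)$, so that
   $\mathrm d\log p/\mathrm dx = 2N\alpha/D$ and density extrema coincide
   exactly with roots of $\alpha$. The exponent is accumulated by cumulative
   trapezoid *in log space* to avoid overflow at large $N$; normalization is
   trapezoidal and verified to $10^{-8}$. Domain edges are reflecting
   (zero-current); an edge with outward-increasing density is reported as an
   edge maximum, which is how the bistable regime of the foraging-colony
   model ($N_C/N > 1$) manifests. Conservation-law models are reduced to 1D
   by exact symbolic substitution (`reduce_by_conservation()`).

## Fixtures and their defaults

* `foraging_colony`: recruitment ($X_1+X_2 \to 2X_1$ and mirror, rate $r$)
  and spontaneous switching (rate $\epsilon$), conserved total
  $x_1+x_2$. The governing ratio is $N_C/N$ with $N_C = r/\epsilon$:
  monostable below 1, bistable (boundary maxima) above. Defaults
  $\epsilon = 0.01$, $N = 1000$ follow the documented 1D solution setting;
  the default $r = 7.5$ picks the monostable case $N_C/N = 0.75$ of that
  figure. These are not sweep knobs; tests vary them explicitly.
* `rosenzweig_macarthur`: logistic prey growth, Holling type-II predation,
  predator death, and small immigration ($q = 0.01$) kept in the network to
  avoid noise-induced extinction. Defaults are the documented
  stable-fixed-point set $A=2/3$, $d=c=0.65$, $b=1$, $\delta=0.2$,
  $\beta=0.8$ ($\kappa = Ac/d = 2/3$,
  $\epsilon_{\mathrm{eff}} = \delta c/(\beta d) = 0.25$); the limit-cycle
  regime is the documented override $\delta=0.1$, $\beta=0.9$. The default
  $N = 1000$ is the size at which the stochastic portrait visually matches
  the deterministic one.

## Known limitations

The method inherits the Fokker–Planck truncation: it degrades when
discreteness dominates (very small molecule numbers), and nothing here
integrates the master equation or the time-dependent 2D Fokker–Planck
equation directly. In two dimensions with $\mathbf j \neq 0$ the stationary
density is not available in closed form, so 2D validation is statistical
(SSA histograms) rather than exact. Relative heights and widths of multiple
maxima are not predicted — only their existence, location and type. Global
bifurcation continuation and basin-of-attraction quantification are out of
scope.
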