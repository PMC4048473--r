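---
title: "Methods: constrained estimation of non-dimensionalized S-systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained estimation of non-dimensionalized S-systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendisc)
```

## The model

`pendisc` works within Biochemical Systems Theory: every pool
(metabolite concentration) $X_i$ evolves as the difference of two
aggregated power-law terms,

$$\frac{dX_i}{dt} \;=\; \alpha_i \prod_j X_j^{g_{ij}} \;-\;
  \beta_i \prod_j X_j^{h_{ij}},$$

where all influxes of pool $i$ collapse into the first term and all
effluxes into the second. The exponents (kinetic orders) $g_{ij},
h_{ij}$ are nonzero only for pools that actually take part in the
corresponding reactions: precursors and activators enter positively,
inhibitors negatively, and a pool never appears in its own influx term.
This structure is written down mechanically from a pathway map
(`pathway_network()` + `build_ssystem()`), which is the method's main
practical appeal: no rate-law literature search is needed to get a
simulable model.

**Assumptions.** The system possesses a positive steady state $X^*$
(every pool must have at least one influx and one efflux); the flux
graph is connected; concentrations stay positive. Power-law kinetics
are an approximation around an operating point — far from it, saturable
enzymes deviate from any fixed-order power law.

## Non-dimensionalization

With $x_i = X_i / X_i^*$ the model becomes

$$\frac{dx_i}{dt} = A_i\Big(\prod_j x_j^{g_{ij}} - \prod_j x_j^{h_{ij}}\Big),
\qquad
A_i = \frac{\alpha_i}{X_i^*}\prod_j X_j^{*\,g_{ij}},$$

because the influx- and efflux-side dimensionless constants coincide at
the steady state. `nondimensionalize()` computes both sides
independently and errors (default relative tolerance $10^{-6}$) if they
disagree — the symptom of passing an $X^*$ that is not actually a
steady state of the model. The transformation halves the number of
rate-constant unknowns from $2N$ to $N$ and is exactly invertible
(`redimensionalize()`), a round trip the test suite checks to
$10^{-10}$.

## Structural constraints

At the steady state $Y_i := X_i^* A_i$ equals the total flux through
pool $i$. Reading the aggregated terms as sums of edge fluxes gives
affine relations:

* chain edge $i \to j$ (sole influx of $j$): $Y_i = Y_j$;
* branch point $b$ with internal children $c_1,\dots,c_q$:
  $Y_b = \sum_k Y_{c_k}$;
* confluence of $u_1,\dots,u_q$ into $p$: $\sum_k Y_{u_k} = Y_p$.

`derive_constraints()` collects these into a relation matrix $R$ (with
$R\,Y = 0$), and the number of free constants is the rank deficiency
$N - \mathrm{rank}(R)$: one for a linear pathway, $p+1$ when the
(single-source, tree-like) structure has $p$ branch points; each
additional external source adds one more. Dependent constants are
linear in the free ones with coefficients built from $X^*$
(`expand_rate_constants()`).

**Free-set convention.** The free set is chosen deterministically as
the first pool in topological order plus, at each branch point, its
highest-index internal child; if that preference ever leaves the
dependent block rank-deficient, the next pool in topological order is
taken instead. For the branched benchmark this selects $\{A_1, A_4\}$,
so the branch relation eliminates $A_2$ (and the chain relation $A_3$).
Networks mixing branches and confluences in arbitrary arrangements have
no canonical free set; this rule is simply this package's reproducible
convention, and any maximal feasible set parameterizes the same
solution family.

**Infeasibility is a signal, not a clamp.** A branch expansion
$A_c = (X_b^* A_b - X_{c'}^* A_{c'})/X_c^*$ can go non-positive for
trial parameters. `expand_rate_constants()` raises a classed condition
(`pendisc_infeasible`) and the optimizer rejects the step; clamping to
a small positive value would instead corrupt the $\chi^2$ geometry near
the feasibility boundary.

## Fixed kinetic orders

When true orders are unknown, all order magnitudes are fixed at 0.5
(signed by role). Power-law transformations of Michaelis–Menten-type
rate laws give orders mostly inside $(0, 1)$ (or $(-1, 0)$ for
inhibition), so 0.5 is the natural average; trajectory shapes are
dominated by the network structure while the fitted rate constants
absorb timing and magnitude differences. `build_ssystem()` also accepts
any uniform magnitude $c$ (the test suite sweeps 0.25–1.00 and checks
that fitted trajectories stay within 0.5 dimensionless units of each
other) and fully explicit `g`/`h` matrices.

## Estimation

`lm_fit()` minimizes

$$\chi^2(\mathbf A) = \sum_{i,k}
  \left[\frac{x_{i,k} - \hat x_{i,k}(\mathbf A)}{\sigma_{i,k}}\right]^2$$

over the free constants, integrating the dimensionless model from the
first data row for every trial point. The optimizer is a classic
Levenberg–Marquardt with Press-style damping of the normal equations:
$\lambda$ is divided by 10 on accepted steps and multiplied by 10 on
rejections (rejection = $\chi^2$ increase, positivity violation,
infeasible expansion, or integration failure).

* **Initial guesses** default to 5 for every free parameter — a
  deliberately uninformed start that the benchmark protocol uses
  throughout.
* **Convergence** is declared when an accepted step satisfies both
  $[\chi^2_{\text{old}} - \chi^2_{\text{new}}]/\chi^2_{\text{old}} \le 10^{-8}$
  and $\chi^2_{\text{new}} \le 10^{-5}$. The absolute criterion is
  meaningful only for unweighted residuals on (near) noise-free data —
  which is why $\sigma$ defaults to 1 — and unattainable on noisy data,
  so a documented fallback declares convergence when the relative
  criterion alone holds for 5 consecutive accepted steps, or when no
  downhill step exists at any damping (a stalled iterate is the limit
  of zero relative decrease). The criterion actually met is reported in
  every `pendisc_fit`.
* **Derivatives.** The residual Jacobian uses central differences with
  two-level Richardson extrapolation (step
  $h_i = \max(10^{-4}|x_i|, 10^{-6})$), falling back to one-sided
  differences at feasibility boundaries. A cheaper forward-difference
  scheme is available via `fit_config(derivative_scheme = "forward")`.
* **Positivity** is enforced by step rejection, keeping the plain LM
  geometry; `fit_config(log_params = TRUE)` switches to optimizing
  $\log A$ instead.

## Hidden pools

For an unmeasured pool the steady state $X_h^*$ is unknown, so $A_h$
cannot be eliminated: it joins the parameter vector, trajectories of
all pools are integrated, residuals are summed over measured pools
only, and the steady state is recovered afterwards by splitting the
flux composite, $X_h^* = Y_h / A_h$ (`estimate_hidden_steady_state()`).
If a hidden pool sits in the free set itself, its composite $Y_h$ is
estimated directly. The hidden pool's dimensionless initial value
$x_{h,0}$ cannot be inferred from data; it defaults to 1 (start at the
steady state) and is configurable. The fitted constants do depend on
this choice — the package reports it with every result rather than
optimizing it silently.

## Evaluation utilities

* `add_noise()` multiplies each point by $1 + u$, $u \sim
  \mathcal U(-L, L)$ — bounded noise "up to" $\pm L$, preserving
  positivity. A truncated-Gaussian alternative sits behind a flag.
* `steady_states_from_data()` averages the last five points (after the
  transient has decayed) as the experimental $X^*$ for
  non-dimensionalization of noisy data.
* `loo_cv()` removes one time index at a time across all pools
  (per-pool removal available), refits, and records each refit's MSE
  against the full data. The first point is kept by default because it
  anchors the initial state of every trajectory integration.
* `perturbation_response()` doubles (by default) one pool at the fitted
  steady state and integrates until all pools are back within 0.1%.
* `mse()` is the *joint* mean of squared dimensionless residuals over
  all measured pools and time points (pooling before averaging; the
  per-pool-then-average variant would differ only when pools have
  different numbers of points).

## Benchmark fixtures and what they show

`branched_reference()` is a four-pool branched pathway with feedback
inhibition and feedforward activation:
$dX_1/dt = 12X_3^{-0.8} - 10X_1^{0.5}$,
$dX_2/dt = 8X_1^{0.5} - 3X_2^{0.75}$,
$dX_3/dt = 3X_2^{0.75} - 5X_3^{0.5}X_4^{0.2}$,
$dX_4/dt = 2X_1^{0.5} - 6X_4^{0.8}$, $X_0 = (1.4, 2.7, 1.2, 0.4)$. The
fixture self-verifies at construction: its solved steady state, its
dimensionless constants, and the exact round-trip of
$\alpha = (12,8,3,2)$, $\beta = (10,3,5,6)$ are pinned in the test
suite. `linear_chain()` builds chains of any length (one free
constant), and `aspartate_network()` ships the seven-pool aspartate
amino-acid pathway *topology* (branch at aspartate-semialdehyde,
reducing seven constants to two); no Michaelis–Menten rate law is
attached to it, so all aspartate results here are structural.

`generate_timeseries()` integrates a fixture on an equally spaced grid
over $[0, t_{\text{end}}]$, default $t_{\text{end}} = 5$ — for the
branched benchmark the transient is essentially complete by $t = 5$,
and the 11-point grid then contains an early interior point at
$t = 0.5$ whose removal is the most informative leave-one-out case.
Grid sizes of 11 and 21 points are the benchmark conditions; both the
grid and the noise level are recorded in each dataset's provenance
attribute.

**What passing tests do not show.** The generator produces data from
the same model family that is being fitted (or from the true rate law
with mismatched fixed orders), with uniform bounded noise, a shared
time grid for all pools, and an exactly attained steady state. Real
metabolomics data have relative-quantity calibration, pool-specific
missingness, correlated and heteroscedastic errors, and systems that
drift rather than equilibrate. Success on these fixtures demonstrates
algorithmic correctness and robustness to bounded noise and hidden
pools — not instrument-level validity.

## Numerical choices

* **Steady states** are solved in log space: S-system steady-state
  conditions are linear in $\log X$, so one linear solve suffices when
  $g - h$ is nonsingular; a damped Newton iteration on the log-space
  residual is the fallback. Solutions are verified to residual
  $10^{-12}$.
* **Integration** uses `deSolve::lsoda` (stiff-capable): tolerances
  $10^{-10}/10^{-12}$ (rtol/atol) for fixture generation, so data are
  far more accurate than fit tolerances, and $10^{-8}/10^{-10}$ inside
  fitting for speed. States are clamped at $10^{-300}$ only inside the
  right-hand-side logarithm to survive transient negative trial steps
  of the integrator; simulated trajectories are checked positive.
* **Stiffness ratio** (`stiffness_ratio()`): max/min absolute real
  parts of the Jacobian eigenvalues at an equilibrium, with numerically
  zero real parts (below $10^{-9}$ of the largest) excluded and
  counted separately; the Jacobian uses the same Richardson scheme as
  the fit.
* **Degenerate inputs** rejected with named errors: pools without both
  an influx and an efflux, disconnected flux graphs, duplicate pool or
  modifier entries, non-monotone time grids, non-positive
  concentrations, cyclic flux topologies with no valid elimination
  order.

## Problem sizes

The shipped tests and the acceptance script run the full protocol at
the benchmark sizes: 11- and 21-point series of the four-pool branched
system, leave-one-out over the 10 removable points, a four-magnitude
order sweep, and random tree networks of up to 8 pools for the
property checks. These sizes are the study conditions themselves, not
reductions of them.

## Known limitations

* Kinetic orders are never estimated — fixing them is the point of the
  reduction; fitted rate constants absorb (and are biased by) order
  misspecification.
* Single local LM start (default guess 5): multimodal $\chi^2$ surfaces
  with wrong orders can converge to different basins depending on the
  time grid; no global search or uncertainty quantification is
  provided.
* Constraint derivation covers chains, branch points and confluences
  whose neighborhoods are tree-like; fully cyclic flux structures
  without external input are rejected rather than approximated.
* Hidden-pool estimates inherit the arbitrariness of $x_{h,0}$ and the
  estimated steady states of the measured pools; with noisy data the
  recovered $X_h^*$ is an order-of-magnitude estimate, not a
  measurement substitute.
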