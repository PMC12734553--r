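---
title: "Stochastic intra-carrier cargo transfer between two compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic intra-carrier cargo transfer between two compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargoflip)
```

## The model

Many nanocarriers hold their cargo in two distinct compartments. The
motivating case is a lipid vesicle whose bilayer hosts amphipathic drug
molecules in either the outer (external) or inner (internal) leaflet, with
spontaneous flip-flop moving molecules between the two. `cargoflip` models an
ensemble of `N` such carriers. Each carrier offers `mE` identical external
and `mI` identical internal binding sites, each site empty or singly
occupied, and a molecule hops from an occupied external site to a vacant
internal one with rate constant `KEI` (and back with `KIE`). Transfer between
different carriers is excluded, so each carrier's total load is frozen: the
ensemble decomposes into independent subpopulations of fixed total cargo
`v = i + n`, and the class sizes `S_v` are constants of the motion.

The ensemble state is the matrix `y[i, n](t)` counting carriers with `i`
external and `n` internal cargo items. Its exact dynamics is a linear
chemical master equation whose transition rates carry the combinatorial
factors `i (1 - n/mI)` and `n (1 - i/mE)`: the number of movable items times
the fraction of vacant destination sites. Transfer into a full compartment is
impossible. Two fixed rate constants mean transfer events are independent; we
do not model cooperativity, compositional heterogeneity, or time-dependent
rates, and there is a single carrier species.

Three layers of description are implemented, each exact within its regime,
and each testable against the others:

1. **Master equation** (`master_rhs()`, `master_integrate()`) — exact on the
   discrete grid, integrated numerically.
2. **Fokker–Planck limit** (`fp_propagate()`, `green_density()`) — analytic,
   valid for many sites at low occupation.
3. **Gillespie simulation** (`ssa_sample_initial()`, `ssa_run()`) — exact
   samples of the underlying jump process, used as an independent oracle.

## Moments and equilibrium

The compartment totals `ME(t) = Σ i y[i,n]`, `MI(t) = Σ n y[i,n]` obey a
first-order-reaction relaxation whenever the hierarchy closes (large site
counts, or the special balance `KEI mE = KIE mI`):

    ME(t)/N = muE + exp(-t/tau) (etaE - muE),   tau = 1/(KEI + KIE),

with equilibrium means per carrier `muE = (M/N) KIE/(KEI+KIE)` and
`muI = (M/N) KEI/(KEI+KIE)`. We compute `muI` as `M/N - muE` so the
conservation identity holds to the last floating-point bit.

On the discrete grid the stationary distribution is, within each fixed-`v`
class, a product of two binomials `Binom(mE, p) Binom(mI, q)` conditioned on
`i + n = v`. Detailed balance plus cargo conservation fix `(p, q)`:

    mE KEI p (1 - q) = mI KIE (1 - p) q,     p mE + q mI = M/N.

`solve_pq()` eliminates `q` (which is a rational function of `p` under the
first relation), solves the resulting quadratic for the root in (0, 1), and
polishes it with Newton steps on the conservation residual; this yields
residuals at machine precision, which the test suite checks against an
independent bisection oracle and over 1000 random parameter draws. The exact
closed form is unwieldy, but as `mE, mI → ∞` at fixed `M/N` the solution
approaches `p mE → muE`, `q mI → muI` (tested at site counts 10^2..10^4).
The per-class normalising constant `g(v)` of the stationary law is fixed
uniquely by the conserved class sizes,
`g(v) = S_v / Σ_i Binom(mE, i; p) Binom(mI, v-i; q)`, and is evaluated in log
space so that occupied classes far in the binomial tails do not underflow.

## The continuum solution

For large site counts with low occupation (`p, q ≪ 1` with `p mE`, `q mI`
finite — for a 100 nm vesicle with ~10^3 effective sites and tens to hundreds
of drug molecules, both assumptions are comfortable) the master equation
becomes a Fokker–Planck equation for the density `y(x, z, t)`. In the rotated
coordinates `u = x - z`, `v = x + z` the equation acts on `u` alone and is of
Ornstein–Uhlenbeck type, so its Green's function is Gaussian,

    G(u, v, t | u') = Normal(u; mu(v, t | u'), sigma(t)),
    mu = u' e^{-t/tau} + v Δ (1 - e^{-t/tau}),   Δ = (muE - muI)/(muE + muI),
    sigma(t) = 4 muE muI/(muE + muI) (1 - e^{-2 t/tau}),

and any initial density is propagated by convolution over `u'` at fixed `v`.
The `v`-marginal `f(v)` is conserved along with all its moments, and the
equilibrium is `f(v) Normal(u; v Δ, sigma(∞))`: initial conditions that share
`f(v)` share their equilibrium, while a different `⟨v²⟩₀` shifts the
equilibrium width `⟨u²⟩_eq = sigma(∞) + Δ² ⟨v²⟩₀`.

Numerically we exploit that the propagator is an affine-Gaussian map: every
initial condition offered by the package (delta, product Gaussian with
Poisson widths, finite Gaussian mixtures) is represented as a Gaussian
mixture in `(u, v)` whose components are pushed through the map in closed
form. This makes `fp_propagate()` exact to rounding, conserves `N`, `M` and
`f(v)` identically, and satisfies the Chapman–Kolmogorov semigroup property
by construction (all verified in the tests). Arbitrary gridded densities take
the quadrature route `fp_propagate_grid()` (per-`v` trapezoid convolution;
recommended grid: mean ± 8 standard deviations, ≥ 400 points), which the
tests hold against the closed form at 1e-8. Degenerate kernels are avoided by
convention: at `t = 0` propagation is an exact pass-through, and delta
initial conditions stay symbolic — `green_density()` itself requires `t > 0`.

Chart conventions: the `uv`-chart density integrates to `2N` (because
`dx dz = du dv / 2`) and the `xz`-chart density to `N`; pointwise the two are
equal, and `field_to_uv()` / `field_to_xz()` round-trip exactly.

## Worked examples

Three closed-form scenarios are bundled (all with `KEI/KIE = 1/2`, i.e.
`muE = 2 muI`, time in units of `tau`, `M/N = 100` in the shipped
configurations):

* **All cargo external** (`ic_delta(M/N, M/N)`, `example1_marginal()`): the
  `u`-marginal is the Green's function itself, drifting from `M/N` to
  `muE - muI` with variance `sigma(t)`.
* **Mirrored Gaussian start** (`example2_ic()`, `example2_field()`): initial
  means `(M/3N, 2M/3N)`, the reverse of the equilibrium `(2M/3N, M/3N)`. The
  density stays Gaussian, its maximum travelling the slope −1 line
  `ME(t)/N = (M/3N)(2 - e^{-t/tau})`; both compartments hold half the cargo
  at `t = tau ln 2`, and the external fraction passes 4/12, 5/12, 6/12, 7/12,
  8/12 at `t/tau = 0, ln(4/3), ln 2, ln 4, ∞`. The transverse variance
  `var_u = (M/N)(1 - (4/9)(e^{-t/tau} - e^{-2t/tau}))` dips to `(8/9)(M/N)`
  at `t = tau ln 2`. The closed form's exponent is evaluated in the grouping
  `(x+z)(e^{-2t/tau}(x+z) + 2 e^{-t/tau}(x-2z))`, which stays finite for all
  `t`; we verified it against the generic kernel propagation at 1e-14.
* **Two-Gaussian mixtures** (`example3_ic()`): the `"redistributed"` variant
  moves half the mass along a line of constant `v` (second component
  `etaE2 = etaE1 (1 + e^{-2/5})`, `etaI2 = etaI1 (1 - e^{-2/5}/2)`, chosen so
  each component still carries `M/N` cargo with the same Poisson `v`-width —
  this is the unique reading of the construction under which `f(v)` is
  unchanged, and the tests verify `f(v)` equality at 1e-10); the `"shifted"`
  variant separates the components along `x`, changes `f(v)`, and relaxes to
  a different equilibrium.

The whole module is redundant by design: every closed form is held pointwise
against `fp_propagate()` in the tests, making it the verification surface for
the generic machinery.

## Master-vs-continuum comparison and truncation

`figure3_setup(scale)` builds the discrete reference configuration
(`N = 100`, `M = 10000`, `mE = mI = 2500 * scale`, product-binomial start
with means matching the mirrored-Gaussian example). Because all the mass
lives within a few standard deviations of means of order `M/N`, the
integrator works on a `truncation_window()` — means ± k·sd with `k` set by a
Gaussian tail bound (ε = 1e-12 by default, and the reported `massBound` is
the exact binomial mass outside the window). The active grid is then roughly
170 × 170 cells regardless of the site count, so even the full
`mE = mI = 2500` configuration integrates in seconds; a full-grid mode is
used automatically below 10^6 cells, and the tests confirm windowed and
full-grid trajectories agree.

The integrator is `deSolve`'s non-stiff Adams method with `rtol = 1e-8`,
`atol = 1e-12 N` (the operator is linear and only mildly stiff at these
parameter ratios; tolerances are arguments throughout). Negative entries of
order `atol` can appear transiently and are clipped on output only.
Conservation of `N`, `M` and every `S_v` is asserted along trajectories at
`10 · rtol`.

A caution on accuracy: the continuum solution assumes *low occupation*, so
its distance from the master equation is controlled by the occupancies
`p0 = M/(3 N mE)` and `q0 = 2M/(3 N mI)`, not by the integration error. The
acceptance script measures the cross-section sup-norm along `i + n = M/N`
(relative to the peak, maximised over `t/tau ∈ {0, ln 4/3, ln 2, ln 4}`):
it decreases roughly like the occupancy — tens of percent at `mE = mI = 250`
(where `q0 ≈ 0.27`), a few percent at 2500 — and already at `t = 0` it
reflects pure binomial-vs-Gaussian algebra rather than any numerics. The
tests therefore assert the monotone improvement with site count; treating
the continuum solution as quantitatively exact requires occupancies well
below those of the smaller benchmark grids.

## The Gillespie oracle

`ssa_run()` advances each carrier's two-reaction jump process by the exact
direct method, with propensities `KEI i (1 - n/mI)` and `KIE n (1 - i/mE)`.
Carriers are independent, so the ensemble is processed in a synchronised
vectorised event loop; per-carrier totals are conserved in integer
arithmetic, and a run is bit-reproducible for fixed seed, ensemble size and
parameters. Gaussian initial conditions are discretised by rounding and
clipping — an approximation accepted only for oracle comparisons. No
tau-leaping or other acceleration is offered: exactness is the point.

The oracle validates the other layers distributionally: at the small
reference grid (`mE = 8`, `mI = 5`, `M/N = 3`, a scale chosen so every state
is populated) the stationary histogram of 10^5 carriers is compared with the
detailed-balance equilibrium by total-variation distance against its
Monte-Carlo expectation `½ Σ sqrt(p_s(1-p_s)/n)`, and transient ensemble
means track the integrated master equation within sampling error. Standard
errors come from plug-in formulas (delta-method fourth-moment expression for
variances), which for these smooth statistics coincide with the delete-1
jackknife to leading order.

## What the built-in configurations do and do not emulate

The shipped configurations are idealisations: identical carriers, fixed rate
constants, no inter-carrier exchange, no loss to the medium, and initial
conditions (delta, product binomial, Gaussian mixtures) whose compartment
loads are statistically independent across carriers. Real release data would
add carrier polydispersity, collision-mediated exchange and measurement
noise; passing tests here demonstrate the internal consistency of the three
solution layers under the stated regime, not agreement with any particular
experiment. Estimating `KEI`, `KIE` from data is out of scope, though the
exponential moment law shows how they would enter.

Problem sizes used by the test suite and the acceptance script — site counts
up to 2500 (truncated grids ≈ 170 × 170), 10^5-carrier Gillespie ensembles,
1000-draw property checks — were chosen as comfortable desk-scale settings
that still expose every asymptotic trend the model predicts.

## A worked session

```{r example}
m <- carrier_model(mE = Inf, mI = Inf, KEI = 1/3, KIE = 2/3,
                   N = 100, M = 10000)
coef(m)

## mirrored-Gaussian start: closed-form moments
predict(m, times = c(0, log(2), log(4)), ic = example2_ic(m))

## the discrete reference configuration at 1/10 scale
setup <- figure3_setup(0.1)
traj <- master_integrate(setup$ic, c(0, log(2)), setup$model)
moments_discrete(traj[[2]])

## exact stochastic sample
ens <- simulate(m, nsim = 1000, seed = 1,
                ic = ic_gaussian(100/3, 200/3), t_end = log(2))
empirical_moments(ens)[, c("t", "ME_over_N", "var_u")]
```
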