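#' Worked example 1: all cargo initially external, identical carriers
#'
#' Every carrier starts with exactly `M/N` cargo items, all in the external
#' compartment (a delta initial condition at `u = v = M/N`). Because `v` is
#' frozen, the interesting object is the `u`-marginal, which is the Green's
#' function itself: a Gaussian of mean `muE - muI (1 - 2 e^{-t/tau})` and
#' variance `sigma(t)`, scaled to `2N`.
#'
#' @param u Evaluation points.
#' @param t Positive time (`t = 0` is a delta peak; request it via
#'   [fp_propagate()] which keeps deltas symbolic).
#' @param model A [carrier_model()].
#' @return Density values over `u`, integrating to `2N`.
#' @export
example1_marginal <- function(u, t, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (t <= 0)
    stop("t = 0 is a degenerate delta peak; no pointwise density",
         call. = FALSE)
  d <- derived_quantities(model)
  m <- d$muE - d$muI * (1 - 2 * exp(-t / d$tau))
  2 * model$N * stats::dnorm(u, m, sqrt(sigma_t(t, model)))
}

# guard for the example-2 family: muE = 2 muI requires KEI/KIE = 1/2
check_example2 <- function(model) {
  if (abs(model$KEI / model$KIE - 0.5) > 1e-12)
    stop("example 2 requires KEI/KIE = 1/2 (so muE = 2 muI)", call. = FALSE)
  invisible(TRUE)
}

#' Worked example 2: Gaussian start opposite to the preferred partition
#'
#' Initial product Gaussian with per-carrier means `etaE = M/(3N)` external
#' and `etaI = 2M/(3N)` internal, relaxing under `KEI/KIE = 1/2` toward the
#' mirrored equilibrium `muE = 2M/(3N)`, `muI = M/(3N)`. The full
#' time-dependent density has the closed form
#' `y(x, z, t) = y_eq(x, z) * exp(-(N/4M) e^{-2t/tau} (x+z) ((x+z) + 2 e^{t/tau} (x - 2z)))`.
#'
#' `example2_path()` returns the straight slope `-1` line along which the
#' density maximum travels, `ME(t)/N = (M/3N)(2 - e^{-t/tau})`,
#' `MI(t)/N = (M/3N)(1 + e^{-t/tau})`; the compartments hold equal cargo at
#' `t = tau ln 2`. `example2_variances()` gives `var_v = M/N` (conserved) and
#' `var_u = (M/N)(1 - (4/9)(e^{-t/tau} - e^{-2t/tau}))`, which dips to
#' `(8/9)(M/N)` at `t = tau ln 2`.
#'
#' @param x,z Evaluation points (vectorised elementwise).
#' @param t Time(s), non-negative.
#' @param model A [carrier_model()] with `KEI/KIE = 1/2`.
#' @return `example2_field`: density values. `example2_path`: data frame
#'   `t`, `ME_over_N`, `MI_over_N`. `example2_variances`: data frame `t`,
#'   `var_v`, `var_u`.
#' @name example2
NULL

#' @rdname example2
#' @export
example2_ic <- function(model) {
  mn <- model$M / model$N
  ic_gaussian(etaE = mn / 3, etaI = 2 * mn / 3)
}

#' @rdname example2
#' @export
example2_field <- function(x, z, t, model) {
  stopifnot(inherits(model, "carrier_model"), all(t >= 0))
  check_example2(model)
  d <- derived_quantities(model)
  N <- model$N; MN <- model$M / model$N
  yeq <- N / (2 * pi * sqrt(d$muE * d$muI)) *
    exp(-(x - d$muE)^2 / (2 * d$muE) - (z - d$muI)^2 / (2 * d$muI))
  # e^{-2t/tau} (x+z)[(x+z) + 2 e^{t/tau} (x-2z)], grouped to stay finite
  # for large t
  e1 <- exp(-t / d$tau); e2 <- e1^2
  yeq * exp(-(1 / (4 * MN)) * (x + z) *
              (e2 * (x + z) + 2 * e1 * (x - 2 * z)))
}

#' @rdname example2
#' @export
example2_path <- function(t, model) {
  stopifnot(all(t >= 0))
  check_example2(model)
  d <- derived_quantities(model)
  c3 <- model$M / (3 * model$N)
  e <- exp(-t / d$tau)
  data.frame(t = t, ME_over_N = c3 * (2 - e), MI_over_N = c3 * (1 + e))
}

#' @rdname example2
#' @export
example2_variances <- function(t, model) {
  stopifnot(all(t >= 0))
  check_example2(model)
  d <- derived_quantities(model)
  mn <- model$M / model$N
  e <- exp(-t / d$tau)
  data.frame(t = t, var_v = rep(mn, length(t)),
             var_u = mn * (1 - (4 / 9) * (e - e^2)))
}

#' Worked example 3: two-Gaussian initial mixtures
#'
#' Equal-weight mixtures of two product Gaussians under the example-2 rate
#' ratio. The `"redistributed"` variant shifts the second component along a
#' line of fixed total cargo `v = x + z` (component means
#' `etaE2 = etaE1 (1 + e^{-2/5})`, `etaI2 = etaI1 (1 - e^{-2/5}/2)`), leaving
#' the conserved marginal `f(v)` — and therefore the equilibrium — identical
#' to example 2. The `"shifted"` variant separates the components along the
#' `x` axis (`etaE = (1/3 -+ 1/10) M/N`, `etaI = (2/3) M/N` for both), which
#' changes `f(v)` and hence relaxes toward a different equilibrium.
#'
#' @param kind `"redistributed"` (same equilibrium as example 2) or
#'   `"shifted"` (different equilibrium).
#' @param model A [carrier_model()] with `KEI/KIE = 1/2`.
#' @return An [ic_mixture()].
#' @export
example3_ic <- function(kind = c("redistributed", "shifted"), model) {
  kind <- match.arg(kind)
  check_example2(model)
  mn <- model$M / model$N
  if (kind == "redistributed") {
    e1E <- mn / 3; e1I <- 2 * mn / 3
    ic_mixture(alpha = c(0.5, 0.5),
               etaE = c(e1E, e1E * (1 + exp(-0.4))),
               etaI = c(e1I, e1I * (1 - exp(-0.4) / 2)))
  } else {
    ic_mixture(alpha = c(0.5, 0.5),
               etaE = c((1 / 3 - 1 / 10) * mn, (1 / 3 + 1 / 10) * mn),
               etaI = c(2 * mn / 3, 2 * mn / 3))
  }
}

#' Reference configuration for the master-vs-continuum comparison
#'
#' The discrete configuration used to benchmark the master equation against
#' the analytic continuum solution: `KEI = 1/(3 tau)`, `KIE = 2/(3 tau)`,
#' `N = 100`, `M = 10000`, site counts `mE = mI = 2500` (scaled by `scale`),
#' and the product-binomial start `p0 = M/(3 N mE)`, `q0 = 2M/(3 N mI)` whose
#' compartment means match the example-2 Gaussian. Time is measured in units
#' of `tau` (i.e. `tau = 1`).
#'
#' @param scale Multiplier on the site counts (1 reproduces `mE = mI = 2500`;
#'   smaller values probe the approach to the continuum limit).
#' @return List with elements `model` and `ic`.
#' @export
figure3_setup <- function(scale = 1) {
  stopifnot(scale > 0)
  m <- round(2500 * scale)
  model <- carrier_model(mE = m, mI = m, KEI = 1 / 3, KIE = 2 / 3,
                         N = 100, M = 10000)
  ic <- ic_binomial(p0 = model$M / (3 * model$N * m),
                    q0 = 2 * model$M / (3 * model$N * m))
  list(model = model, ic = ic)
}
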