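#' Analytic Fokker-Planck solution via the Green's function
#'
#' In the Gaussian regime at low occupation the master equation reduces to a
#' drift-diffusion (Fokker-Planck) equation for the carrier density
#' `y(x, z, t)`. In the rotated coordinates `u = x - z`, `v = x + z` the
#' equation acts only on `u` (the total `v` of each carrier is conserved) and
#' is of Ornstein-Uhlenbeck type, so its propagator is Gaussian:
#' `G(u, v, t | u') = Normal(u; mu(v, t | u'), sigma(t))` with
#' `mu(v, t | u') = u' e^{-t/tau} + v (muE - muI)/(muE + muI) (1 - e^{-t/tau})`
#' and `sigma(t) = 4 muE muI/(muE + muI) (1 - e^{-2t/tau})`.
#'
#' `sigma_t()` and `green_density()` expose these two ingredients directly.
#'
#' @param t Time, non-negative (`green_density` requires `t > 0`; at `t = 0`
#'   the kernel is a delta and propagation is an exact pass-through).
#' @param model A [carrier_model()].
#' @param u,v Evaluation point in the rotated chart.
#' @param uprime Source location of the kernel.
#' @return `sigma_t`: the kernel variance (cargo^2). `green_density`: the
#'   Gaussian density in `u`, normalised so `integral G du = 1`.
#' @name greens_kernel
NULL

#' @rdname greens_kernel
#' @export
sigma_t <- function(t, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  d <- derived_quantities(model)
  4 * d$muE * d$muI / (d$muE + d$muI) * (1 - exp(-2 * t / d$tau))
}

#' @rdname greens_kernel
#' @export
green_mean <- function(v, t, uprime, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  d <- derived_quantities(model)
  del <- (d$muE - d$muI) / (d$muE + d$muI)
  e <- exp(-t / d$tau)
  uprime * e + v * del * (1 - e)
}

#' @rdname greens_kernel
#' @export
green_density <- function(u, v, t, uprime, model) {
  if (any(t <= 0))
    stop("green_density requires t > 0 (the t = 0 kernel is a delta)",
         call. = FALSE)
  stats::dnorm(u, mean = green_mean(v, t, uprime, model),
               sd = sqrt(sigma_t(t, model)))
}

# ---- continuum fields -------------------------------------------------------

# A carrier_field is a finite Gaussian-mixture density over the plane, in
# either the uv or the xz chart. Weights sum to 2N in uv (so that
# (1/2)\int\int = N) and to N in xz (so \int\int = N). Components may be
# degenerate in v (delta of conserved total cargo).
new_field <- function(comp, chart, t, model) {
  structure(list(comp = comp, chart = chart, t = t, model = model),
            class = "carrier_field")
}

#' @export
print.carrier_field <- function(x, ...) {
  cat(sprintf("Continuum carrier field (%s chart, t = %g): %d Gaussian component(s)\n",
              x$chart, x$t, nrow(x$comp)))
  print(x$comp, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Propagate an initial cargo distribution in time
#'
#' Applies the Green's-function solution of the Fokker-Planck equation:
#' `ytilde(u, v, t) = integral G(u, v, t | u') ytilde0(u', v) du'`.
#' For the supported initial conditions (finite Gaussian mixtures and deltas
#' in `(u, v)`) the convolution is carried out in closed form: the propagator
#' is the affine-Gaussian map `u -> u e^{-t/tau} + v delta (1 - e^{-t/tau})`
#' plus independent noise of variance `sigma(t)`, with `v` untouched, so every
#' Gaussian component stays Gaussian. Carrier number, total cargo, and the
#' whole `v`-marginal `f(v)` are conserved exactly.
#'
#' A `carrier_field` may be supplied instead of an initial condition, in which
#' case it is advanced by a further `t` (the Chapman-Kolmogorov semigroup
#' property).
#'
#' @param ic A continuum initial condition ([initial_conditions]) or a
#'   `carrier_field` in the `uv` chart.
#' @param t Time step(s), non-negative. With a vector, a list of fields is
#'   returned.
#' @param model A [carrier_model()].
#' @return A `carrier_field` (or list of them) in the `uv` chart.
#' @export
fp_propagate <- function(ic, t, model) {
  stopifnot(inherits(model, "carrier_model"), all(t >= 0))
  if (inherits(ic, "carrier_field")) {
    fld <- if (ic$chart == "uv") ic else field_to_uv(ic)
  } else {
    check_ic_total(ic, model)
    fld <- ic_uv_mixture(ic, model)
  }
  if (length(t) > 1) return(lapply(t, function(ti) fp_propagate(fld, ti, model)))
  d <- derived_quantities(model)
  del <- (d$muE - d$muI) / (d$muE + d$muI)
  e <- exp(-t / d$tau)
  s <- sigma_t(t, model)
  comp <- fld$comp
  mu2 <- comp$mu * e + comp$mv * del * (1 - e)
  cuu2 <- e^2 * comp$cuu + 2 * e * del * (1 - e) * comp$cuv +
    del^2 * (1 - e)^2 * comp$cvv + s
  cuv2 <- e * comp$cuv + del * (1 - e) * comp$cvv
  new_field(data.frame(w = comp$w, mu = mu2, mv = comp$mv,
                       cuu = cuu2, cuv = cuv2, cvv = comp$cvv),
            chart = "uv", t = fld$t + t, model = model)
}

#' Continuum equilibrium distribution
#'
#' The stationary density of the Fokker-Planck equation compatible with a
#' conserved cargo-total marginal `f(v)`:
#' `ytilde_eq(u, v) = f(v) Normal(u; v (muE-muI)/(muE+muI), sigma(Inf))`.
#' Expressed in `(x, z)` this is the low-occupation equilibrium
#' `y_eq(x, z) = (1/2) f(x+z) / sqrt(2 pi (muE+muI)) * exp(...) *`
#' product of Gaussians centred at `muE`, `muI`.
#'
#' @param f A `v_marginal` from [f_of_v()], or an initial condition from which
#'   it is derived.
#' @param model A [carrier_model()].
#' @return A `carrier_field` in the `uv` chart (with `t = Inf`).
#' @export
fp_equilibrium <- function(f, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (inherits(f, "cargo_ic")) f <- f_of_v(f, model)
  stopifnot(inherits(f, "v_marginal"))
  d <- derived_quantities(model)
  del <- (d$muE - d$muI) / (d$muE + d$muI)
  sinf <- 4 * d$muE * d$muI / (d$muE + d$muI)
  comp <- f$comp
  new_field(data.frame(w = comp$w, mu = del * comp$m, mv = comp$m,
                       cuu = sinf + del^2 * comp$s2, cuv = del * comp$s2,
                       cvv = comp$s2),
            chart = "uv", t = Inf, model = model)
}

# density of one (possibly correlated) bivariate normal component
dbvnorm <- function(a, b, ma, mb, caa, cab, cbb) {
  det <- caa * cbb - cab^2
  if (det <= 0) stop("degenerate covariance: density undefined pointwise",
                     call. = FALSE)
  da <- a - ma; db <- b - mb
  qf <- (cbb * da^2 - 2 * cab * da * db + caa * db^2) / det
  exp(-qf / 2) / (2 * pi * sqrt(det))
}

#' Evaluate a continuum field
#'
#' @param field A `carrier_field`.
#' @param a,b Coordinates: `(u, v)` for a `uv`-chart field, `(x, z)` for an
#'   `xz`-chart field. Vectors are recycled elementwise.
#' @return Density values (carriers per unit cargo^2 in the field's chart).
#' @export
field_density <- function(field, a, b) {
  stopifnot(inherits(field, "carrier_field"))
  comp <- field$comp
  if (any(comp$cvv * comp$cuu - comp$cuv^2 <= 0))
    stop("field has a degenerate (delta) component; use field_marginal_u()",
         call. = FALSE)
  out <- 0
  for (k in seq_len(nrow(comp)))
    out <- out + comp$w[k] *
      dbvnorm(a, b, comp$mu[k], comp$mv[k],
              comp$cuu[k], comp$cuv[k], comp$cvv[k])
  out
}

#' Marginal density over u = x - z
#'
#' Integrates a `uv`-chart field over `v`; well defined even for fields with a
#' delta `v`-component (e.g. propagated `ic_delta`). Normalised to `2N`.
#'
#' @param field A `carrier_field` in the `uv` chart.
#' @param u Evaluation points.
#' @export
field_marginal_u <- function(field, u) {
  stopifnot(inherits(field, "carrier_field"), field$chart == "uv")
  comp <- field$comp
  if (any(comp$cuu == 0))
    stop("marginal is a delta in u; no pointwise density", call. = FALSE)
  out <- 0
  for (k in seq_len(nrow(comp)))
    out <- out + comp$w[k] * stats::dnorm(u, comp$mu[k], sqrt(comp$cuu[k]))
  out
}

#' Chart changes between (x, z) and (u, v)
#'
#' `u = x - z`, `v = x + z`; the Jacobian gives `dx dz = du dv / 2`, so the
#' `uv`-chart density integrates to `2N` while the `xz`-chart density
#' integrates to `N`; pointwise the two densities are equal,
#' `y(x, z) = ytilde(u, v)`.
#'
#' @param field A `carrier_field`.
#' @return The field re-expressed in the other chart.
#' @name chart_change
NULL

#' @rdname chart_change
#' @export
field_to_xz <- function(field) {
  stopifnot(inherits(field, "carrier_field"))
  if (field$chart == "xz") return(field)
  comp <- field$comp
  # x = (u+v)/2, z = (v-u)/2
  mx <- (comp$mu + comp$mv) / 2
  mz <- (comp$mv - comp$mu) / 2
  cxx <- (comp$cuu + 2 * comp$cuv + comp$cvv) / 4
  czz <- (comp$cvv - 2 * comp$cuv + comp$cuu) / 4
  cxz <- (comp$cvv - comp$cuu) / 4
  new_field(data.frame(w = comp$w / 2, mu = mx, mv = mz,
                       cuu = cxx, cuv = cxz, cvv = czz),
            chart = "xz", t = field$t, model = field$model)
}

#' @rdname chart_change
#' @export
field_to_uv <- function(field) {
  stopifnot(inherits(field, "carrier_field"))
  if (field$chart == "uv") return(field)
  comp <- field$comp
  mu <- comp$mu - comp$mv            # u = x - z
  mv <- comp$mu + comp$mv            # v = x + z
  cuu <- comp$cuu - 2 * comp$cuv + comp$cvv
  cvv <- comp$cuu + 2 * comp$cuv + comp$cvv
  cuv <- comp$cuu - comp$cvv
  new_field(data.frame(w = comp$w * 2, mu = mu, mv = mv,
                       cuu = cuu, cuv = cuv, cvv = cvv),
            chart = "uv", t = field$t, model = field$model)
}

#' Moments of a continuum field
#'
#' Exact mixture moments for closed-form fields, or 2-D trapezoid quadrature
#' for gridded fields from [fp_propagate_grid()]. Averages are per carrier,
#' i.e. `<g> = (1/2N) integral g ytilde du dv`.
#'
#' @param field A `carrier_field` or `grid_field`.
#' @return One-row data frame: `t`, `ME_over_N`, `MI_over_N`, `mean_u`,
#'   `mean_v`, `m2_u`, `m2_v`, `m11`, `var_u`, `var_v`.
#' @export
field_moments <- function(field) {
  if (inherits(field, "grid_field")) return(grid_moments(field))
  stopifnot(inherits(field, "carrier_field"))
  fld <- if (field$chart == "uv") field else field_to_uv(field)
  comp <- fld$comp
  w <- comp$w / sum(comp$w)
  mean_u <- sum(w * comp$mu)
  mean_v <- sum(w * comp$mv)
  m2_u <- sum(w * (comp$cuu + comp$mu^2))
  m2_v <- sum(w * (comp$cvv + comp$mv^2))
  m11 <- sum(w * (comp$cuv + comp$mu * comp$mv))
  data.frame(t = fld$t,
             ME_over_N = (mean_v + mean_u) / 2,
             MI_over_N = (mean_v - mean_u) / 2,
             mean_u = mean_u, mean_v = mean_v,
             m2_u = m2_u, m2_v = m2_v, m11 = m11,
             var_u = m2_u - mean_u^2, var_v = m2_v - mean_v^2)
}

# ---- moment algebra ---------------------------------------------------------

#' Closed-form moments in the rotated chart
#'
#' `mean_u()` gives the first moment
#' `<u>(t) = muE - muI + e^{-t/tau}(etaE - etaI - muE + muI)`, identical to
#' `ME(t)/N - MI(t)/N`. `second_moment_u()` propagates the second moment from
#' its initial value:
#' `<u^2>(t) = sigma(Inf)(1 - e^{-2t/tau}) + e^{-2t/tau} <u^2>_0
#'  + 2 delta (e^{-t/tau} - e^{-2t/tau}) <uv>_0
#'  + delta^2 (1 - e^{-t/tau})^2 <v^2>_0`, with
#' `delta = (muE - muI)/(muE + muI)`. At `t -> Inf` only the conserved
#' `<v^2>_0` survives: `<u^2>_eq = sigma(Inf) + delta^2 <v^2>_0`, so initial
#' distributions differing in `<v^2>_0` reach different equilibria.
#'
#' @param t Time(s), non-negative.
#' @param model A [carrier_model()].
#' @param etaE,etaI Initial per-carrier compartment means.
#' @param m2u0,m11_0,m2v0 Initial second moments `<u^2>_0`, `<uv>_0`,
#'   `<v^2>_0`.
#' @name uv_moments
NULL

#' @rdname uv_moments
#' @export
mean_u <- function(t, model, etaE, etaI) {
  stopifnot(all(t >= 0))
  d <- derived_quantities(model)
  d$muE - d$muI + exp(-t / d$tau) * (etaE - etaI - d$muE + d$muI)
}

#' @rdname uv_moments
#' @export
second_moment_u <- function(t, model, m2u0, m11_0, m2v0) {
  stopifnot(all(t >= 0))
  d <- derived_quantities(model)
  del <- (d$muE - d$muI) / (d$muE + d$muI)
  e <- exp(-t / d$tau)
  sinf <- 4 * d$muE * d$muI / (d$muE + d$muI)
  sinf * (1 - e^2) + e^2 * m2u0 + 2 * del * (e - e^2) * m11_0 +
    del^2 * (1 - e)^2 * m2v0
}

# ---- gridded propagation (quadrature route) ---------------------------------

#' Propagate a gridded initial condition by direct quadrature
#'
#' Reference route for arbitrary initial densities: for each fixed `v` the
#' Green's-function convolution over `u'` is evaluated by trapezoid quadrature
#' on a rectangular grid. Used as the numerical cross-check of the closed-form
#' mixture propagation; scales linearly in `length(v) * length(u)^2`.
#'
#' @param y0fun Function `y0fun(u, v)` returning the initial `uv`-chart
#'   density (vectorised in `u`).
#' @param t Positive time.
#' @param model A [carrier_model()].
#' @param u,v Strictly increasing grid vectors. The `u` grid is used both for
#'   the source and the target points and should span the initial and
#'   equilibrium mass (roughly mean +/- 8 sd) with at least a few hundred
#'   points.
#' @return A `grid_field`: list with `u`, `v`, matrix `Y` (`length(u)` x
#'   `length(v)`), chart `uv`.
#' @export
fp_propagate_grid <- function(y0fun, t, model, u, v) {
  stopifnot(is.function(y0fun), t > 0, all(diff(u) > 0), all(diff(v) > 0))
  d <- derived_quantities(model)
  del <- (d$muE - d$muI) / (d$muE + d$muI)
  e <- exp(-t / d$tau)
  s <- sigma_t(t, model)
  wq <- trap_weights(u)
  Y <- matrix(0, length(u), length(v))
  for (j in seq_along(v)) {
    y0 <- y0fun(u, v[j])
    mk <- u * e + v[j] * del * (1 - e)     # kernel mean for each source u'
    # target x source kernel matrix
    G <- stats::dnorm(outer(u, mk, "-"), sd = sqrt(s))
    Y[, j] <- as.vector(G %*% (wq * y0))
  }
  structure(list(u = u, v = v, Y = Y, chart = "uv", t = t, model = model),
            class = "grid_field")
}

# trapezoid moments of a gridded uv field
grid_moments <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  u <- field$u; v <- field$v; Y <- field$Y
  wu <- trap_weights(u); wv <- trap_weights(v)
  tot <- as.numeric(t(wu) %*% Y %*% wv)           # = 2N
  avg <- function(g) as.numeric(t(wu * g(u)) %*% Y %*% wv) / tot
  avg2 <- function(gu, gv) {
    as.numeric(t(wu * gu) %*% Y %*% (wv * gv)) / tot
  }
  mean_u <- avg(identity)
  mean_v <- as.numeric(t(wu) %*% Y %*% (wv * v)) / tot
  m2_u <- avg(function(x) x^2)
  m2_v <- as.numeric(t(wu) %*% Y %*% (wv * v^2)) / tot
  m11 <- avg2(u, v)
  data.frame(t = field$t,
             ME_over_N = (mean_v + mean_u) / 2,
             MI_over_N = (mean_v - mean_u) / 2,
             mean_u = mean_u, mean_v = mean_v,
             m2_u = m2_u, m2_v = m2_v, m11 = m11,
             var_u = m2_u - mean_u^2, var_v = m2_v - mean_v^2)
}

trap_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# carrier count of a grid field: (1/2) \int\int Y du dv
grid_carriers <- function(field) {
  wu <- trap_weights(field$u); wv <- trap_weights(field$v)
  as.numeric(t(wu) %*% field$Y %*% wv) / 2
}
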