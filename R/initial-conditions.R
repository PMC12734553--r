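#' Initial cargo distributions
#'
#' Constructors for the tagged initial-condition variants used throughout the
#' package. Continuum variants describe the carrier density at `t = 0` in the
#' `(x, z)` plane (cargo in external and internal compartment); the
#' product-binomial variant lives on the discrete `(i, n)` grid.
#'
#' * `ic_delta(u0, v0)` — all carriers share one state, expressed in the
#'   rotated coordinates `u = x - z`, `v = x + z`.
#' * `ic_gaussian(etaE, etaI)` — product Gaussian centred at `(etaE, etaI)`
#'   with variances equal to the means (the low-occupation Poisson widths).
#' * `ic_mixture(alpha, etaE, etaI)` — finite mixture of such Gaussians with
#'   weights `alpha` (summing to 1).
#' * `ic_binomial(p0, q0)` — independent binomial occupancies
#'   `Binom(mE, p0) x Binom(mI, q0)`, discrete grids only.
#'
#' @param u0,v0 Location of the delta peak in `(u, v)` coordinates.
#' @param etaE,etaI Initial mean cargo per carrier in the external/internal
#'   compartment (vectors of equal length for mixtures).
#' @param alpha Mixture weights, positive, summing to 1.
#' @param p0,q0 Initial site-occupation probabilities, each in (0,1).
#' @return An object of class `cargo_ic` with a `kind` field.
#' @name initial_conditions
NULL

#' @rdname initial_conditions
#' @export
ic_delta <- function(u0, v0) {
  stopifnot(is.numeric(u0), is.numeric(v0), v0 >= 0, abs(u0) <= v0)
  structure(list(kind = "delta", u0 = u0, v0 = v0), class = "cargo_ic")
}

#' @rdname initial_conditions
#' @export
ic_gaussian <- function(etaE, etaI) {
  stopifnot(length(etaE) == 1, length(etaI) == 1, etaE >= 0, etaI >= 0)
  structure(list(kind = "gaussian", etaE = etaE, etaI = etaI),
            class = "cargo_ic")
}

#' @rdname initial_conditions
#' @export
ic_mixture <- function(alpha, etaE, etaI) {
  stopifnot(length(alpha) == length(etaE), length(alpha) == length(etaI),
            all(alpha > 0), all(etaE >= 0), all(etaI >= 0))
  if (abs(sum(alpha) - 1) > 1e-12)
    stop("mixture weights must sum to 1", call. = FALSE)
  structure(list(kind = "mixture", alpha = alpha, etaE = etaE, etaI = etaI),
            class = "cargo_ic")
}

#' @rdname initial_conditions
#' @export
ic_binomial <- function(p0, q0) {
  stopifnot(p0 > 0, p0 < 1, q0 > 0, q0 < 1)
  structure(list(kind = "product_binomial", p0 = p0, q0 = q0),
            class = "cargo_ic")
}

#' @export
print.cargo_ic <- function(x, ...) {
  cat("Initial cargo distribution:", x$kind, "\n")
  switch(x$kind,
    delta = cat(sprintf("  u0 = %g, v0 = %g\n", x$u0, x$v0)),
    gaussian = cat(sprintf("  etaE = %g, etaI = %g\n", x$etaE, x$etaI)),
    mixture = cat(sprintf("  %d components, weights %s\n",
                          length(x$alpha),
                          paste(signif(x$alpha, 4), collapse = ", "))),
    product_binomial = cat(sprintf("  p0 = %g, q0 = %g\n", x$p0, x$q0))
  )
  invisible(x)
}

# Mean cargo per carrier implied by a continuum initial condition.
ic_mean_total <- function(ic, model) {
  switch(ic$kind,
    delta = ic$v0,
    gaussian = ic$etaE + ic$etaI,
    mixture = sum(ic$alpha * (ic$etaE + ic$etaI)),
    product_binomial = ic$p0 * model$mE + ic$q0 * model$mI
  )
}

# Validate that the initial condition carries M/N cargo per carrier.
check_ic_total <- function(ic, model, tol = 1e-9) {
  mn <- model$M / model$N
  tot <- ic_mean_total(ic, model)
  if (abs(tot - mn) > tol * max(1, mn))
    stop(sprintf(
      "initial condition implies %.6g cargo per carrier but M/N = %.6g",
      tot, mn), call. = FALSE)
  invisible(TRUE)
}

# Gaussian-mixture representation of a continuum ic in the (u, v) chart.
# Components are bivariate normal densities (possibly degenerate, zero
# covariance for deltas) with weights summing to 2N, so that
# (1/2) \int\int ytilde du dv = N.
ic_uv_mixture <- function(ic, model) {
  N <- model$N
  comp <- switch(ic$kind,
    delta = data.frame(w = 2 * N, mu = ic$u0, mv = ic$v0,
                       cuu = 0, cuv = 0, cvv = 0),
    gaussian = {
      eE <- ic$etaE; eI <- ic$etaI
      data.frame(w = 2 * N, mu = eE - eI, mv = eE + eI,
                 cuu = eE + eI, cuv = eE - eI, cvv = eE + eI)
    },
    mixture = {
      eE <- ic$etaE; eI <- ic$etaI
      data.frame(w = 2 * N * ic$alpha, mu = eE - eI, mv = eE + eI,
                 cuu = eE + eI, cuv = eE - eI, cvv = eE + eI)
    },
    stop("initial condition kind '", ic$kind,
         "' has no continuum representation", call. = FALSE)
  )
  new_field(comp, chart = "uv", t = 0, model = model)
}

#' Conserved cargo-total marginal f(v)
#'
#' The marginal `f(v) = integral of ytilde(u, v, t) du` over carriers with
#' total cargo `v = x + z` is invariant under intra-carrier transfer and is
#' normalised as `(1/2) integral f(v) dv = N`. For the supported initial
#' conditions it is a Gaussian mixture in `v` (a delta for `ic_delta`).
#'
#' @param ic A continuum initial condition (see [initial_conditions]).
#' @param model A [carrier_model()].
#' @return Object of class `v_marginal`: data frame of components
#'   (`w`, `m`, `s2`) with weights summing to `2N`; callable through
#'   [f_density()].
#' @export
f_of_v <- function(ic, model) {
  fld <- ic_uv_mixture(ic, model)
  comp <- fld$comp
  structure(list(comp = data.frame(w = comp$w, m = comp$mv, s2 = comp$cvv),
                 model = model),
            class = "v_marginal")
}

#' Evaluate a cargo-total marginal
#'
#' @param f A `v_marginal` from [f_of_v()].
#' @param v Numeric vector of evaluation points.
#' @return `f(v)` values. Degenerate (delta) components contribute only
#'   through integrals and raise an error on pointwise evaluation.
#' @export
f_density <- function(f, v) {
  stopifnot(inherits(f, "v_marginal"))
  comp <- f$comp
  if (any(comp$s2 == 0))
    stop("pointwise evaluation of a delta marginal is undefined",
         call. = FALSE)
  out <- numeric(length(v))
  for (k in seq_len(nrow(comp)))
    out <- out + comp$w[k] * stats::dnorm(v, comp$m[k], sqrt(comp$s2[k]))
  out
}
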