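#' Two-compartment carrier model
#'
#' Constructs the parameter object for an ensemble of `N` nanocarriers, each
#' with an external compartment of `mE` identical binding sites and an internal
#' compartment of `mI` sites. Cargo items (at most one per site) migrate between
#' the two compartments of a carrier with first-order rate constants `KEI`
#' (external to internal) and `KIE` (internal to external); there is no
#' cargo exchange between different carriers, so the total cargo `i + n` of
#' every carrier is an invariant of the dynamics.
#'
#' The relaxation of the compartment totals is governed by the characteristic
#' time `tau = 1/(KEI + KIE)`. At equilibrium the mean cargo per carrier splits
#' into `muE = (M/N) KIE/(KEI+KIE)` external and `muI = (M/N) KEI/(KEI+KIE)`
#' internal items, with `muE + muI = M/N` exactly.
#'
#' @param mE,mI Site counts of the external and internal compartment. Positive
#'   integers, or `Inf` for continuum (Fokker-Planck) work where only the mean
#'   occupancies matter.
#' @param KEI,KIE Transfer rate constants (1/time), both strictly positive.
#' @param N Number of carriers (positive integer).
#' @param M Total number of cargo items across the ensemble (non-negative;
#'   at most `N*(mE+mI)` when the site counts are finite).
#' @return An object of class `carrier_model`.
#' @examples
#' m <- carrier_model(mE = 8, mI = 5, KEI = 1, KIE = 1, N = 100, M = 300)
#' coef(m)
#' @export
carrier_model <- function(mE, mI, KEI, KIE, N, M) {
  stopifnot(length(mE) == 1, length(mI) == 1, length(KEI) == 1,
            length(KIE) == 1, length(N) == 1, length(M) == 1)
  if (!is.numeric(KEI) || !is.numeric(KIE) || KEI <= 0 || KIE <= 0)
    stop("rate constants KEI and KIE must be strictly positive", call. = FALSE)
  if (!is.numeric(N) || N < 1 || N != round(N))
    stop("N must be a positive integer", call. = FALSE)
  if (!is.numeric(M) || M < 0)
    stop("M must be non-negative", call. = FALSE)
  for (m in list(mE, mI))
    if (!is.numeric(m) || m <= 0 || (is.finite(m) && m != round(m)))
      stop("site counts mE, mI must be positive integers or Inf", call. = FALSE)
  if (is.finite(mE) && is.finite(mI) && M > N * (mE + mI))
    stop("M exceeds the total site capacity N*(mE+mI)", call. = FALSE)
  structure(
    list(mE = mE, mI = mI, KEI = KEI, KIE = KIE, N = N, M = M),
    class = "carrier_model"
  )
}

#' Derived equilibrium quantities
#'
#' Characteristic time and equilibrium per-carrier compartment means,
#' `tau = 1/(KEI+KIE)`, `muE = (M/N) KIE/(KEI+KIE)`,
#' `muI = (M/N) KEI/(KEI+KIE)`.
#'
#' @param model A [carrier_model()].
#' @return Named list with `tau`, `muE`, `muI`.
#' @export
derived_quantities <- function(model) {
  stopifnot(inherits(model, "carrier_model"))
  K <- model$KEI + model$KIE
  mn <- model$M / model$N
  muE <- mn * model$KIE / K
  # complement, so that muE + muI == M/N holds to the last bit
  list(tau = 1 / K, muE = muE, muI = mn - muE)
}

#' @export
print.carrier_model <- function(x, ...) {
  d <- derived_quantities(x)
  cat("Two-compartment carrier model\n")
  cat(sprintf("  sites: mE = %s (external), mI = %s (internal)\n",
              format(x$mE), format(x$mI)))
  cat(sprintf("  rates: KEI = %g, KIE = %g  (tau = %g)\n",
              x$KEI, x$KIE, d$tau))
  cat(sprintf("  ensemble: N = %g carriers, M = %g cargo (M/N = %g)\n",
              x$N, x$M, x$M / x$N))
  cat(sprintf("  equilibrium means per carrier: muE = %g, muI = %g\n",
              d$muE, d$muI))
  invisible(x)
}

#' @export
summary.carrier_model <- function(object, ...) {
  d <- derived_quantities(object)
  occ <- NULL
  if (is.finite(object$mE) && is.finite(object$mI) &&
      object$M > 0 && object$M < object$N * (object$mE + object$mI))
    occ <- solve_pq(object)
  out <- c(object, d, occ)
  class(out) <- "summary.carrier_model"
  out
}

#' @export
print.summary.carrier_model <- function(x, ...) {
  cls <- x; class(cls) <- "carrier_model"
  print.carrier_model(cls)
  if (!is.null(x$p))
    cat(sprintf("  equilibrium site occupancies: p = %.6g, q = %.6g\n",
                x$p, x$q))
  invisible(x)
}

#' @export
coef.carrier_model <- function(object, ...) {
  d <- derived_quantities(object)
  out <- c(KEI = object$KEI, KIE = object$KIE, tau = d$tau,
           muE = d$muE, muI = d$muI)
  if (is.finite(object$mE) && is.finite(object$mI) &&
      object$M > 0 && object$M < object$N * (object$mE + object$mI)) {
    pq <- solve_pq(object)
    out <- c(out, p = pq$p, q = pq$q)
  }
  out
}

#' Analytic first moments of the compartment totals
#'
#' Exponential relaxation of the per-carrier compartment means from initial
#' values `(etaE, etaI)` toward `(muE, muI)`:
#' `ME(t)/N = muE + exp(-t/tau) (etaE - muE)` and analogously for `MI`.
#' Exact in the limit of large site counts or when `KEI*mE == KIE*mI`
#' (otherwise the correlation term of the moment hierarchy does not close).
#'
#' @param model A [carrier_model()].
#' @param t Time(s), non-negative.
#' @param etaE,etaI Initial per-carrier means; must satisfy
#'   `etaE + etaI == M/N` (within `tol`).
#' @param tol Tolerance for the initial-condition consistency check.
#' @return Data frame with columns `t`, `ME_over_N`, `MI_over_N`.
#' @export
first_moments <- function(model, t, etaE, etaI, tol = 1e-9) {
  stopifnot(inherits(model, "carrier_model"), all(t >= 0),
            etaE >= 0, etaI >= 0)
  mn <- model$M / model$N
  if (abs(etaE + etaI - mn) > tol * max(1, mn))
    stop("inconsistent initial condition: etaE + etaI must equal M/N",
         call. = FALSE)
  d <- derived_quantities(model)
  e <- exp(-t / d$tau)
  data.frame(t = t,
             ME_over_N = d$muE + e * (etaE - d$muE),
             MI_over_N = d$muI + e * (etaI - d$muI))
}

#' Equilibrium site-occupation probabilities from detailed balance
#'
#' Solves the pair of equilibrium conditions
#' `mE KEI p (1-q) = mI KIE (1-p) q` (detailed balance) and
#' `p mE + q mI = M/N` (cargo conservation) for the probabilities that a given
#' external (`p`) or internal (`q`) site is occupied at equilibrium.
#' Eliminating `q = a p / (b + (a-b) p)` with `a = mE KEI`, `b = mI KIE`
#' reduces the system to a quadratic in `p`; the root inside (0,1) is selected
#' and polished by Newton iteration on the conservation residual.
#'
#' In the joint limit of large `mE`, `mI` at fixed `M/N` the solution
#' approaches `p mE -> muE`, `q mI -> muI`.
#'
#' @param model A [carrier_model()] with finite site counts and
#'   `0 < M < N*(mE+mI)`.
#' @return List with elements `p` and `q`, both in (0,1).
#' @export
solve_pq <- function(model) {
  stopifnot(inherits(model, "carrier_model"))
  mE <- model$mE; mI <- model$mI
  if (!is.finite(mE) || !is.finite(mI))
    stop("solve_pq requires finite site counts", call. = FALSE)
  mn <- model$M / model$N
  if (model$M <= 0 || model$M >= model$N * (mE + mI))
    stop("boundary occupancy: need 0 < M < N*(mE+mI) for p, q in (0,1)",
         call. = FALSE)
  a <- mE * model$KEI
  b <- mI * model$KIE
  qp <- function(p) a * p / (b + (a - b) * p)
  h  <- function(p) p * mE + qp(p) * mI - mn
  if (a == b) {
    p <- mn / (mE + mI)
  } else {
    # (a-b) mE p^2 + [b mE + a mI - (M/N)(a-b)] p - (M/N) b = 0
    A <- (a - b) * mE
    B <- b * mE + a * mI - mn * (a - b)
    C <- -mn * b
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("no real detailed-balance root", call. = FALSE)
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    ok <- roots > 0 & roots < 1 & qp(roots) > 0 & qp(roots) < 1
    if (sum(ok) == 0)
      stop("no detailed-balance root inside (0,1)^2", call. = FALSE)
    if (sum(ok) > 1)
      stop("degenerate detailed-balance system: two interior roots",
           call. = FALSE)
    p <- roots[ok]
  }
  # Newton polish of the conservation residual; detailed balance is satisfied
  # identically through q(p).
  for (it in 1:3) {
    dq <- a * b / (b + (a - b) * p)^2
    p <- p - h(p) / (mE + mI * dq)
  }
  list(p = p, q = qp(p))
}
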