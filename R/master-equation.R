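#' Combinatorial transfer factors
#'
#' Occupancy-dependent multipliers of the two transfer channels. A carrier in
#' state `(i, n)` loses external cargo at rate `KEI * i * (1 - n/mI)` (one of
#' `i` items moves, provided a vacant internal site exists) and internal cargo
#' at rate `KIE * n * (1 - i/mE)`. Transfer into a completely filled
#' compartment is impossible: the factor vanishes at `n = mI` (resp.
#' `i = mE`). Infinite site counts give the unsaturated factors `i` and `n`.
#'
#' @param i,n Occupancies of the external and internal compartment
#'   (vectorised; each within `0..mE`, `0..mI`).
#' @param model A [carrier_model()].
#' @return The dimensionless rate multiplier.
#' @name transfer_factors
NULL

#' @rdname transfer_factors
#' @export
factor_ei <- function(i, n, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(i < 0 | i > model$mE) || any(n < 0 | n > model$mI))
    stop("occupancy indices out of range", call. = FALSE)
  if (is.finite(model$mI)) i * (1 - n / model$mI) else i + 0 * n
}

#' @rdname transfer_factors
#' @export
factor_ie <- function(n, i, model) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(i < 0 | i > model$mE) || any(n < 0 | n > model$mI))
    stop("occupancy indices out of range", call. = FALSE)
  if (is.finite(model$mE)) n * (1 - i / model$mE) else n + 0 * i
}

# ---- occupancy container ----------------------------------------------------

#' Carrier occupancy distribution
#'
#' A matrix `y[i, n]` of carrier counts over the discrete state grid, possibly
#' restricted to a truncation window `i = i0..i0+nrow-1`, `n = n0..n0+ncol-1`.
#'
#' @param y Numeric matrix of carrier counts (entries `>= 0`).
#' @param model A [carrier_model()] with finite site counts.
#' @param t Time stamp.
#' @param i0,n0 Occupancies of the first row/column (0 for a full grid).
#' @return An object of class `occupancy`.
#' @export
occupancy <- function(y, model, t = 0, i0 = 0L, n0 = 0L) {
  stopifnot(inherits(model, "carrier_model"), is.matrix(y),
            is.finite(model$mE), is.finite(model$mI),
            i0 >= 0, n0 >= 0,
            i0 + nrow(y) - 1 <= model$mE, n0 + ncol(y) - 1 <= model$mI)
  structure(list(y = y, model = model, t = t, i0 = as.integer(i0),
                 n0 = as.integer(n0)),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("Occupancy distribution at t = %g: %d x %d states (i = %d..%d, n = %d..%d)\n",
              x$t, nrow(x$y), ncol(x$y), x$i0, x$i0 + nrow(x$y) - 1,
              x$n0, x$n0 + ncol(x$y) - 1))
  cat(sprintf("  carriers = %.6g, cargo (ME, MI) = (%.6g, %.6g)\n",
              sum(x$y), moments_discrete(x)$ME, moments_discrete(x)$MI))
  invisible(x)
}

i_values <- function(occ) occ$i0 + seq_len(nrow(occ$y)) - 1L
n_values <- function(occ) occ$n0 + seq_len(ncol(occ$y)) - 1L

#' Discrete state for an initial condition
#'
#' Realises an initial condition on the `(i, n)` grid of a finite model:
#' `ic_binomial` gives the product-binomial ensemble
#' `y[i,n] = N Binom(mE, i; p0) Binom(mI, n; q0)`; `ic_delta` places all `N`
#' carriers in the single state `(x0, z0) = ((v0+u0)/2, (v0-u0)/2)` (which
#' must be integer).
#'
#' @param ic An initial condition.
#' @param model A [carrier_model()] with finite `mE`, `mI`.
#' @param window Optional `truncation_window()`; when supplied the state is
#'   restricted to it.
#' @return An `occupancy`.
#' @export
discrete_state <- function(ic, model, window = NULL) {
  stopifnot(inherits(ic, "cargo_ic"), inherits(model, "carrier_model"),
            is.finite(model$mE), is.finite(model$mI))
  if (is.null(window)) {
    ii <- 0:model$mE; nn <- 0:model$mI; i0 <- 0L; n0 <- 0L
  } else {
    ii <- window$iLo:window$iHi; nn <- window$nLo:window$nHi
    i0 <- window$iLo; n0 <- window$nLo
  }
  y <- switch(ic$kind,
    product_binomial = {
      check_ic_total(ic, model)
      model$N * outer(stats::dbinom(ii, model$mE, ic$p0),
                      stats::dbinom(nn, model$mI, ic$q0))
    },
    delta = {
      x0 <- (ic$v0 + ic$u0) / 2; z0 <- (ic$v0 - ic$u0) / 2
      if (x0 != round(x0) || z0 != round(z0))
        stop("delta initial state must sit on integer (i, n)", call. = FALSE)
      y <- matrix(0, length(ii), length(nn))
      y[match(x0, ii), match(z0, nn)] <- model$N
      y
    },
    stop("no discrete realisation for initial condition kind '",
         ic$kind, "'", call. = FALSE)
  )
  occupancy(y, model, t = 0, i0 = i0, n0 = n0)
}

# ---- right-hand side --------------------------------------------------------

# core operator on a plain matrix over i = ii, n = nn (absolute occupancies)
rhs_core <- function(Y, ii, nn, model) {
  gEI <- model$KEI * outer(ii, nn, function(i, n) i * (1 - n / model$mI))
  gIE <- model$KIE * outer(ii, nn, function(i, n) n * (1 - i / model$mE))
  F1 <- gEI * Y   # (i, n) -> (i-1, n+1)
  F2 <- gIE * Y   # (i, n) -> (i+1, n-1)
  R <- -F1 - F2
  ni <- length(ii); nj <- length(nn)
  if (ni > 1 && nj > 1) {
    R[1:(ni - 1), 2:nj] <- R[1:(ni - 1), 2:nj] + F1[2:ni, 1:(nj - 1)]
    R[2:ni, 1:(nj - 1)] <- R[2:ni, 1:(nj - 1)] + F2[1:(ni - 1), 2:nj]
  }
  R
}

#' Master-equation right-hand side
#'
#' The chemical master equation for the carrier population numbers: state
#' `(i, n)` exchanges probability flux with `(i-1, n+1)` (external-to-internal
#' transfer at rate `KEI * factor_ei`) and `(i+1, n-1)` (the reverse channel
#' at rate `KIE * factor_ie`). Both channels conserve the carrier count and
#' every anti-diagonal subpopulation `S_v` exactly; the returned matrix sums
#' to zero along each anti-diagonal.
#'
#' @param occ An [occupancy()].
#' @return Matrix of time derivatives, same shape and indexing as `occ$y`.
#' @export
master_rhs <- function(occ) {
  stopifnot(inherits(occ, "occupancy"))
  rhs_core(occ$y, i_values(occ), n_values(occ), occ$model)
}

# ---- conserved quantities ---------------------------------------------------

#' Anti-diagonal subpopulation sizes
#'
#' `S_v = sum_i y[i, v - i]`, the number of carriers holding exactly `v` cargo
#' items in total. Because transfer is intra-carrier only, every `S_v` is a
#' constant of the motion.
#'
#' @param occ An [occupancy()] (or plain matrix on the full grid).
#' @return Named numeric vector over `v = 0..mE+mI` (full grid) or the window
#'   range.
#' @export
antidiagonal_sums <- function(occ) {
  stopifnot(inherits(occ, "occupancy"))
  Y <- occ$y
  v <- as.vector(outer(i_values(occ), n_values(occ), "+"))
  s <- rowsum(as.vector(Y), group = v)
  out <- as.vector(s)
  names(out) <- rownames(s)
  out
}

#' First moments of a discrete distribution
#'
#' `ME = sum i y[i,n]`, `MI = sum n y[i,n]`; their sum is the conserved total
#' cargo `M`.
#'
#' @param occ An [occupancy()].
#' @return List with `ME`, `MI`.
#' @export
moments_discrete <- function(occ) {
  stopifnot(inherits(occ, "occupancy"))
  list(ME = sum(i_values(occ) * rowSums(occ$y)),
       MI = sum(n_values(occ) * colSums(occ$y)))
}

# ---- equilibrium ------------------------------------------------------------

#' Discrete equilibrium distribution
#'
#' Within each subpopulation of carriers with total cargo `v = i + n` the
#' stationary state of the master equation is the product-binomial law
#' conditioned on `i + n = v`:
#' `y_eq[i, n] = g(i+n) Binom(mE, i; p) Binom(mI, n; q)`, where `(p, q)` come
#' from detailed balance ([solve_pq()]) and the per-anti-diagonal constant
#' `g(v) = S_v / sum_i Binom(mE, i; p) Binom(mI, v-i; q)` is fixed by the
#' conserved subpopulation sizes `S_v` (computed in log space to avoid
#' underflow on large grids).
#'
#' @param S Vector of anti-diagonal sums, named by `v` (as returned by
#'   [antidiagonal_sums()]) or unnamed of length `mE + mI + 1`.
#' @param model A [carrier_model()] with finite site counts.
#' @param occ_pq Optional list `(p, q)`; defaults to [solve_pq()].
#' @return An `occupancy` on the full grid with `t = Inf`.
#' @export
equilibrium_discrete <- function(S, model, occ_pq = solve_pq(model)) {
  stopifnot(inherits(model, "carrier_model"),
            is.finite(model$mE), is.finite(model$mI))
  mE <- model$mE; mI <- model$mI
  if (is.null(names(S))) {
    if (length(S) != mE + mI + 1)
      stop("unnamed S must have length mE + mI + 1", call. = FALSE)
    names(S) <- 0:(mE + mI)
  }
  if (abs(sum(S) - model$N) > 1e-8 * model$N)
    stop("anti-diagonal sums must total N", call. = FALSE)
  lbE <- stats::dbinom(0:mE, mE, occ_pq$p, log = TRUE)
  lbI <- stats::dbinom(0:mI, mI, occ_pq$q, log = TRUE)
  L <- outer(lbE, lbI, "+")
  v <- as.vector(outer(0:mE, 0:mI, "+"))
  # log-sum-exp of the binomial mass on each anti-diagonal
  lmax <- tapply(as.vector(L), v, max)
  esum <- rowsum(exp(as.vector(L) - lmax[as.character(v)]), group = v)
  logB <- lmax + log(as.vector(esum))
  lg <- rep(-Inf, mE + mI + 1)
  names(lg) <- 0:(mE + mI)
  pos <- names(S)[S > 0]
  if (any(!is.finite(logB[pos])))
    stop("anti-diagonal binomial mass underflows for an occupied v",
         call. = FALSE)
  lg[pos] <- log(S[pos]) - logB[pos]
  Y <- matrix(exp(as.vector(L) + lg[as.character(v)]), mE + 1, mI + 1)
  occupancy(Y, model, t = Inf)
}

# ---- truncation -------------------------------------------------------------

#' State-space truncation window
#'
#' Index bounds containing essentially all carrier mass over the whole
#' trajectory. The window covers the initial and the equilibrium marginal
#' means (between which the means relax monotonically) extended by
#' `k` standard deviations, with `k` chosen so that the Gaussian tail bound
#' `2 pnorm(-k)` is below `epsilon`; the reported `massBound` is the exact
#' initial mass outside the window.
#'
#' Truncation makes the grid cost depend on the cargo scale `M/N`, not on the
#' site counts, so large-`m` configurations integrate at desk scale.
#'
#' @param ic Initial condition with a discrete realisation.
#' @param model A [carrier_model()] with finite site counts.
#' @param epsilon Neglected-mass target (fraction of `N`).
#' @return List of class `truncation_window`: `iLo`, `iHi`, `nLo`, `nHi`,
#'   `massBound`.
#' @export
truncation_window <- function(ic, model, epsilon = 1e-12) {
  stopifnot(inherits(ic, "cargo_ic"), inherits(model, "carrier_model"),
            is.finite(model$mE), is.finite(model$mI), epsilon > 0)
  d <- derived_quantities(model)
  stats0 <- switch(ic$kind,
    product_binomial = list(
      mi = ic$p0 * model$mE, si = sqrt(model$mE * ic$p0 * (1 - ic$p0)),
      mn = ic$q0 * model$mI, sn = sqrt(model$mI * ic$q0 * (1 - ic$q0))),
    delta = list(mi = (ic$v0 + ic$u0) / 2, si = 0,
                 mn = (ic$v0 - ic$u0) / 2, sn = 0),
    gaussian = list(mi = ic$etaE, si = sqrt(ic$etaE),
                    mn = ic$etaI, sn = sqrt(ic$etaI)),
    stop("unsupported initial condition kind", call. = FALSE)
  )
  k <- max(8, -stats::qnorm(epsilon / 8)) + 2
  # Poisson widths sqrt(mean) bound the binomial ones from above
  si <- max(stats0$si, sqrt(max(stats0$mi, d$muE)))
  sn <- max(stats0$sn, sqrt(max(stats0$mn, d$muI)))
  iLo <- max(0, floor(min(stats0$mi, d$muE) - k * si))
  iHi <- min(model$mE, ceiling(max(stats0$mi, d$muE) + k * si))
  nLo <- max(0, floor(min(stats0$mn, d$muI) - k * sn))
  nHi <- min(model$mI, ceiling(max(stats0$mn, d$muI) + k * sn))
  massBound <- switch(ic$kind,
    product_binomial = 1 -
      (stats::pbinom(iHi, model$mE, ic$p0) -
         stats::pbinom(iLo - 1, model$mE, ic$p0)) *
      (stats::pbinom(nHi, model$mI, ic$q0) -
         stats::pbinom(nLo - 1, model$mI, ic$q0)),
    delta = 0,
    gaussian = 1 -
      (stats::pnorm(iHi + 0.5, stats0$mi, max(stats0$si, 1e-12)) -
         stats::pnorm(iLo - 0.5, stats0$mi, max(stats0$si, 1e-12))) *
      (stats::pnorm(nHi + 0.5, stats0$mn, max(stats0$sn, 1e-12)) -
         stats::pnorm(nLo - 0.5, stats0$mn, max(stats0$sn, 1e-12)))
  )
  structure(list(iLo = iLo, iHi = iHi, nLo = nLo, nHi = nHi,
                 massBound = massBound, epsilon = epsilon),
            class = "truncation_window")
}

# ---- integration ------------------------------------------------------------

#' Integrate the master equation
#'
#' Adaptive ODE integration of the linear master equation. The state may be a
#' full-grid or windowed `occupancy`, or an initial condition (in which case a
#' truncation window is computed automatically when the full grid exceeds
#' `full_grid_max` cells). Carrier number, cargo and all anti-diagonal sums
#' are conserved by the operator; the integrator preserves them to
#' `O(10 * rtol)`.
#'
#' @param y0 An [occupancy()] or a `cargo_ic` with a discrete realisation.
#' @param times Non-decreasing times starting at the state's `t` (typically
#'   0).
#' @param model A [carrier_model()] with finite site counts.
#' @param rtol,atol Integrator tolerances; `atol` defaults to `1e-12 * N`.
#' @param method `deSolve` method; the default non-stiff Adams scheme suits
#'   the mildly stiff linear operator at these tolerances.
#' @param epsilon Truncation neglected-mass target (used only when a window
#'   is computed automatically).
#' @param full_grid_max Cell-count threshold above which truncation is
#'   applied to `cargo_ic` inputs.
#' @param maxsteps Maximum internal integrator steps between output times.
#' @return List of `occupancy` objects, one per requested time. Entries are
#'   clipped to be non-negative on output.
#' @export
master_integrate <- function(y0, times, model, rtol = 1e-8, atol = NULL,
                             method = "adams", epsilon = 1e-12,
                             full_grid_max = 1e6, maxsteps = 50000) {
  stopifnot(inherits(model, "carrier_model"),
            is.finite(model$mE), is.finite(model$mI),
            !is.unsorted(times), times[1] >= 0)
  if (inherits(y0, "cargo_ic")) {
    window <- NULL
    if ((model$mE + 1) * (model$mI + 1) > full_grid_max)
      window <- truncation_window(y0, model, epsilon)
    y0 <- discrete_state(y0, model, window)
  }
  stopifnot(inherits(y0, "occupancy"))
  if (is.null(atol)) atol <- 1e-12 * model$N
  ii <- i_values(y0); nn <- n_values(y0)
  ni <- length(ii); nj <- length(nn)
  f <- function(t, y, parms) {
    list(as.vector(rhs_core(matrix(y, ni, nj), ii, nn, model)))
  }
  tt <- times
  if (length(tt) == 1 && tt == y0$t)
    return(list(occupancy(pmax(y0$y, 0), model, t = y0$t,
                          i0 = y0$i0, n0 = y0$n0)))
  prepend <- FALSE
  if (tt[1] > 0) { tt <- c(0, tt); prepend <- TRUE }
  sol <- deSolve::ode(as.vector(y0$y), tt, f, NULL, method = method,
                      rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (attr(sol, "istate")[1] < 0)
    stop("master-equation integration failed to converge (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  rows <- seq_len(nrow(sol))
  if (prepend) rows <- rows[-1]
  out <- lapply(rows, function(k) {
    Y <- matrix(pmax(sol[k, -1], 0), ni, nj)
    occupancy(Y, model, t = sol[k, 1], i0 = y0$i0, n0 = y0$n0)
  })
  out
}
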