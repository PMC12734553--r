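#' Sample an initial carrier ensemble
#'
#' Draws `ncarriers` independent carriers from an initial condition for the
#' exact stochastic (Gillespie) simulator. Delta conditions give identical
#' carriers; product-binomial draws independent binomial occupancies;
#' Gaussian/mixture conditions are discretised by rounding to the nearest
#' integer and clipping to `[0, m]` (an approximation used only for oracle
#' comparisons against the continuum solution).
#'
#' @param ic An initial condition ([initial_conditions]).
#' @param model A [carrier_model()].
#' @param ncarriers Number of carriers to draw (defaults to `model$N`).
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return Object of class `carrier_ensemble`: integer vectors `i`, `n`, time
#'   `t`, and the model.
#' @export
ssa_sample_initial <- function(ic, model, ncarriers = model$N, seed = NULL) {
  stopifnot(inherits(ic, "cargo_ic"), inherits(model, "carrier_model"),
            ncarriers >= 1)
  if (!is.null(seed)) set.seed(seed)
  clip <- function(x, m) pmin(pmax(round(x), 0), if (is.finite(m)) m else Inf)
  draw_gauss <- function(nc, eE, eI) {
    list(i = clip(stats::rnorm(nc, eE, sqrt(eE)), model$mE),
         n = clip(stats::rnorm(nc, eI, sqrt(eI)), model$mI))
  }
  st <- switch(ic$kind,
    delta = {
      x0 <- (ic$v0 + ic$u0) / 2; z0 <- (ic$v0 - ic$u0) / 2
      stopifnot(x0 == round(x0), z0 == round(z0))
      list(i = rep(x0, ncarriers), n = rep(z0, ncarriers))
    },
    product_binomial = list(i = stats::rbinom(ncarriers, model$mE, ic$p0),
                            n = stats::rbinom(ncarriers, model$mI, ic$q0)),
    gaussian = draw_gauss(ncarriers, ic$etaE, ic$etaI),
    mixture = {
      k <- sample.int(length(ic$alpha), ncarriers, replace = TRUE,
                      prob = ic$alpha)
      g <- draw_gauss(ncarriers, ic$etaE[k], ic$etaI[k])
      g
    }
  )
  structure(list(i = as.numeric(st$i), n = as.numeric(st$n), t = 0,
                 model = model),
            class = "carrier_ensemble")
}

#' @export
print.carrier_ensemble <- function(x, ...) {
  cat(sprintf("Carrier ensemble: %d carriers at t = %g\n", length(x$i), x$t))
  cat(sprintf("  mean (i, n) = (%.4g, %.4g)\n", mean(x$i), mean(x$n)))
  invisible(x)
}

#' Exact stochastic simulation of intra-carrier transfer
#'
#' Direct-method Gillespie simulation of the two-reaction jump process per
#' carrier, with propensities `a_EI = KEI i (1 - n/mI)` and
#' `a_IE = KIE n (1 - i/mE)`. Carriers are independent, so the ensemble is
#' advanced in a synchronised vectorised event loop; each carrier's total
#' `i + n` is conserved exactly (integer arithmetic). Runs are reproducible
#' for a fixed `(seed, ncarriers, model)`.
#'
#' @param state A `carrier_ensemble` from [ssa_sample_initial()].
#' @param t_end Final time, `>= state$t`.
#' @param seed Optional integer seed.
#' @return The ensemble advanced to `t_end`.
#' @export
ssa_run <- function(state, t_end, seed = NULL) {
  stopifnot(inherits(state, "carrier_ensemble"), t_end >= state$t)
  if (!is.null(seed)) set.seed(seed)
  model <- state$model
  i <- state$i; n <- state$n
  t <- rep(state$t, length(i))
  active <- seq_along(i)
  fEI <- function(i, n) if (is.finite(model$mI)) i * (1 - n / model$mI) else i
  fIE <- function(n, i) if (is.finite(model$mE)) n * (1 - i / model$mE) else n
  while (length(active) > 0) {
    aEI <- model$KEI * fEI(i[active], n[active])
    aIE <- model$KIE * fIE(n[active], i[active])
    a0 <- aEI + aIE
    live <- a0 > 0
    if (!any(live)) break
    act <- active[live]
    dt <- stats::rexp(length(act)) / a0[live]
    tn <- t[act] + dt
    fire <- tn <= t_end
    t[act] <- pmin(tn, t_end)
    hit <- act[fire]
    if (length(hit) > 0) {
      toI <- stats::runif(length(hit)) * (aEI + aIE)[live][fire] <
        aEI[live][fire]
      i[hit] <- i[hit] - ifelse(toI, 1, -1)
      n[hit] <- n[hit] + ifelse(toI, 1, -1)
    }
    active <- hit
  }
  structure(list(i = i, n = n, t = t_end, model = model),
            class = "carrier_ensemble")
}

#' Empirical moments of a carrier ensemble
#'
#' Plug-in moment estimates in both charts with standard errors. Means carry
#' the usual `sd/sqrt(nc)` error; variance standard errors use the
#' fourth-moment (delta-method / delete-1 jackknife) formula
#' `sqrt((m4 - s^4 (nc-3)/(nc-1)) / nc)`.
#'
#' @param state A `carrier_ensemble`.
#' @return One-row data frame: `t`, `ME_over_N`, `MI_over_N`, `mean_u`,
#'   `mean_v`, `var_u`, `var_v` and `se_*` columns.
#' @export
empirical_moments <- function(state) {
  stopifnot(inherits(state, "carrier_ensemble"))
  u <- state$i - state$n; v <- state$i + state$n
  nc <- length(u)
  se_mean <- function(x) stats::sd(x) / sqrt(nc)
  se_var <- function(x) {
    m <- mean(x); s2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
    sqrt(max(m4 - s2^2 * (nc - 3) / (nc - 1), 0) / nc)
  }
  pvar <- function(x) mean((x - mean(x))^2)
  data.frame(t = state$t,
             ME_over_N = mean(state$i), MI_over_N = mean(state$n),
             mean_u = mean(u), mean_v = mean(v),
             var_u = pvar(u), var_v = pvar(v),
             se_ME = se_mean(state$i), se_MI = se_mean(state$n),
             se_mean_u = se_mean(u), se_var_u = se_var(u),
             se_var_v = se_var(v))
}

#' Histogram of a carrier ensemble over the state grid
#'
#' @param state A `carrier_ensemble` with a finite-grid model.
#' @return An [occupancy()] holding carrier counts (summing to the ensemble
#'   size).
#' @export
ensemble_occupancy <- function(state) {
  stopifnot(inherits(state, "carrier_ensemble"))
  model <- state$model
  stopifnot(is.finite(model$mE), is.finite(model$mI))
  Y <- matrix(0, model$mE + 1, model$mI + 1)
  tab <- table(factor(state$i, levels = 0:model$mE),
               factor(state$n, levels = 0:model$mI))
  Y[] <- as.numeric(tab)
  occupancy(Y, model, t = state$t)
}

#' Simulate a carrier ensemble from the model
#'
#' Convenience wrapper combining [ssa_sample_initial()] and [ssa_run()],
#' following the base-R `simulate` generic.
#'
#' @param object A [carrier_model()].
#' @param nsim Number of carriers (defaults to `object$N`).
#' @param seed Integer seed.
#' @param ic Initial condition (default: all cargo external, delta at
#'   `u = v = M/N` when integer).
#' @param t_end Final time.
#' @param ... Unused.
#' @return A `carrier_ensemble` at `t_end`.
#' @export
simulate.carrier_model <- function(object, nsim = object$N, seed = NULL,
                                   ic = NULL, t_end = 1, ...) {
  if (is.null(ic)) {
    mn <- object$M / object$N
    ic <- ic_delta(u0 = mn, v0 = mn)
  }
  st <- ssa_sample_initial(ic, object, ncarriers = nsim, seed = seed)
  ssa_run(st, t_end)
}
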