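#' Closed-form moment trajectories
#'
#' Evaluates the analytic moment algebra for a continuum initial condition:
#' compartment means from the exponential relaxation law, `<u>` and `<u^2>`
#' from the Green's-function moments, the conserved `<v>` and `var_v`, and
#' the variances.
#'
#' @param object A [carrier_model()].
#' @param times Non-negative times.
#' @param ic A continuum initial condition (default: the delta start with all
#'   cargo external).
#' @param ... Unused.
#' @return Data frame with columns `t`, `ME_over_N`, `MI_over_N`, `mean_u`,
#'   `mean_v`, `var_u`, `var_v`.
#' @export
predict.carrier_model <- function(object, times = seq(0, 5, by = 0.1),
                                  ic = NULL, ...) {
  stopifnot(all(times >= 0))
  mn <- object$M / object$N
  if (is.null(ic)) ic <- ic_delta(u0 = mn, v0 = mn)
  check_ic_total(ic, object)
  m0 <- field_moments(ic_uv_mixture(ic, object))
  mu <- mean_u(times, object,
               etaE = (m0$mean_v + m0$mean_u) / 2,
               etaI = (m0$mean_v - m0$mean_u) / 2)
  m2u <- second_moment_u(times, object, m0$m2_u, m0$m11, m0$m2_v)
  data.frame(t = times,
             ME_over_N = (mn + mu) / 2,
             MI_over_N = (mn - mu) / 2,
             mean_u = mu, mean_v = mn,
             var_u = m2u - mu^2,
             var_v = m0$m2_v - mn^2)
}

#' Plot moment trajectories of a carrier model
#'
#' Draws the compartment means `ME(t)/N`, `MI(t)/N` (and optionally the
#' variance `var_u(t)`) for an initial condition.
#'
#' @param x A [carrier_model()].
#' @param times Times to draw.
#' @param ic Initial condition (see [predict.carrier_model()]).
#' @param what `"means"` or `"var_u"`.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @export
plot.carrier_model <- function(x, times = seq(0, 5 / (x$KEI + x$KIE),
                                              length.out = 200),
                               ic = NULL, what = c("means", "var_u"), ...) {
  what <- match.arg(what)
  tr <- predict(x, times = times, ic = ic)
  if (what == "means") {
    graphics::matplot(tr$t, cbind(tr$ME_over_N, tr$MI_over_N), type = "l",
                      lty = 1, col = c("firebrick", "steelblue"),
                      xlab = "time", ylab = "cargo per carrier", ...)
    graphics::legend("right", legend = c("external ME/N", "internal MI/N"),
                     col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  } else {
    graphics::plot(tr$t, tr$var_u, type = "l", xlab = "time",
                   ylab = "var(u)", ...)
  }
  invisible(tr)
}
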