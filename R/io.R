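#' Load a run configuration from JSON
#'
#' Reads and validates a JSON configuration describing a model, an initial
#' condition, output times and solver settings. Recognised top-level keys:
#' `params` (with `mE`, `mI` — numbers or the string `"inf"` —, `KEI`, `KIE`,
#' `N`, `M`), `ic` (a `kind` tag plus its parameters), `times`, `time_unit`
#' (`"tau"` to express times in units of the relaxation time, else absolute),
#' `solver` (optional: `rtol`, `atol`, `epsilon`, `grid`), and `seed`
#' (optional). Unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return List with `model`, `ic`, `times` (converted to absolute time
#'   units), `solver`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("params", "ic", "times", "time_unit", "solver", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- cfg$params
  for (key in c("mE", "mI", "KEI", "KIE", "N", "M"))
    if (is.null(p[[key]]))
      stop("config params block is missing '", key, "'", call. = FALSE)
  site <- function(x) if (identical(x, "inf")) Inf else as.numeric(x)
  model <- carrier_model(mE = site(p$mE), mI = site(p$mI),
                         KEI = as.numeric(p$KEI), KIE = as.numeric(p$KIE),
                         N = as.numeric(p$N), M = as.numeric(p$M))
  ic <- NULL
  if (!is.null(cfg$ic)) {
    b <- cfg$ic
    ic <- switch(b$kind,
      delta = ic_delta(b$u0, b$v0),
      gaussian = ic_gaussian(b$etaE, b$etaI),
      mixture = ic_mixture(b$alpha, b$etaE, b$etaI),
      product_binomial = ic_binomial(b$p0, b$q0),
      stop("unknown ic kind '", b$kind, "'", call. = FALSE))
  }
  times <- if (is.null(cfg$times)) numeric(0) else as.numeric(cfg$times)
  if (identical(cfg$time_unit, "tau"))
    times <- times * derived_quantities(model)$tau
  solver <- list(rtol = 1e-8, atol = NULL, epsilon = 1e-12, grid = 200)
  solver[names(cfg$solver)] <- cfg$solver
  list(model = model, ic = ic, times = times, solver = solver,
       seed = cfg$seed)
}

#' Write ready-to-run configuration fixtures
#'
#' Emits JSON configurations for the package's reference setups: the delta
#' start of example 1, the example-2 / master-equation comparison at site
#' scales 0.1, 0.2 and 1 (`mE = mI = 250`, `500`, `2500`), the two
#' two-Gaussian mixtures of example 3, and a small-grid regression
#' configuration (`mE = 8`, `mI = 5`).
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  base_params <- list(mE = "inf", mI = "inf", KEI = 1 / 3, KIE = 2 / 3,
                      N = 100, M = 10000)
  times_tau <- c(0, log(4 / 3), log(2), log(4))
  paths <- c(
    wj(list(params = base_params,
            ic = list(kind = "delta", u0 = 100, v0 = 100),
            times = times_tau, time_unit = "tau"), "example1.json"),
    wj(list(params = base_params,
            ic = list(kind = "gaussian", etaE = 100 / 3, etaI = 200 / 3),
            times = times_tau, time_unit = "tau"), "example2.json"),
    wj(list(params = base_params,
            ic = list(kind = "mixture", alpha = c(0.5, 0.5),
                      etaE = c(100 / 3, (100 / 3) * (1 + exp(-0.4))),
                      etaI = c(200 / 3, (200 / 3) * (1 - exp(-0.4) / 2))),
            times = times_tau, time_unit = "tau"), "example3_left.json"),
    wj(list(params = base_params,
            ic = list(kind = "mixture", alpha = c(0.5, 0.5),
                      etaE = c((1 / 3 - 1 / 10) * 100, (1 / 3 + 1 / 10) * 100),
                      etaI = c(200 / 3, 200 / 3)),
            times = times_tau, time_unit = "tau"), "example3_right.json"))
  for (scale in c(0.1, 0.2, 1)) {
    m <- round(2500 * scale)
    paths <- c(paths, wj(
      list(params = list(mE = m, mI = m, KEI = 1 / 3, KIE = 2 / 3,
                         N = 100, M = 10000),
           ic = list(kind = "product_binomial",
                     p0 = 10000 / (3 * 100 * m),
                     q0 = 2 * 10000 / (3 * 100 * m)),
           times = times_tau, time_unit = "tau",
           solver = list(rtol = 1e-8, epsilon = 1e-12)),
      sprintf("fig3_scale%s.json", sub("\\.", "", format(scale)))))
  }
  paths <- c(paths, wj(
    list(params = list(mE = 8, mI = 5, KEI = 1, KIE = 1, N = 100, M = 300),
         ic = list(kind = "product_binomial", p0 = 3 / 13, q0 = 3 / 13),
         times = c(0, 1, 2, 5), time_unit = "tau", seed = 1),
    "smallgrid.json"))
  invisible(paths)
}

#' Delimited-text writers and readers
#'
#' Moment tables and occupancy snapshots are exchanged as comma-separated
#' text with a header row ('.' decimal separator). Occupancies use the long
#' format `i, n, y`.
#'
#' @param x A data frame (moment table) or [occupancy()].
#' @param path Output file.
#' @param drop_zero For occupancies, omit empty states.
#' @return `write_*` return the path invisibly; `read_moments` the data
#'   frame; `read_occupancy` an `occupancy` (requires `model`).
#' @name delimited_io
NULL

#' @rdname delimited_io
#' @export
write_moments <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname delimited_io
#' @export
read_moments <- function(path) utils::read.csv(path)

#' @rdname delimited_io
#' @export
write_occupancy <- function(x, path, drop_zero = TRUE) {
  stopifnot(inherits(x, "occupancy"))
  df <- data.frame(i = rep(i_values(x), times = ncol(x$y)),
                   n = rep(n_values(x), each = nrow(x$y)),
                   y = as.vector(x$y))
  if (drop_zero) df <- df[df$y != 0, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname delimited_io
#' @param path Input file.
#' @param model The model the snapshot belongs to.
#' @param t Time stamp to attach.
#' @export
read_occupancy <- function(path, model, t = 0) {
  df <- utils::read.csv(path)
  stopifnot(all(c("i", "n", "y") %in% names(df)))
  i0 <- min(df$i); n0 <- min(df$n)
  Y <- matrix(0, max(df$i) - i0 + 1, max(df$n) - n0 + 1)
  Y[cbind(df$i - i0 + 1, df$n - n0 + 1)] <- df$y
  occupancy(Y, model, t = t, i0 = i0, n0 = n0)
}
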