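test_that("kernel variance follows the Ornstein-Uhlenbeck law", {
  m <- ex2_model()   # muE = 200/3, muI = 100/3
  expect_equal(sigma_t(0, m), 0)
  sinf <- 800 / 9
  expect_equal(sigma_t(1e3, m), sinf)
  expect_equal(sigma_t(log(2), m), sinf * 3 / 4)
  # strictly increasing
  s <- sigma_t(seq(0, 3, by = 0.1), m)
  expect_true(all(diff(s) > 0))
  expect_error(sigma_t(-1, m), "non-negative")
})

test_that("the Green's function is a normalised Gaussian with the stated mean", {
  m <- ex2_model()
  set.seed(11)
  for (k in 1:5) {
    v <- runif(1, 50, 150); t <- runif(1, 0.05, 2); up <- runif(1, -80, 80)
    nrm <- stats::integrate(function(u) green_density(u, v, t, up, m),
                            -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(nrm, 1, tolerance = 1e-10)
    m1 <- stats::integrate(function(u) u * green_density(u, v, t, up, m),
                           -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(m1, up * exp(-t) + v * (1 / 3) * (1 - exp(-t)),
                 tolerance = 1e-9)
  }
  # long-time kernel forgets its source point
  g1 <- green_density(40, 100, 60, -50, m)
  g2 <- green_density(40, 100, 60, 80, m)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(green_mean(100, 1e3, 123, m), 100 / 3)
  expect_error(green_density(0, 100, 0, 0, m), "t > 0")
})

test_that("propagation conserves carriers, cargo and the whole v-marginal", {
  m <- ex2_model()
  ic <- example3_ic("shifted", m)
  f0 <- f_of_v(ic, m)
  for (t in c(0, 0.3, 2)) {
    fld <- fp_propagate(ic, t, m)
    expect_equal(sum(fld$comp$w), 2 * m$N)
    mom <- field_moments(fld)
    expect_equal(mom$mean_v, m$M / m$N)
    # f(v) is untouched component by component
    expect_equal(fld$comp$mv, f0$comp$m)
    expect_equal(fld$comp$cvv, f0$comp$s2)
    v <- seq(60, 140, by = 5)
    expect_equal(f_density(f0, v),
                 sapply(v, function(vi) stats::integrate(
                   function(u) field_density(fld, u, vi),
                   -Inf, Inf, rel.tol = 1e-10)$value),
                 tolerance = 1e-8)
  }
})

test_that("zero-time propagation reproduces the initial distribution", {
  m <- ex2_model()
  ic <- example2_ic(m)
  fld <- fp_propagate(ic, 0, m)
  ref <- cargoflip:::ic_uv_mixture(ic, m)
  expect_equal(fld$comp, ref$comp)
})

test_that("long-time propagation reaches the equilibrium of f(v)", {
  m <- ex2_model()
  for (ic in list(example2_ic(m), example3_ic("shifted", m))) {
    late <- fp_propagate(ic, 50, m)
    eq <- fp_equilibrium(f_of_v(ic, m), m)
    u <- seq(-20, 90, by = 5); v <- seq(70, 130, by = 10)
    du <- field_density(late, rep(u, length(v)), rep(v, each = length(u)))
    de <- field_density(eq, rep(u, length(v)), rep(v, each = length(u)))
    expect_lt(max(abs(du - de)) / max(de), 1e-8)
  }
})

test_that("propagation satisfies the Chapman-Kolmogorov semigroup property", {
  m <- ex2_model()
  ic <- example3_ic("redistributed", m)
  one <- fp_propagate(ic, 1.3, m)
  two <- fp_propagate(fp_propagate(ic, 0.5, m), 0.8, m)
  expect_equal(two$comp, one$comp, tolerance = 1e-12)
  expect_equal(two$t, one$t)
})

test_that("closed-form moments match the Green's-function algebra", {
  m <- ex2_model()
  mn <- m$M / m$N
  # initial moments of the mirrored-Gaussian start
  ic <- example2_ic(m)
  m0 <- field_moments(fp_propagate(ic, 0, m))
  expect_equal(m0$m2_u, 10900 / 9)
  expect_equal(m0$m11, -10100 / 3)
  expect_equal(m0$m2_v, 10100)
  for (t in c(0.2, log(2), 1.7)) {
    mom <- field_moments(fp_propagate(ic, t, m))
    expect_equal(mom$mean_u, mean_u(t, m, mn / 3, 2 * mn / 3),
                 tolerance = 1e-12)
    expect_equal(mom$m2_u,
                 second_moment_u(t, m, m0$m2_u, m0$m11, m0$m2_v),
                 tolerance = 1e-12)
    expect_equal(mom$ME_over_N - mom$MI_over_N, mom$mean_u)
  }
  # equilibrium second moment keeps the memory of <v^2>_0
  meq <- field_moments(fp_equilibrium(ic, m))
  expect_equal(meq$m2_u, 800 / 9 + (1 / 9) * 10100, tolerance = 1e-12)
})

test_that("quadrature propagation of a grid agrees with the closed form", {
  m <- ex2_model()
  ic <- example2_ic(m)
  u <- seq(-140, 140, length.out = 421)
  v <- seq(40, 160, length.out = 121)
  y0 <- function(uu, vv) field_density(fp_propagate(ic, 0, m), uu, vv)
  t <- 0.6
  grd <- fp_propagate_grid(y0, t, m, u, v)
  cf <- fp_propagate(ic, t, m)
  Yref <- outer(u, v, function(a, b) field_density(cf, a, b))
  expect_lt(max(abs(grd$Y - Yref)) / max(Yref), 1e-8)
  # quadrature moments against the analytic moment algebra
  gm <- field_moments(grd)
  cm <- field_moments(cf)
  for (col in c("mean_u", "mean_v", "m2_u", "m2_v", "m11"))
    expect_equal(gm[[col]], cm[[col]], tolerance = 1e-8)
  expect_equal(cargoflip:::grid_carriers(grd), m$N, tolerance = 1e-8)
})

test_that("v-moments up to order four are invariant under propagation", {
  m <- ex2_model()
  ic <- example3_ic("shifted", m)
  vmom <- function(t, k) {
    fld <- fp_propagate(ic, t, m)
    comp <- fld$comp; w <- comp$w / sum(comp$w)
    # Gaussian raw moments in v per component
    sapply(seq_len(nrow(comp)), function(j) {
      mu <- comp$mv[j]; s2 <- comp$cvv[j]
      switch(k, mu, mu^2 + s2, mu^3 + 3 * mu * s2,
             mu^4 + 6 * mu^2 * s2 + 3 * s2^2)
    }) |> weighted.mean(w)
  }
  for (k in 1:4)
    expect_equal(vmom(0, k), vmom(1.1, k), tolerance = 1e-12)
})

test_that("chart changes round-trip and preserve carrier number", {
  m <- ex2_model()
  fld <- fp_propagate(example3_ic("shifted", m), 0.4, m)
  back <- field_to_uv(field_to_xz(fld))
  expect_equal(back$comp, fld$comp, tolerance = 1e-12)
  xz <- field_to_xz(fld)
  expect_equal(sum(xz$comp$w), m$N)
  # pointwise the two charts agree: y(x, z) = ytilde(u, v)
  x <- c(30, 50, 70); z <- c(20, 40, 60)
  expect_equal(field_density(xz, x, z),
               field_density(fld, x - z, x + z), tolerance = 1e-12)
})

test_that("equilibria depend on the initial state only through f(v)", {
  m <- ex2_model()
  same <- fp_equilibrium(example3_ic("redistributed", m), m)
  ref <- fp_equilibrium(example2_ic(m), m)
  u <- seq(-30, 90, by = 10)
  expect_equal(field_marginal_u(same, u), field_marginal_u(ref, u),
               tolerance = 1e-10)
  other <- fp_equilibrium(example3_ic("shifted", m), m)
  expect_gt(max(abs(field_marginal_u(other, u) - field_marginal_u(ref, u))),
            1e-4)
  # Eq-27 mechanism: different <v^2>_0 shifts the equilibrium second moment
  d2 <- field_moments(other)$m2_u - field_moments(ref)$m2_u
  dv2 <- field_moments(fp_propagate(example3_ic("shifted", m), 0, m))$m2_v -
    10100
  expect_equal(d2, (1 / 9) * dv2, tolerance = 1e-10)
})
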