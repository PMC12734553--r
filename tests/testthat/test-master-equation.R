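test_that("combinatorial factors count accessible transfer configurations", {
  m <- small_model()
  expect_equal(factor_ei(3, 2, m), 3 * (1 - 2 / 5))
  expect_equal(factor_ie(2, 3, m), 2 * (1 - 3 / 8))
  # transfer into a full compartment is impossible
  expect_equal(factor_ei(4, m$mI, m), 0)
  expect_equal(factor_ie(3, m$mE, m), 0)
  # nothing to transfer
  expect_equal(factor_ei(0, 2, m), 0)
  expect_equal(factor_ie(0, 2, m), 0)
  expect_error(factor_ei(9, 0, m), "out of range")
  expect_error(factor_ie(6, 0, m), "out of range")
  # unsaturated limit for infinite site counts
  minf <- carrier_model(Inf, Inf, 1, 1, 10, 100)
  expect_equal(factor_ei(7, 3, minf), 7)
  expect_equal(factor_ie(4, 9, minf), 4)
})

test_that("a single occupied state feeds exactly its two neighbours", {
  m <- small_model()
  Y <- matrix(0, m$mE + 1, m$mI + 1)
  i <- 3; n <- 2
  Y[i + 1, n + 1] <- m$N
  R <- master_rhs(occupancy(Y, m))
  loss <- (m$KEI * factor_ei(i, n, m) + m$KIE * factor_ie(n, i, m)) * m$N
  expect_equal(R[i + 1, n + 1], -loss)
  expect_equal(R[i, n + 2], m$KEI * factor_ei(i, n, m) * m$N)   # (i-1, n+1)
  expect_equal(R[i + 2, n], m$KIE * factor_ie(n, i, m) * m$N)   # (i+1, n-1)
  expect_equal(sum(R != 0), 3)
  expect_equal(sum(R), 0)
})

test_that("the master operator conserves carriers and every anti-diagonal", {
  set.seed(7)
  m <- small_model()
  for (k in 1:100) {
    Y <- matrix(stats::rexp((m$mE + 1) * (m$mI + 1)), m$mE + 1, m$mI + 1)
    Y <- Y / sum(Y) * m$N
    R <- master_rhs(occupancy(Y, m))
    expect_lt(abs(sum(R)), 1e-12 * m$N)
    expect_lt(max(abs(antidiag_of_matrix(R))), 1e-12 * m$N)
  }
})

test_that("anti-diagonal sums identify the conserved subpopulations", {
  m <- small_model()
  # delta state
  occ <- discrete_state(ic_delta(u0 = 1, v0 = 5), m)  # (i, n) = (3, 2)
  S <- antidiagonal_sums(occ)
  expect_equal(unname(S["5"]), m$N)
  expect_equal(sum(S), m$N)
  expect_equal(sum(S > 0), 1)
  # product binomial: S_v is the convolution of the two binomial laws
  ic <- ic_binomial(3 / 13, 3 / 13)
  S2 <- antidiagonal_sums(discrete_state(ic, m))
  conv <- sapply(0:(m$mE + m$mI), function(v) {
    i <- max(0, v - m$mI):min(v, m$mE)
    sum(dbinom(i, m$mE, 3 / 13) * dbinom(v - i, m$mI, 3 / 13))
  }) * m$N
  expect_equal(unname(S2), conv, tolerance = 1e-12)
})

test_that("discrete first moments recover compartment totals", {
  m <- small_model()
  occ <- discrete_state(ic_delta(u0 = 3, v0 = 3), m)  # all cargo external
  md <- moments_discrete(occ)
  expect_equal(md$ME, m$M)
  expect_equal(md$MI, 0)
  empty <- occupancy(matrix(c(m$N, rep(0, 53)), 9, 6), m)
  expect_equal(unlist(moments_discrete(empty)), c(ME = 0, MI = 0))
  # equilibrium moments: ME = N p mE
  pq <- solve_pq(m)
  S <- antidiagonal_sums(discrete_state(ic_binomial(pq$p, pq$q), m))
  eq <- equilibrium_discrete(S, m)
  expect_equal(moments_discrete(eq)$ME, m$N * pq$p * m$mE, tolerance = 1e-9)
})

test_that("the product-binomial-per-anti-diagonal state is stationary", {
  m <- small_model()
  S <- antidiagonal_sums(discrete_state(ic_binomial(3 / 13, 3 / 13), m))
  eq <- equilibrium_discrete(S, m)
  expect_equal(sum(eq$y), m$N, tolerance = 1e-12)
  expect_equal(unname(antidiagonal_sums(eq)), unname(S), tolerance = 1e-10)
  expect_lt(max(abs(master_rhs(eq))), 1e-10 * m$N)
})

test_that("equilibrium on one anti-diagonal is the conditioned product law", {
  m <- small_model(KEI = 2, KIE = 3)
  pq <- solve_pq(m)
  v0 <- 5
  S <- rep(0, m$mE + m$mI + 1); S[v0 + 1] <- m$N
  eq <- equilibrium_discrete(S, m)
  # brute-force normalisation over the anti-diagonal
  i <- max(0, v0 - m$mI):min(v0, m$mE)
  w <- dbinom(i, m$mE, pq$p) * dbinom(v0 - i, m$mI, pq$q)
  expected <- m$N * w / sum(w)
  expect_equal(eq$y[cbind(i + 1, v0 - i + 1)], expected, tolerance = 1e-12)
  expect_equal(sum(eq$y), m$N, tolerance = 1e-12)
})

test_that("integration preserves N, M and all S_v and matches moment law", {
  # closure condition KEI mE = KIE mI makes the first-moment ODE exact
  m <- carrier_model(mE = 100, mI = 50, KEI = 1, KIE = 2, N = 50, M = 1500)
  p0 <- 0.2; q0 <- (1500 / 50 - p0 * 100) / 50
  ic <- ic_binomial(p0, q0)
  rtol <- 1e-8
  times <- c(0, 0.1, 0.35, 0.8)
  traj <- master_integrate(ic, times, m, rtol = rtol)
  S0 <- antidiagonal_sums(traj[[1]])
  d <- derived_quantities(m)
  for (k in seq_along(traj)) {
    occ <- traj[[k]]
    expect_equal(sum(occ$y), m$N, tolerance = 10 * rtol)
    md <- moments_discrete(occ)
    expect_equal(md$ME + md$MI, m$M, tolerance = 10 * rtol)
    expect_equal(unname(antidiagonal_sums(occ)), unname(S0),
                 tolerance = 10 * rtol)
    # exponential relaxation of the first moment
    fm <- first_moments(m, occ$t, etaE = p0 * 100, etaI = q0 * 50)
    expect_equal(md$ME / m$N, fm$ME_over_N, tolerance = rtol * 100)
  }
})

test_that("integrating over zero time returns the state unchanged", {
  m <- small_model()
  y0 <- discrete_state(ic_binomial(3 / 13, 3 / 13), m)
  out <- master_integrate(y0, 0, m)
  expect_equal(out[[1]]$y, y0$y)
})

test_that("trajectories relax to the detailed-balance equilibrium", {
  m <- carrier_model(mE = 50, mI = 50, KEI = 1, KIE = 2, N = 20, M = 600)
  ic <- ic_binomial(0.4, 0.2)
  traj <- master_integrate(ic, c(0, 12), m, rtol = 1e-8)
  S <- antidiagonal_sums(traj[[1]])
  eq <- equilibrium_discrete(S, m)
  expect_lt(max(abs(traj[[2]]$y - eq$y)), 1e-6 * m$N)
})

test_that("truncation windows bound the neglected mass", {
  setup <- figure3_setup(0.2)   # mE = mI = 500
  w <- truncation_window(setup$ic, setup$model, epsilon = 1e-12)
  expect_s3_class(w, "truncation_window")
  d <- derived_quantities(setup$model)
  mi0 <- setup$ic$p0 * setup$model$mE
  # covers initial and equilibrium means +- 10 sd
  expect_lte(w$iLo, max(0, floor(mi0 - 10 * sqrt(mi0))))
  expect_gte(w$iHi, ceiling(d$muE + 10 * sqrt(d$muE)))
  expect_gte(w$iLo, 0); expect_lte(w$iHi, setup$model$mE)
  expect_gte(w$nLo, 0); expect_lte(w$nHi, setup$model$mI)
  expect_lt(w$massBound, 1e-12)
  # direct binomial tail sum outside the window
  outside <- 1 -
    sum(dbinom(w$iLo:w$iHi, setup$model$mE, setup$ic$p0)) *
    sum(dbinom(w$nLo:w$nHi, setup$model$mI, setup$ic$q0))
  expect_lt(outside, 1e-12)
})

test_that("windowed and full-grid integration agree", {
  m <- carrier_model(mE = 60, mI = 60, KEI = 1 / 3, KIE = 2 / 3,
                     N = 100, M = 1200)
  ic <- ic_binomial(12 / (3 * 60), 24 / (3 * 60))
  full <- master_integrate(discrete_state(ic, m), c(0, 0.5), m)
  w <- truncation_window(ic, m, epsilon = 1e-12)
  win <- master_integrate(discrete_state(ic, m, w), c(0, 0.5), m)
  sub <- full[[2]]$y[w$iLo:w$iHi + 1, w$nLo:w$nHi + 1]
  expect_lt(max(abs(win[[2]]$y - sub)), 1e-9 * m$N)
})
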