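# Shared fixtures, built in code.

# Continuum model of the mirrored-Gaussian example: KEI/KIE = 1/2 in units of
# 1/tau, so muE = 2 M/(3N), muI = M/(3N), tau = 1.
ex2_model <- function(N = 100, M = 10000) {
  carrier_model(mE = Inf, mI = Inf, KEI = 1 / 3, KIE = 2 / 3, N = N, M = M)
}

# Small finite grid used for exact brute-force checks.
small_model <- function(KEI = 1, KIE = 1) {
  carrier_model(mE = 8, mI = 5, KEI = KEI, KIE = KIE, N = 100, M = 300)
}

# anti-diagonal sums of a plain matrix over full grids starting at (0, 0)
antidiag_of_matrix <- function(Y) {
  v <- as.vector(outer(seq_len(nrow(Y)) - 1, seq_len(ncol(Y)) - 1, "+"))
  s <- rowsum(as.vector(Y), group = v)
  out <- as.vector(s)
  names(out) <- rownames(s)
  out
}

# independent detailed-balance oracle: substitute q from cargo conservation
# and bisect the detailed-balance residual in p
solve_pq_bisect <- function(model) {
  mn <- model$M / model$N
  qc <- function(p) (mn - p * model$mE) / model$mI
  resid <- function(p) {
    q <- qc(p)
    model$mE * model$KEI * p * (1 - q) - model$mI * model$KIE * (1 - p) * q
  }
  lo <- max(0, (mn - model$mI) / model$mE) + 1e-12
  hi <- min(1, mn / model$mE) - 1e-12
  p <- stats::uniroot(resid, c(lo, hi), tol = 1e-15)$root
  list(p = p, q = qc(p))
}

# random feasible finite model
random_model <- function() {
  mE <- sample(3:60, 1); mI <- sample(3:60, 1)
  N <- sample(10:1000, 1)
  M <- round(stats::runif(1, 0.05, 0.95) * N * (mE + mI))
  if (M == 0) M <- 1
  carrier_model(mE, mI, KEI = stats::runif(1, 0.05, 5),
                KIE = stats::runif(1, 0.05, 5), N = N, M = M)
}
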