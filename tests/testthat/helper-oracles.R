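# Independent reference implementations used as oracles. These are written
# directly from the textbook series/formulas in plain R, with a fixed large
# truncation instead of the package's adaptive switching rule, and never call
# the package's density internals.

# first-passage density at a boundary for drift v, separation a, relative
# start z (from the lower boundary), decision time u = rt - t0
ref_wfpt_density <- function(u, v, a, z, boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  if (boundary == "upper") { v <- -v; z <- 1 - z }
  if (u <= 0) return(0)
  tt <- u / a^2
  K <- 150
  k <- -K:K
  s <- sum((z + 2 * k) * exp(-(z + 2 * k)^2 / (2 * tt)))
  f_std <- s / sqrt(2 * pi * tt^3)
  f_std * exp(-v * a * z - v^2 * u / 2) / a^2
}

# naive trial-by-trial log likelihood: R loop over trials, delta-rule updates
# and per-trial density calls; mirrors the model definition, not the package
# implementation
ref_subject_loglik <- function(subject, params) {
  p <- unclass(params)
  qr <- 0; ql <- 0; ll <- 0
  tr <- subject$trials
  for (i in seq_len(nrow(tr))) {
    dq <- qr - ql
    z <- 1 / (1 + exp(-p[["b_z"]] * dq))
    s <- if (tr$stimulus[i] == "rich") 1 else -1
    v <- s * p[["v_intercept"]] + p[["b_v"]] * dq
    if (tr$valid[i] && tr$response[i] != "none" && !is.na(tr$rt[i])) {
      u <- tr$rt[i] - p[["t"]]
      bnd <- if (tr$response[i] == "rich") "upper" else "lower"
      dens <- ref_wfpt_density(u, v, p[["a"]], z, bnd)
      ll <- ll + log(dens)
    }
    if (tr$response[i] == "rich") qr <- qr + p[["alpha"]] * (tr$reward[i] - qr)
    if (tr$response[i] == "lean") ql <- ql + p[["alpha"]] * (tr$reward[i] - ql)
  }
  ll
}

# split-chain Gelman-Rubin statistic evaluated directly from the formula
ref_split_rhat <- function(mat) {
  n2 <- floor(nrow(mat) / 2)
  halves <- cbind(mat[seq_len(n2), , drop = FALSE],
                  mat[(nrow(mat) - n2 + 1):nrow(mat), , drop = FALSE])
  n <- nrow(halves)
  W <- mean(apply(halves, 2, var))
  B_over_n <- var(colMeans(halves))
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

# memoized small fitted model shared across test files (built once per run)
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(6, seed = 42)
  .fixture_env$cohort
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- suppressWarnings(fit_hierarchical(
      fixture_cohort(),
      mcmc = mcmc_config("fast", n_chains = 3, n_iter = 1100, n_warmup = 600),
      seed = 9))
  }
  .fixture_env$fit
}
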