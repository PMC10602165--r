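one_cell_data <- function(kind, params, n = 1000, seed = 1) {
  exact_twin_data(implied_sigma(kind, params), n, n, seed = seed)
}

test_that("fitting the generating model to its own exact data recovers the truth", {
  cases <- list(
    doc    = mrdoc_params(g1 = 0.04, ra = 0.2, rc = 0.2),
    mrdoc  = mrdoc_params(g1 = 0.04, b1 = 0.05, b2 = 0.025, ra = 0.2),
    mrdoc2 = design3_cell_params()
  )
  for (kind in names(cases)) {
    p <- cases[[kind]]
    dat <- one_cell_data(kind, p)
    fit <- fit_ml(kind, dat$mz, dat$dz, start = as_theta(p))
    expect_true(fit$converged)
    expect_lt(fit$minus2lnL, 1e-8)
    expect_lt(max(abs(fit$estimates - as_theta(p)[names(fit$estimates)])), 1e-4)
    expect_equal(fit$n_free, length(free_parameters(kind)))
  }
})

test_that("the discrepancy difference equals the record-level likelihood ratio", {
  # record-level -2lnL with known zero means:
  #   N p log(2pi) + N log|Sigma| + sum_i x_i' Sigma^-1 x_i
  raw_m2ll <- function(fit, dat) {
    total <- 0
    for (g in c("mz", "dz")) {
      sig <- mrdoctwin:::build_pair_sigma(fit$theta, fit$kind)[[g]]
      x <- dat[[g]]$values[, colnames(sig), drop = FALSE]
      n <- nrow(x)
      total <- total + n * ncol(x) * log(2 * pi) +
        n * determinant(sig)$modulus[1] + sum((x %*% solve(sig)) * x)
    }
    total
  }
  p <- design3_cell_params()
  dat <- one_cell_data("mrdoc2", p, seed = 2)
  full <- fit_ml("mrdoc2", dat$mz, dat$dz, start = as_theta(p))
  constr <- fit_ml("mrdoc2", dat$mz, dat$dz, constraints = c(g1 = 0),
                   start = full$theta)
  lr_raw <- raw_m2ll(constr, dat) - raw_m2ll(full, dat)
  lr_cov <- constr$minus2lnL - full$minus2lnL
  # conventions differ by an O(1/n) factor on the trace term
  expect_equal(lr_cov, lr_raw, tolerance = 0.01)
})

test_that("re misspecification biases the causal path in the documented direction", {
  for (re in c(0.3, -0.3)) {
    p <- design3_cell_params(re = re)
    dat <- one_cell_data("mrdoc2", p, seed = 3)
    fit <- fit_ml("mrdoc", dat$mz, dat$dz, start = as_theta(p))
    if (re > 0) expect_gt(fit$estimates[["g1"]], p$g1)
    else expect_lt(fit$estimates[["g1"]], p$g1)
  }
})

test_that("likelihood-ratio statistics behave as non-centrality parameters", {
  # constraint true in the population: ncp exactly 0
  p0 <- mrdoc_params(g1 = 0, b1 = 0.05, b3 = 0.05, g2 = 0.04,
                     ra = 0.2, rc = 0.2, re = 0.2, rf = 0.2)
  dat0 <- one_cell_data("mrdoc2", p0, seed = 4)
  f0 <- fit_ml("mrdoc2", dat0$mz, dat0$dz, start = as_theta(p0))
  c0 <- fit_ml("mrdoc2", dat0$mz, dat0$dz, constraints = c(g1 = 0),
               start = f0$theta)
  l0 <- lrt_ncp(f0, c0)
  expect_equal(l0$ncp, 0, tolerance = 1e-6)
  expect_equal(l0$df, 1)

  # false constraint: positive ncp; joint constraint: df = 2
  p1 <- design3_cell_params()
  dat1 <- one_cell_data("mrdoc2", p1, seed = 5)
  f1 <- fit_ml("mrdoc2", dat1$mz, dat1$dz, start = as_theta(p1))
  c1 <- fit_ml("mrdoc2", dat1$mz, dat1$dz, constraints = c(g1 = 0),
               start = f1$theta)
  expect_gt(lrt_ncp(f1, c1)$ncp, 0)
  c2 <- fit_ml("mrdoc2", dat1$mz, dat1$dz, constraints = c(g1 = 0, g2 = 0),
               start = f1$theta)
  l2 <- lrt_ncp(f1, c2)
  expect_equal(l2$df, 2)
  expect_gte(l2$ncp, lrt_ncp(f1, c1)$ncp - 1e-8)
  expect_error(lrt_ncp(f1, f1), "strictly more")
})

test_that("ncp is invariant to the simulation seed (exact data fixes the moments)", {
  p <- design3_cell_params()
  ncps <- vapply(c(1, 42), function(seed) {
    dat <- one_cell_data("mrdoc2", p, seed = seed)
    f <- fit_ml("mrdoc2", dat$mz, dat$dz, start = as_theta(p))
    cns <- fit_ml("mrdoc2", dat$mz, dat$dz, constraints = c(g1 = 0),
                  start = f$theta)
    lrt_ncp(f, cns)$ncp
  }, numeric(1))
  expect_equal(ncps[1], ncps[2], tolerance = 1e-8)
})

test_that("chi-square power follows the noncentral distribution", {
  expect_equal(power_from_ncp(0, 1, 0.05), 0.05)
  # strictly increasing in ncp, saturating at 1
  grid <- power_from_ncp(seq(0, 30, by = 0.5), 1, 0.05)
  expect_true(all(diff(grid) > 0))
  expect_equal(power_from_ncp(1e4, 1, 0.05), 1, tolerance = 1e-12)
  expect_gte(power_from_ncp(2, 3, 0.05), 0.05)

  # simulation oracle: (Z + sqrt(ncp))^2 exceeds the central 1-df critical
  # value with the claimed probability (~0.80 at ncp = 7.849)
  set.seed(10)
  z <- stats::rnorm(2e6)
  prop <- mean((z + sqrt(7.849))^2 > stats::qchisq(0.95, 1))
  pw <- power_from_ncp(7.849, 1, 0.05)
  expect_equal(pw, 0.80, tolerance = 5e-4)
  expect_lt(abs(prop - pw), 3 * sqrt(0.8 * 0.2 / 2e6))
  expect_error(power_from_ncp(-1, 1, 0.05))
})

test_that("the bidirectional identification recovers reciprocal causation", {
  # g1, g2, rc free with ra = re = 0: the other identified choice of three
  # free trait-connecting paths
  p <- mrdoc_params(g1 = 0.04, g2 = 0.04, rc = 0.2)
  dat <- one_cell_data("doc", p)
  fit <- fit_ml("doc", dat$mz, dat$dz, start = as_theta(p),
                causal = "bidirectional")
  expect_true(fit$converged)
  expect_setequal(names(fit$estimates), free_parameters("doc", "bidirectional"))
  expect_lt(max(abs(fit$estimates - as_theta(p)[names(fit$estimates)])), 1e-4)
  expect_equal(fit$estimates[["g2"]], 0.04, tolerance = 1e-4)
})

test_that("the fitter validates constraints and variable sets", {
  p <- mrdoc_params(g1 = 0.04)
  dat <- one_cell_data("doc", p, n = 100)
  expect_error(fit_ml("doc", dat$mz, dat$dz, constraints = c(b1 = 0)),
               "non-free")
  # DoC data cannot support an MR-DoC fit (no polygenic score)
  expect_error(fit_ml("mrdoc", dat$mz, dat$dz), "lacks variables")
})
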