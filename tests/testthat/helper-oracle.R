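# Structural Monte-Carlo oracle for the model-implied pair covariance.
#
# Independent of the reduced-form block assembly in implied_sigma(): it
# draws ACE factor scores and polygenic scores with the defining cross-twin
# correlations (A and PGS: 1 in MZ / 0.5 in DZ; C: 1; E: 0) and solves the
# two simultaneous phenotype equations record by record.
#
# `exact_moments = TRUE` draws the factor scores with exactly matched
# sample moments (a single joint empirical draw over the block-diagonal
# factor covariance) - standard Monte-Carlo variance reduction that removes
# the sampling noise of the factor draws while leaving the record-level
# equation solving untouched, so the comparison against implied_sigma()
# is limited only by floating point.
oracle_pair_sample <- function(params, group = c("mz", "dz"), n,
                               seed = 4242, exact_moments = FALSE) {
  group <- match.arg(group)
  alpha <- if (group == "mz") 1 else 0.5
  set.seed(seed)
  p <- params

  # factor scores over (trait1 twin1, trait2 twin1, trait1 twin2, trait2 twin2)
  factor_cov <- function(v1, v2, cw, r_cross) {
    w <- matrix(c(v1, cw, cw, v2), 2, 2)
    rbind(cbind(w, r_cross * w), cbind(r_cross * w, w))
  }
  ps_w <- matrix(c(p$vP1, p$cF, p$cF, p$vP2), 2, 2)
  blocks <- list(
    A = factor_cov(p$VA1, p$VA2, p$CA, alpha),
    C = factor_cov(p$VC1, p$VC2, p$CC, 1),
    E = factor_cov(p$VE1, p$VE2, p$CE, 0),
    # MZ co-twins carry literally the same scores: draw one pair of scores
    # and duplicate below
    PS = if (group == "mz") ps_w else
      rbind(cbind(ps_w, 0.5 * ps_w), cbind(0.5 * ps_w, ps_w))
  )
  dims <- vapply(blocks, ncol, integer(1))
  sigma_f <- matrix(0, sum(dims), sum(dims))
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(ncol(b))
    sigma_f[idx, idx] <- b
    at <- at + ncol(b)
  }
  FS <- MASS::mvrnorm(n, rep(0, ncol(sigma_f)), sigma_f,
                      empirical = exact_moments)
  A <- FS[, 1:4]; C <- FS[, 5:8]; E <- FS[, 9:12]
  PS <- if (group == "mz") cbind(FS[, 13:14], FS[, 13:14]) else FS[, 13:16]

  solve_twin <- function(ps1, ps2, ax, ay, cx, cy, ex, ey) {
    ux <- p$b1 * ps1 + ax + cx + ex
    uy <- p$b2 * ps1 + p$b3 * ps2 + ay + cy + ey
    det <- 1 - p$g1 * p$g2
    cbind(X = (ux + p$g2 * uy) / det, Y = (uy + p$g1 * ux) / det)
  }
  t1 <- solve_twin(PS[, 1], PS[, 2], A[, 1], A[, 2], C[, 1], C[, 2],
                   E[, 1], E[, 2])
  t2 <- solve_twin(PS[, 3], PS[, 4], A[, 3], A[, 4], C[, 3], C[, 4],
                   E[, 3], E[, 4])
  out <- cbind(PS[, 1], PS[, 2], t1, PS[, 3], PS[, 4], t2)
  colnames(out) <- c("PS1_t1", "PS2_t1", "X_t1", "Y_t1",
                     "PS1_t2", "PS2_t2", "X_t2", "Y_t2")
  out
}

# Monte-Carlo standard error of each sample-covariance entry of `values`
# (normal theory: var(s_ij) = (s_ii s_jj + s_ij^2) / n).
cov_mc_se <- function(values) {
  S <- stats::cov(values)
  n <- nrow(values)
  v <- diag(S)
  sqrt((outer(v, v) + S^2) / n)
}

# Assert |S_hat - Sigma| <= k * SE elementwise for the variables of `kind`.
expect_cov_matches_oracle <- function(kind, params, group, n, k = 3,
                                      seed = 4242, exact_moments = FALSE) {
  draws <- oracle_pair_sample(params, group, n, seed = seed,
                              exact_moments = exact_moments)
  vars <- model_variables(kind, group)
  draws <- draws[, vars, drop = FALSE]
  S <- stats::cov(draws)
  se <- cov_mc_se(draws)
  sigma <- implied_sigma(kind, params)[[paste0("sigma_", group)]]
  expect_lt(max(abs(S - sigma) / pmax(se, 1e-12)), k)
}

# A representative Design-3 cell (the largest-effect corner).
design3_cell_params <- function(re = 0.2) {
  mrdoc_params(b1 = 0.05, b3 = 0.05, g1 = 0.04, g2 = 0.04,
               ra = 0.2, rc = 0.2, re = re, rf = 0.2)
}
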