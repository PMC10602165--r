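test_that("pure ACE algebra gives the textbook variances and cross-twin covariances", {
  p <- mrdoc_params(VA1 = 0.10, VC1 = 0.10, VE1 = 0.80)
  tc <- implied_sigma("doc", p)
  expect_equal(tc$sigma_mz["X_t1", "X_t1"], 1.0)
  expect_equal(tc$sigma_mz["X_t1", "X_t2"], 0.20)
  expect_equal(tc$sigma_dz["X_t1", "X_t2"], 0.15)
  # unit residual phenotypic variance under the e = 1 - a - c scaling
  a1 <- 0.1; c1 <- 0.1
  p2 <- mrdoc_params(VA1 = a1, VC1 = c1, VE1 = 1 - a1 - c1)
  expect_equal(p2$VE1, 0.80)
  expect_equal(implied_sigma("doc", p2)$sigma_dz["X_t1", "X_t1"], 1.0)
})

test_that("twin blocks are exchangeable and within-twin blocks match across zygosity", {
  p <- design3_cell_params()
  for (kind in c("doc", "mrdoc", "mrdoc2")) {
    pk <- if (kind == "doc") {
      mrdoc_params(g1 = 0.04, g2 = 0.04, ra = 0.2, rc = 0.2, re = 0.2)
    } else if (kind == "mrdoc") {
      mrdoc_params(g1 = 0.04, b1 = 0.05, b2 = 0.025, ra = 0.2, rc = 0.2)
    } else p
    tc <- implied_sigma(kind, pk)
    # DZ observes the full duplicated variable set: swap the twin blocks
    nv <- length(tc$var_order) / 2
    perm <- c(nv + seq_len(nv), seq_len(nv))
    expect_equal(unname(tc$sigma_dz[perm, perm]), unname(tc$sigma_dz),
                 tolerance = 1e-12)
    # within-twin phenotype moments agree between MZ and DZ
    for (v in c("X_t1", "Y_t1")) {
      expect_equal(tc$sigma_mz[v, v], tc$sigma_dz[v, v])
    }
    expect_equal(tc$sigma_mz["X_t1", "Y_t1"], tc$sigma_dz["X_t1", "Y_t1"])
    # twin-2 phenotypes mirror twin-1 in both groups
    expect_equal(tc$sigma_mz["X_t2", "Y_t2"], tc$sigma_mz["X_t1", "Y_t1"])
    expect_equal(tc$sigma_dz["X_t2", "Y_t2"], tc$sigma_dz["X_t1", "Y_t1"])
  }
})

test_that("nested models are special cases of MR-DoC2", {
  # rf = 0, b3 = 0 (and b2 = 0) reduces MR-DoC2 to MR-DoC
  p <- mrdoc_params(g1 = 0.04, b1 = 0.05, ra = 0.2, rc = 0.2, re = 0.1)
  full <- implied_sigma("mrdoc2", p)
  sub <- submodel_sigma(full, "mrdoc")
  direct <- implied_sigma("mrdoc", p)
  expect_equal(sub$sigma_mz, direct$sigma_mz, tolerance = 1e-12)
  expect_equal(sub$sigma_dz, direct$sigma_dz, tolerance = 1e-12)
  # b1 = b2 = 0 reduces MR-DoC to DoC on the phenotype block
  p0 <- mrdoc_params(g1 = 0.04, ra = 0.2, rc = 0.2)
  expect_equal(submodel_sigma(implied_sigma("mrdoc2", p0), "doc")$sigma_mz,
               implied_sigma("doc", p0)$sigma_mz, tolerance = 1e-12)
})

test_that("marginalization preserves entries and validates labels", {
  full <- implied_sigma("mrdoc2", design3_cell_params())
  expect_equal(submodel_sigma(full, "mrdoc2")$sigma_dz, full$sigma_dz)
  doc <- submodel_sigma(full, "doc")
  expect_equal(doc$sigma_mz,
               full$sigma_mz[c("X_t1", "Y_t1", "X_t2", "Y_t2"),
                             c("X_t1", "Y_t1", "X_t2", "Y_t2")])
  # a DoC matrix cannot be marginalized "up" to MR-DoC
  expect_error(submodel_sigma(doc, "mrdoc"), "missing")
})

test_that("implied covariance is positive definite across all 104 design cells", {
  for (d in 1:3) {
    grid <- design_grid(d)
    for (i in seq_len(nrow(grid$cells))) {
      tc <- implied_sigma(grid$kind, mrdoctwin:::cell_params(grid, i))
      expect_s3_class(tc, "twin_covariance")
    }
  }
})

test_that("indirect horizontal pleiotropy equals rf * b3 when causal paths vanish", {
  p <- mrdoc_params(b1 = 0.05, b3 = 0.05, rf = 0.2)
  tc <- implied_sigma("mrdoc2", p)
  expect_equal(tc$sigma_mz["PS1_t1", "Y_t1"], 0.2 * 0.05)
  expect_equal(tc$sigma_dz["PS1_t1", "Y_t1"], 0.2 * 0.05)
  # with vP != 1 the term scales with sqrt(vP1 * vP2)
  p2 <- mrdoc_params(b3 = 0.05, rf = 0.2, vP1 = 4, vP2 = 9)
  expect_equal(implied_sigma("mrdoc2", p2)$sigma_dz["PS1_t1", "Y_t1"],
               0.2 * sqrt(36) * 0.05)
})

test_that("path and variance-component styles agree for a consistent parameter set", {
  p <- design3_cell_params()
  a <- implied_sigma("mrdoc2", p, style = "path")
  b <- implied_sigma("mrdoc2", p, style = "varcomp")
  expect_equal(a$sigma_mz, b$sigma_mz)
  expect_equal(a$sigma_dz, b$sigma_dz)
})

test_that("degenerate inputs are rejected with explicit errors", {
  expect_error(implied_sigma("mrdoc2", mrdoc_params(g1 = 1, g2 = 1, b3 = 0.05)),
               "causal loop unit root")
  expect_error(mrdoc_params(VA1 = -0.1), "non-negative")
  expect_error(mrdoc_params(ra = 1.2), "\\[-1, 1\\]")
  expect_error(mrdoc_params(rhoX = 0), "\\(0, 1\\]")
  # PGS paths are structurally absent from DoC
  expect_error(implied_sigma("doc", mrdoc_params(b1 = 0.05)), "must be zero")
  expect_error(implied_sigma("mrdoc2", mrdoc_params(b2 = 0.05)), "must be zero")
})

test_that("implied covariance matches the structural Monte-Carlo oracle", {
  # moderate-n spot check with a multiplicity-aware 4-SE bound (the max is
  # taken over ~30 covariance entries); the 10^6-replicate 3-SE check runs
  # in the acceptance suite
  p <- design3_cell_params()
  expect_cov_matches_oracle("mrdoc2", p, "mz", n = 2e5, seed = 11, k = 4)
  expect_cov_matches_oracle("mrdoc2", p, "dz", n = 2e5, seed = 12, k = 4)
})
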