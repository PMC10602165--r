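#' Model-implied twin-pair covariance matrices
#'
#' Builds the model-implied covariance matrices of an MZ and a DZ twin pair
#' under the DoC, MR-DoC or MR-DoC2 model. Observed variables are ordered
#' `[PS1_t1, PS2_t1, X_t1, Y_t1, PS1_t2, PS2_t2, X_t2, Y_t2]`, dropping the
#' polygenic-score columns a model does not observe. Monozygotic co-twins
#' carry identical polygenic scores, so the MZ group observes each score
#' once (see [model_variables()]); the DZ group observes both, correlating
#' 0.5.
#'
#' The phenotypes form a (possibly) nonrecursive simultaneous system
#' `X = g2*Y + b1*PS1 + uX`, `Y = g1*X + b2*PS1 + b3*PS2 + uY`, solved in
#' reduced form through `Lambda = (I - B)^{-1}` with
#' `B = rbind(c(0, g2), c(g1, 0))`. Residuals follow a bivariate ACE
#' structure: additive-genetic factors correlate 1 (MZ) / 0.5 (DZ) across
#' twins, shared environment correlates 1, unshared environment 0. Polygenic
#' scores, being additive-genetic, share the 1 / 0.5 cross-twin correlation.
#'
#' @param kind model name: `"doc"`, `"mrdoc"` or `"mrdoc2"`.
#' @param params an [mrdoc_params()] object. Paths absent from `kind`
#'   (for example `b1` in DoC) must be zero.
#' @param style `"path"` rebuilds the ACE cross-trait covariances from the
#'   correlations `ra`, `rc`, `re`, `rf`; `"varcomp"` uses the stored
#'   covariances `CA`, `CC`, `CE`, `cF` directly. For a consistent object the
#'   two give identical matrices.
#' @return An object of class `twin_covariance`: list with elements
#'   `sigma_mz`, `sigma_dz` (symmetric positive-definite matrices with
#'   dimnames), `var_order` and `kind`.
#' @examples
#' p <- mrdoc_params(g1 = 0.04, g2 = 0.04, b1 = 0.05, b3 = 0.05,
#'                   ra = 0.2, rc = 0.2, re = 0.2, rf = 0.2)
#' tc <- implied_sigma("mrdoc2", p)
#' tc$sigma_mz["X_t1", "X_t2"]
#' @export
implied_sigma <- function(kind, params, style = c("path", "varcomp")) {
  kind <- match.arg(kind, MODEL_KINDS)
  style <- match.arg(style)
  stopifnot(inherits(params, "mrdoc_params"))
  check_generating_mask(kind, params)

  th <- as_theta(params)
  if (style == "path") {
    th["CA"] <- params$ra * sqrt(params$VA1 * params$VA2)
    th["CC"] <- params$rc * sqrt(params$VC1 * params$VC2)
    th["CE"] <- params$re * sqrt(params$VE1 * params$VE2)
    th["cF"] <- params$rf * sqrt(params$vP1 * params$vP2)
  }
  sig <- build_pair_sigma(th, kind)
  new_twin_covariance(sig$mz, sig$dz, kind,
                      context = "implied_sigma")
}

# Row/column indices retained per model and group within the 8-variable
# ordering [PS1_t1, PS2_t1, X_t1, Y_t1, PS1_t2, PS2_t2, X_t2, Y_t2].
PAIR_KEEP <- list(
  doc    = list(mz = c(3, 4, 7, 8), dz = c(3, 4, 7, 8)),
  mrdoc  = list(mz = c(1, 3, 4, 7, 8), dz = c(1, 3, 4, 5, 7, 8)),
  mrdoc2 = list(mz = c(1, 2, 3, 4, 7, 8), dz = 1:8)
)

# Assemble the 8-variable pair covariance from the canonical parameter
# vector, then drop the PGS rows/columns the model (and zygosity group)
# does not observe. Returns unclassed list(mz, dz); `label = FALSE` skips
# dimnames and symmetrization for the optimizer's hot path.
build_pair_sigma <- function(theta, kind, label = TRUE) {
  g1 <- theta[["g1"]]; g2 <- theta[["g2"]]
  det_ib <- 1 - g1 * g2
  if (!is.finite(det_ib) || abs(det_ib) < 1e-10) {
    stop("causal loop unit root: 1 - g1*g2 is numerically zero")
  }
  L <- matrix(c(1, g2, g1, 1), 2, 2, byrow = TRUE) / det_ib # (I - B)^{-1}
  G <- matrix(c(theta[["b1"]], 0, theta[["b2"]], theta[["b3"]]),
              2, 2, byrow = TRUE)                           # rows X,Y; cols PS1,PS2
  Pw <- matrix(c(theta[["vP1"]], theta[["cF"]],
                 theta[["cF"]], theta[["vP2"]]), 2, 2)
  cross_trait <- theta[["CA"]] + theta[["CC"]] + theta[["CE"]]
  Rw <- matrix(c(theta[["VA1"]] + theta[["VC1"]] + theta[["VE1"]], cross_trait,
                 cross_trait,
                 theta[["VA2"]] + theta[["VC2"]] + theta[["VE2"]]), 2, 2)

  one_group <- function(alpha) {
    Rx <- matrix(c(alpha * theta[["VA1"]] + theta[["VC1"]],
                   alpha * theta[["CA"]] + theta[["CC"]],
                   alpha * theta[["CA"]] + theta[["CC"]],
                   alpha * theta[["VA2"]] + theta[["VC2"]]), 2, 2)
    Px <- alpha * Pw
    LG <- L %*% G
    within <- rbind(
      cbind(Pw, Pw %*% t(LG)),
      cbind(LG %*% Pw, L %*% (G %*% Pw %*% t(G) + Rw) %*% t(L))
    )
    cross <- rbind(
      cbind(Px, Px %*% t(LG)),
      cbind(LG %*% Px, L %*% (G %*% Px %*% t(G) + Rx) %*% t(L))
    )
    rbind(cbind(within, cross), cbind(t(cross), within))
  }

  # MZ co-twins carry identical polygenic scores: the score enters the MZ
  # group once, otherwise the pair covariance is singular.
  keep <- PAIR_KEEP[[kind]]
  mz <- one_group(1)[keep$mz, keep$mz, drop = FALSE]
  dz <- one_group(0.5)[keep$dz, keep$dz, drop = FALSE]
  if (label) {
    mz <- (mz + t(mz)) / 2
    dz <- (dz + t(dz)) / 2
    dimnames(mz) <- rep(list(model_variables(kind, "mz")), 2)
    dimnames(dz) <- rep(list(model_variables(kind, "dz")), 2)
  }
  list(mz = mz, dz = dz)
}

new_twin_covariance <- function(sigma_mz, sigma_dz, kind, context = NULL) {
  for (nm in c("mz", "dz")) {
    m <- if (nm == "mz") sigma_mz else sigma_dz
    ev <- tryCatch(chol(m), error = function(e) NULL)
    if (is.null(ev)) {
      where <- if (is.null(context)) "" else paste0(" (", context, ")")
      stop(sprintf(
        "model-implied %s covariance is not positive definite%s", toupper(nm), where))
    }
  }
  structure(
    list(sigma_mz = sigma_mz, sigma_dz = sigma_dz,
         var_order = colnames(sigma_dz),
         var_order_mz = colnames(sigma_mz), kind = kind),
    class = "twin_covariance"
  )
}

#' @export
print.twin_covariance <- function(x, ...) {
  cat(sprintf("Twin-pair covariance (%s): %d DZ / %d MZ observed variables\n",
              x$kind, length(x$var_order), length(x$var_order_mz)))
  cat("  variables:", paste(x$var_order, collapse = ", "), "\n")
  cat("MZ:\n"); print(round(x$sigma_mz, 4))
  cat("DZ:\n"); print(round(x$sigma_dz, 4))
  invisible(x)
}

#' Marginal covariance of a nested model
#'
#' Extracts from a full MR-DoC2 pair covariance the marginal covariance over
#' the variables a nested model observes: MR-DoC drops PS2, DoC drops both
#' polygenic scores. Marginalization of a multivariate normal is row/column
#' selection, so retained entries are untouched.
#'
#' @param full a `twin_covariance` over the 8 MR-DoC2 variables.
#' @param kind target model.
#' @return A `twin_covariance` over `model_variables(kind)`.
#' @export
submodel_sigma <- function(full, kind) {
  stopifnot(inherits(full, "twin_covariance"))
  kind <- match.arg(kind, MODEL_KINDS)
  pick <- function(sig, want) {
    have <- colnames(sig)
    if (!all(want %in% have)) {
      stop(sprintf(
        "cannot marginalize to '%s': variables %s missing from input (order: %s)",
        kind, paste(setdiff(want, have), collapse = ", "),
        paste(have, collapse = ", ")))
    }
    idx <- match(want, have)
    sig[idx, idx, drop = FALSE]
  }
  new_twin_covariance(pick(full$sigma_mz, model_variables(kind, "mz")),
                      pick(full$sigma_dz, model_variables(kind, "dz")),
                      kind, context = "submodel_sigma")
}

#' Write a twin-pair covariance to CSV
#'
#' Serializes the MZ and DZ matrices of a `twin_covariance` to two CSV files
#' with the variable order as header row.
#'
#' @param tc a `twin_covariance`.
#' @param path_mz,path_dz output file paths.
#' @return Invisibly, `tc`.
#' @export
write_twin_covariance <- function(tc, path_mz, path_dz) {
  stopifnot(inherits(tc, "twin_covariance"))
  utils::write.csv(as.data.frame(tc$sigma_mz), path_mz, row.names = FALSE)
  utils::write.csv(as.data.frame(tc$sigma_dz), path_dz, row.names = FALSE)
  invisible(tc)
}
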