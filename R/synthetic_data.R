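#' Exact multivariate-normal sample
#'
#' Draws `n_pairs` twin-pair records whose sample covariance (divisor
#' `n - 1`) equals `target` to machine precision and whose column means are
#' exactly zero. Raw draws are centered, whitened by their own sample
#' covariance and recolored by the target (the `empirical = TRUE` mode of
#' [MASS::mvrnorm()]), so the guarantee is on the moments, not on individual
#' records: different seeds give different records with identical sample
#' covariance. Fitting a covariance-structure model to such data therefore
#' recovers the generating parameters exactly, and a constrained refit yields
#' the likelihood-ratio non-centrality parameter directly.
#'
#' @param target symmetric positive-definite covariance matrix (one group of
#'   a [implied_sigma()] result), with dimnames.
#' @param n_pairs number of pairs to draw; must exceed `ncol(target)`.
#' @param seed integer seed (records are reproducible; moments do not depend
#'   on it).
#' @param group group label, `"MZ"` or `"DZ"`.
#' @return Object of class `twin_group_data`: list with `group`, `n_pairs`,
#'   `values` (matrix, `n_pairs` x p), `sample_cov`, `seed`.
#' @examples
#' tc <- implied_sigma("doc", mrdoc_params(g1 = 0.04, ra = 0.2))
#' gd <- exact_mvn_sample(tc$sigma_mz, n_pairs = 100, seed = 1)
#' max(abs(gd$sample_cov - tc$sigma_mz))  # ~1e-15
#' @export
exact_mvn_sample <- function(target, n_pairs, seed = 1L, group = "MZ") {
  stopifnot(is.matrix(target), nrow(target) == ncol(target))
  group <- match.arg(toupper(group), c("MZ", "DZ"))
  p <- ncol(target)
  if (max(abs(target - t(target))) > 1e-12) stop("target must be symmetric")
  if (n_pairs <= p) {
    stop(sprintf("n_pairs (%d) must exceed the number of variables (%d)",
                 n_pairs, p))
  }
  ok <- tryCatch({chol(target); TRUE}, error = function(e) FALSE)
  if (!ok) stop("target covariance is not positive definite")

  set.seed(as.integer(seed))
  values <- MASS::mvrnorm(n_pairs, mu = rep(0, p), Sigma = target,
                          empirical = TRUE)
  colnames(values) <- colnames(target)
  structure(
    list(group = group, n_pairs = as.integer(n_pairs), values = values,
         sample_cov = stats::cov(values), seed = as.integer(seed)),
    class = "twin_group_data"
  )
}

#' @export
print.twin_group_data <- function(x, ...) {
  cat(sprintf("%s group: %d pairs x %d variables (seed %d)\n",
              x$group, x$n_pairs, ncol(x$values), x$seed))
  invisible(x)
}

#' Exact data for both zygosity groups
#'
#' Convenience wrapper generating exact MZ and DZ samples from a
#' `twin_covariance`.
#'
#' @param tc a [implied_sigma()] result.
#' @param n_mz,n_dz pairs per group.
#' @param seed master seed; the DZ group uses `seed + 1`.
#' @return List with elements `mz` and `dz`, each a `twin_group_data`.
#' @export
exact_twin_data <- function(tc, n_mz = 1000, n_dz = 1000, seed = 1L) {
  stopifnot(inherits(tc, "twin_covariance"))
  list(
    mz = exact_mvn_sample(tc$sigma_mz, n_mz, seed = seed, group = "MZ"),
    dz = exact_mvn_sample(tc$sigma_dz, n_dz, seed = seed + 1L, group = "DZ")
  )
}

#' Inject phenotype measurement error into a pair covariance
#'
#' Adds independent measurement error to each phenotype of each twin at the
#' population-covariance level. Reliability `rho` is the share of observed
#' variance due to true score, so the error variance is
#' `Var(true) * (1 - rho) / rho`, leaving `Var(true)/Var(observed) = rho`.
#' Only the phenotype diagonal entries change; every covariance (within-twin,
#' cross-twin, PGS-phenotype) and the PGS variances are untouched. Under
#' exact simulation this is equivalent to adding record-level noise, but is
#' deterministic.
#'
#' @param tc a `twin_covariance`.
#' @param rhoX,rhoY reliabilities of exposure and outcome in (0, 1]; 1 leaves
#'   the phenotype unchanged.
#' @return A `twin_covariance` with inflated phenotype variances.
#' @examples
#' tc <- implied_sigma("doc", mrdoc_params())
#' err <- add_measurement_error(tc, rhoX = 0.9, rhoY = 0.7)
#' err$sigma_mz["Y_t1", "Y_t1"] / tc$sigma_mz["Y_t1", "Y_t1"]  # 1/0.7
#' @export
add_measurement_error <- function(tc, rhoX = 0.90, rhoY = 0.70) {
  stopifnot(inherits(tc, "twin_covariance"))
  for (r in c(rhoX, rhoY)) {
    if (!is.finite(r) || r <= 0 || r > 1) {
      stop("reliabilities must lie in (0, 1]")
    }
  }
  inflate <- function(sig) {
    for (v in colnames(sig)) {
      rho <- if (startsWith(v, "X_")) rhoX else if (startsWith(v, "Y_")) rhoY else NA
      if (!is.na(rho)) sig[v, v] <- sig[v, v] + sig[v, v] * (1 - rho) / rho
    }
    sig
  }
  new_twin_covariance(inflate(tc$sigma_mz), inflate(tc$sigma_dz), tc$kind,
                      context = "add_measurement_error")
}

#' Write simulated twin-pair records to CSV
#'
#' One row per twin pair, one column per observed variable in the model's
#' variable order; plain comma-separated text for interoperability with
#' external SEM software.
#'
#' @param gd a `twin_group_data`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_pairs_csv <- function(gd, path) {
  stopifnot(inherits(gd, "twin_group_data"))
  utils::write.csv(as.data.frame(gd$values), path, row.names = FALSE)
  invisible(path)
}

#' Read twin-pair records written by [write_pairs_csv()]
#'
#' @param path CSV file, header row of variable labels.
#' @param group zygosity label for the resulting object.
#' @return A `twin_group_data` (seed recorded as `NA`).
#' @export
read_pairs_csv <- function(path, group = "MZ") {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  structure(
    list(group = match.arg(toupper(group), c("MZ", "DZ")),
         n_pairs = nrow(values), values = values,
         sample_cov = stats::cov(values), seed = NA_integer_),
    class = "twin_group_data"
  )
}
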