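SCENARIOS <- c("S1", "S2", "S3", "S4", "S5")

# One model fit within a scenario cell, with truth bookkeeping.
# gen_theta: canonical parameter vector of the generating process (the
# reference against which bias is computed). Returns the row fragment.
fit_cell <- function(kind, data, gen_theta, constraints = NULL) {
  fit <- fit_ml(kind, data$mz, data$dz, constraints = constraints,
                start = gen_theta)
  free <- names(fit$estimates)
  truth <- gen_theta[free]
  list(fit = fit, free = free, truth = truth,
       bias = fit$estimates - truth)
}

empty_param_cols <- function(prefix) {
  out <- as.list(rep(NA_real_, length(PARAM_NAMES)))
  names(out) <- paste0(prefix, PARAM_NAMES)
  out
}

result_row <- function(scenario, design_id, cell_index, re_level,
                       rhoX, rhoY, generator_kind, cellfit,
                       gen_row, ncp = NA_real_, df = NA_integer_,
                       power = NA_real_, test = NA_character_) {
  row <- c(
    list(scenario = scenario, design_id = design_id, cell_index = cell_index,
         re_level = re_level, rhoX = rhoX, rhoY = rhoY,
         generator_kind = generator_kind, fitted_kind = cellfit$fit$kind,
         converged = cellfit$fit$converged),
    as.list(stats::setNames(as.numeric(gen_row[c("b1", "b2", "b3", "g1", "g2",
                                                 "ra", "rc", "re", "rf")]),
                            paste0("gen_", c("b1", "b2", "b3", "g1", "g2",
                                             "ra", "rc", "re", "rf")))),
    empty_param_cols("true_"), empty_param_cols("est_"), empty_param_cols("bias_")
  )
  row[paste0("true_", cellfit$free)] <- as.list(cellfit$truth)
  row[paste0("est_", cellfit$free)] <- as.list(cellfit$fit$estimates)
  row[paste0("bias_", cellfit$free)] <- as.list(cellfit$bias)
  row$ncp <- ncp
  row$df <- df
  row$power <- power
  row$test <- test
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Full + constrained fit pair yielding the LRT non-centrality parameter.
# If numerical noise makes the statistic negative, the full model is refit
# from the constrained solution (which then dominates it) before giving up.
ncp_pair <- function(kind, data, gen_theta, constraints, alpha) {
  full <- fit_ml(kind, data$mz, data$dz, start = gen_theta)
  constr <- fit_ml(kind, data$mz, data$dz, constraints = constraints,
                   start = full$theta)
  if (constr$minus2lnL - full$minus2lnL < -1e-8) {
    refull <- fit_ml(kind, data$mz, data$dz, start = constr$theta)
    if (refull$minus2lnL < full$minus2lnL) full <- refull
  }
  list(full = full, constrained = constr,
       lrt = lrt_ncp(full, constr, alpha = alpha))
}

#' Run one of the five simulation scenarios
#'
#' Executes a complete bias or power study over the factorial design grids:
#'
#' * `S1`: unmodeled phenotype measurement error (reliabilities `rhoX`,
#'   `rhoY`), each model fit to exact data from its own design.
#' * `S2`: unshared-environment confounding generated at `re_levels` while
#'   DoC and MR-DoC are fit with `re` fixed to zero (MR-DoC2 estimates it);
#'   each model's own design as generator.
#' * `S3`: measurement error with MR-DoC2 (Design 3) as the generating
#'   process and all three models fitted.
#' * `S4`: `re` misspecification with MR-DoC2 as the generating process and
#'   all three models fitted.
#' * `S5`: power study — MR-DoC2 (Design 3) generates, all three models are
#'   fit unconstrained and with `g1 = 0`, and the likelihood-ratio
#'   non-centrality parameter and chi-square power are recorded per cell.
#'
#' Every cell uses exact data, so results are invariant to `master_seed`.
#'
#' @param scenario one of `"S1"` to `"S5"`.
#' @param n_mz,n_dz twin pairs per zygosity group.
#' @param alpha Type-I error rate for power.
#' @param rhoX,rhoY reliabilities used by the measurement-error scenarios.
#' @param re_levels levels of the unshared-environment confounding factor in
#'   S2/S4.
#' @param master_seed integer; fans out to per-cell seeds. Exact data makes
#'   all summaries independent of it; it only fixes the raw records.
#' @param cells optional integer vector restricting the grid to a subset of
#'   cell indices (useful for quick checks).
#' @param two_df if `TRUE`, S5 additionally records the 2-df joint test of
#'   `g1 = g2 = 0` in MR-DoC2.
#' @param verbose print per-cell progress to stderr.
#' @return A data frame of class `study_result`, one row per design cell x
#'   fitted model (x `re` level for S2/S4, x test for S5), carrying
#'   generating values (`gen_*`), truth/estimate/bias per free parameter
#'   (`true_*`, `est_*`, `bias_*`), and for S5 the columns `ncp`, `df`,
#'   `power`, `test`.
#' @examples
#' \donttest{
#' s5 <- run_scenario("S5", cells = 1:4)
#' s5[, c("cell_index", "fitted_kind", "ncp", "power")]
#' }
#' @export
run_scenario <- function(scenario = SCENARIOS,
                         n_mz = 1000, n_dz = 1000, alpha = 0.05,
                         rhoX = 0.90, rhoY = 0.70,
                         re_levels = c(-0.3, 0.3),
                         master_seed = 1L, cells = NULL,
                         two_df = FALSE, verbose = FALSE) {
  scenario <- match.arg(scenario)
  rows <- list()
  n_bad <- 0L
  task <- 0L

  say <- function(...) if (verbose) message(sprintf(...))

  own_design <- list(doc = 1, mrdoc = 2, mrdoc2 = 3)
  plan <- switch(scenario,
    S1 = lapply(MODEL_KINDS, function(m)
      list(gen_kind = m, design = own_design[[m]], fits = m,
           error = TRUE, re_override = NA)),
    S2 = unlist(lapply(MODEL_KINDS, function(m)
      lapply(re_levels, function(lv)
        list(gen_kind = m, design = own_design[[m]], fits = m,
             error = FALSE, re_override = lv))), recursive = FALSE),
    S3 = list(list(gen_kind = "mrdoc2", design = 3, fits = MODEL_KINDS,
                   error = TRUE, re_override = NA)),
    S4 = unlist(lapply(re_levels, function(lv)
      list(list(gen_kind = "mrdoc2", design = 3, fits = MODEL_KINDS,
                error = FALSE, re_override = lv))), recursive = FALSE),
    S5 = list(list(gen_kind = "mrdoc2", design = 3, fits = MODEL_KINDS,
                   error = FALSE, re_override = NA))
  )

  for (block in plan) {
    grid <- design_grid(block$design)
    idx <- if (is.null(cells)) seq_len(nrow(grid$cells)) else
      intersect(cells, seq_len(nrow(grid$cells)))
    for (i in idx) {
      task <- task + 1L
      overrides <- if (!is.na(block$re_override)) {
        list(re = block$re_override)
      } else NULL
      params <- cell_params(grid, i, overrides)
      gen_theta <- as_theta(params)
      gen_row <- unlist(params[c("b1", "b2", "b3", "g1", "g2",
                                 "ra", "rc", "re", "rf")])
      tc <- implied_sigma(block$gen_kind, params)
      use_rhoX <- if (block$error) rhoX else 1
      use_rhoY <- if (block$error) rhoY else 1
      if (block$error) tc <- add_measurement_error(tc, rhoX, rhoY)
      data <- exact_twin_data(tc, n_mz, n_dz,
                              seed = as.integer(master_seed + 2L * task))

      for (fk in block$fits) {
        if (scenario == "S5") {
          pair <- ncp_pair(fk, data, gen_theta, c(g1 = 0), alpha)
          cf <- list(fit = pair$full, free = names(pair$full$estimates),
                     truth = gen_theta[names(pair$full$estimates)],
                     bias = pair$full$estimates -
                       gen_theta[names(pair$full$estimates)])
          rows[[length(rows) + 1L]] <- result_row(
            scenario, block$design, i, block$re_override, use_rhoX, use_rhoY,
            block$gen_kind, cf, gen_row,
            ncp = pair$lrt$ncp, df = pair$lrt$df, power = pair$lrt$power,
            test = "g1")
          n_bad <- n_bad + !pair$full$converged
          if (two_df && fk == "mrdoc2") {
            pair2 <- ncp_pair(fk, data, gen_theta, c(g1 = 0, g2 = 0), alpha)
            cf2 <- list(fit = pair2$full, free = names(pair2$full$estimates),
                        truth = gen_theta[names(pair2$full$estimates)],
                        bias = pair2$full$estimates -
                          gen_theta[names(pair2$full$estimates)])
            rows[[length(rows) + 1L]] <- result_row(
              scenario, block$design, i, block$re_override,
              use_rhoX, use_rhoY, block$gen_kind, cf2, gen_row,
              ncp = pair2$lrt$ncp, df = pair2$lrt$df, power = pair2$lrt$power,
              test = "g1,g2")
          }
        } else {
          cf <- fit_cell(fk, data, gen_theta)
          rows[[length(rows) + 1L]] <- result_row(
            scenario, block$design, i, block$re_override, use_rhoX, use_rhoY,
            block$gen_kind, cf, gen_row)
          n_bad <- n_bad + !cf$fit$converged
        }
      }
      say("%s design %d cell %d/%d done", scenario, block$design, i,
          length(idx))
    }
  }

  out <- do.call(rbind, rows)
  if (n_bad > 0) {
    message(sprintf("run_scenario(%s): %d non-converged fit(s) flagged",
                    scenario, n_bad))
  }
  attr(out, "scenario") <- scenario
  attr(out, "alpha") <- alpha
  attr(out, "n_mz") <- n_mz
  attr(out, "n_dz") <- n_dz
  attr(out, "master_seed") <- master_seed
  class(out) <- c("study_result", class(out))
  out
}

#' Mean estimation bias per fitted model and parameter
#'
#' Averages `estimate - truth` across design cells, per fitted model and
#' free parameter; negative means underestimation. Non-converged fits are
#' excluded (with a message giving the count).
#'
#' @param results a `study_result` from [run_scenario()].
#' @return Data frame with `fitted_kind`, `parameter`, `mean_bias`,
#'   `n_cells`.
#' @export
bias_summary <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("empty results: nothing to summarize")
  }
  dropped <- sum(!results$converged)
  if (dropped > 0) {
    message(sprintf("bias_summary: excluding %d non-converged fit(s)", dropped))
    results <- results[results$converged, , drop = FALSE]
    if (nrow(results) == 0) stop("no converged fits to summarize")
  }
  out <- list()
  for (fk in unique(results$fitted_kind)) {
    sub <- results[results$fitted_kind == fk, , drop = FALSE]
    for (p in free_parameters(fk)) {
      b <- sub[[paste0("bias_", p)]]
      b <- b[!is.na(b)]
      if (!length(b)) next
      out[[length(out) + 1L]] <- data.frame(
        fitted_kind = fk, parameter = p,
        mean_bias = mean(b), n_cells = length(b))
    }
  }
  do.call(rbind, out)
}

#' Regress non-centrality parameters on design-factor values
#'
#' Ordinary least squares of the per-cell `g1 = 0` non-centrality parameter
#' on the six varying Design-3 factors (`b1`, `b3`, `g1`, `g2`, `ra`, `rc`)
#' with an intercept, for one fitted model. The R-squared is the share of
#' NCP variance across cells explained by the parameter values; the
#' coefficients gauge each parameter's contribution to power. Standardized
#' coefficients (slope x sd(factor)/sd(NCP)) are also returned so factors on
#' different scales are comparable.
#'
#' @param results S5 rows from [run_scenario()].
#' @param fitted_kind which fitted model's NCPs to regress.
#' @return Object of class `ncp_power_regression`: `fitted_kind`,
#'   `intercept`, `coefficients`, `std_coefficients`, `r_squared`,
#'   `n_cells`.
#' @export
ncp_regression <- function(results, fitted_kind) {
  fitted_kind <- match.arg(fitted_kind, MODEL_KINDS)
  sub <- results[results$fitted_kind == fitted_kind &
                   !is.na(results$ncp) &
                   (is.na(results$test) | results$test == "g1"), ,
                 drop = FALSE]
  if (nrow(sub) == 0) stop("no NCP rows for model '", fitted_kind, "'")
  predictors <- c("gen_b1", "gen_b3", "gen_g1", "gen_g2", "gen_ra", "gen_rc")
  if (stats::var(sub$ncp) == 0) {
    stop("NCP response is constant across cells; R-squared undefined")
  }
  fml <- stats::as.formula(paste("ncp ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = sub)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient NCP regression; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  slopes <- cf[-1]
  names(slopes) <- sub("^gen_", "", names(slopes))
  sds <- vapply(predictors, function(p) stats::sd(sub[[p]]), numeric(1))
  std <- slopes * sds / stats::sd(sub$ncp)
  structure(
    list(fitted_kind = fitted_kind,
         intercept = unname(cf[1]),
         coefficients = slopes,
         std_coefficients = std,
         r_squared = summary(fit)$r.squared,
         n_cells = nrow(sub)),
    class = "ncp_power_regression"
  )
}

#' @export
print.ncp_power_regression <- function(x, ...) {
  cat(sprintf("NCP regression for %s over %d cells: R-squared = %.4f\n",
              x$fitted_kind, x$n_cells, x$r_squared))
  tab <- rbind(slope = x$coefficients, standardized = x$std_coefficients)
  print(round(tab, 4))
  invisible(x)
}
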