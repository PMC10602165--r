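#' @keywords internal
MODEL_KINDS <- c("doc", "mrdoc", "mrdoc2")

# Canonical ordering of the full parameter vector used throughout the
# package. Paths first, then residual ACE variance components, then the
# ACE cross-trait covariances, then polygenic-score moments.
PARAM_NAMES <- c(
  "g1", "g2", "b1", "b2", "b3",
  "VA1", "VC1", "VE1", "VA2", "VC2", "VE2",
  "CA", "CC", "CE",
  "vP1", "vP2", "cF"
)

#' Model parameter set for the twin-MR models
#'
#' Bundles the full parameter vector shared by the DoC, MR-DoC and MR-DoC2
#' models: causal paths (`g1` exposure to outcome, `g2` outcome to exposure),
#' instrument paths (`b1` PS1 to exposure, `b3` PS2 to outcome), directional
#' horizontal pleiotropy (`b2`, PS1 to outcome), residual ACE variance
#' components of each phenotype, cross-trait factor correlations (`ra`, `rc`,
#' `re`), the polygenic-score variances and their correlation (`rf`), and the
#' phenotype reliabilities used only by [add_measurement_error()].
#'
#' Correlations are stored alongside the implied factor covariances
#' (`CA = ra * sqrt(VA1 * VA2)` and so on), so the same object serves the
#' path-style and variance-component-style matrix builders.
#'
#' @param g1,g2 causal regression weights (exposure->outcome, outcome->exposure).
#' @param b1 instrument path from PS1 to the exposure.
#' @param b2 directional horizontal pleiotropy, PS1 to the outcome
#'   (a free parameter only in MR-DoC; structurally zero in MR-DoC2).
#' @param b3 instrument path from PS2 to the outcome (MR-DoC2 only).
#' @param VA1,VC1,VE1 additive-genetic, shared- and unshared-environment
#'   residual variances of the exposure.
#' @param VA2,VC2,VE2 the same for the outcome.
#' @param ra,rc,re cross-trait correlations of the A, C and E factors.
#' @param rf correlation between the two polygenic scores.
#' @param vP1,vP2 variances of PS1 and PS2.
#' @param rhoX,rhoY phenotype reliabilities in (0, 1]; 1 means error-free.
#' @return An object of class `mrdoc_params`.
#' @examples
#' p <- mrdoc_params(g1 = 0.04, b1 = 0.05, ra = 0.2, rc = 0.2)
#' p$CA  # = 0.2 * sqrt(0.1 * 0.1)
#' @export
mrdoc_params <- function(g1 = 0, g2 = 0, b1 = 0, b2 = 0, b3 = 0,
                         VA1 = 0.10, VC1 = 0.10, VE1 = 0.80,
                         VA2 = 0.10, VC2 = 0.10, VE2 = 0.80,
                         ra = 0, rc = 0, re = 0, rf = 0,
                         vP1 = 1, vP2 = 1,
                         rhoX = 1, rhoY = 1) {
  vars <- c(VA1 = VA1, VC1 = VC1, VE1 = VE1,
            VA2 = VA2, VC2 = VC2, VE2 = VE2, vP1 = vP1, vP2 = vP2)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop("variance components must be finite and non-negative")
  }
  cors <- c(ra = ra, rc = rc, re = re, rf = rf)
  if (any(!is.finite(cors)) || any(abs(cors) > 1)) {
    stop("correlations ra, rc, re, rf must lie in [-1, 1]")
  }
  for (r in c(rhoX = rhoX, rhoY = rhoY)) {
    if (!is.finite(r) || r <= 0 || r > 1) {
      stop("reliabilities rhoX, rhoY must lie in (0, 1]")
    }
  }
  out <- list(
    g1 = g1, g2 = g2, b1 = b1, b2 = b2, b3 = b3,
    VA1 = VA1, VC1 = VC1, VE1 = VE1, VA2 = VA2, VC2 = VC2, VE2 = VE2,
    ra = ra, rc = rc, re = re, rf = rf,
    vP1 = vP1, vP2 = vP2,
    CA = ra * sqrt(VA1 * VA2),
    CC = rc * sqrt(VC1 * VC2),
    CE = re * sqrt(VE1 * VE2),
    cF = rf * sqrt(vP1 * vP2),
    rhoX = rhoX, rhoY = rhoY
  )
  class(out) <- "mrdoc_params"
  out
}

#' @export
print.mrdoc_params <- function(x, ...) {
  cat("Twin-MR model parameters\n")
  paths <- unlist(x[c("g1", "g2", "b1", "b2", "b3")])
  cat("  paths:      ", paste(names(paths), signif(paths, 4),
                              sep = "=", collapse = "  "), "\n")
  cat("  exposure:    VA1=", x$VA1, " VC1=", x$VC1, " VE1=", x$VE1, "\n", sep = "")
  cat("  outcome:     VA2=", x$VA2, " VC2=", x$VC2, " VE2=", x$VE2, "\n", sep = "")
  cat("  correlations: ra=", x$ra, " rc=", x$rc, " re=", x$re,
      " rf=", x$rf, "\n", sep = "")
  invisible(x)
}

#' Full parameter vector of a parameter set
#'
#' Flattens an [mrdoc_params()] object to the canonical named numeric vector
#' (paths, ACE variances, ACE cross-trait covariances, PGS moments) used by
#' the matrix builder and the fitter.
#'
#' @param params an `mrdoc_params` object.
#' @return Named numeric vector over the canonical parameter names.
#' @export
as_theta <- function(params) {
  stopifnot(inherits(params, "mrdoc_params"))
  vapply(PARAM_NAMES, function(nm) params[[nm]], numeric(1))
}

#' Observed variables of a model
#'
#' Variable labels per model and zygosity group, twin-1 block before twin-2
#' block, PGS columns before phenotypes within a twin. Monozygotic twins
#' carry identical polygenic scores, so the MZ group observes each score
#' once (as `PS*_t1`); including it twice would make the MZ pair covariance
#' singular. Dizygotic co-twins' scores correlate 0.5 and both are observed.
#'
#' @param kind model name.
#' @param group `"dz"` (default, the full variable set) or `"mz"`.
#' @return Character vector of variable labels.
#' @export
model_variables <- function(kind, group = c("dz", "mz")) {
  kind <- match.arg(kind, MODEL_KINDS)
  group <- match.arg(group)
  keep <- switch(kind,
    doc    = c("X", "Y"),
    mrdoc  = c("PS1", "X", "Y"),
    mrdoc2 = c("PS1", "PS2", "X", "Y")
  )
  vars <- c(paste0(keep, "_t1"), paste0(keep, "_t2"))
  if (group == "mz") vars <- vars[!grepl("^PS[12]_t2$", vars)]
  vars
}

# Parameters fixed (not estimated) under each model's identification
# constraints; values are the fixed values. A bivariate twin model is
# identified with any three of {g1, g2, ra, rc, re} free: the
# unidirectional specification frees g1, ra, rc (g2 = re = 0, the Design 1/2
# parameter lists); the bidirectional specification frees g1, g2, rc (ra = re = 0).
# b2 is structurally zero in MR-DoC2. PGS moments that the model does not
# observe are pinned at arbitrary reference values (they never enter the
# retained blocks).
fitting_mask <- function(kind, causal = c("unidirectional", "bidirectional")) {
  kind <- match.arg(kind, MODEL_KINDS)
  causal <- match.arg(causal)
  if (causal == "unidirectional" || kind == "mrdoc2") {
    switch(kind,
      doc    = c(g2 = 0, b1 = 0, b2 = 0, b3 = 0, CE = 0,
                 vP1 = 1, vP2 = 1, cF = 0),
      mrdoc  = c(g2 = 0, b3 = 0, CE = 0, vP2 = 1, cF = 0),
      mrdoc2 = c(b2 = 0)
    )
  } else {
    switch(kind,
      doc   = c(b1 = 0, b2 = 0, b3 = 0, CA = 0, CE = 0,
                vP1 = 1, vP2 = 1, cF = 0),
      mrdoc = c(b3 = 0, CA = 0, CE = 0, vP2 = 1, cF = 0)
    )
  }
}

#' Free parameters of a model
#'
#' The parameters estimated when fitting `kind` in the variance-component
#' parameterization: 9 for DoC, 12 for MR-DoC, 16 for MR-DoC2. MR-DoC2 is
#' bidirectional by construction; for DoC and MR-DoC the `causal`
#' specification selects which three of the five trait-connecting paths
#' (`g1`, `g2`, `ra`, `rc`, `re`) are freed: `g1`, `ra`, `rc`
#' (unidirectional, the default) or `g1`, `g2`, `rc` (bidirectional).
#'
#' @param kind one of `"doc"`, `"mrdoc"`, `"mrdoc2"`.
#' @param causal `"unidirectional"` or `"bidirectional"`; ignored for
#'   MR-DoC2.
#' @return Character vector of free parameter names.
#' @export
free_parameters <- function(kind, causal = c("unidirectional", "bidirectional")) {
  setdiff(PARAM_NAMES, names(fitting_mask(kind, causal)))
}

# Structural zeros a *generating* parameter set must satisfy for a given
# model (looser than fitting_mask: generation may use re != 0 or g2 != 0 to
# build misspecification studies).
check_generating_mask <- function(kind, params) {
  kind <- match.arg(kind, MODEL_KINDS)
  bad <- switch(kind,
    doc    = c("b1", "b2", "b3")[c(params$b1, params$b2, params$b3) != 0],
    mrdoc  = "b3"[params$b3 != 0],
    mrdoc2 = "b2"[params$b2 != 0]
  )
  if (length(bad)) {
    stop(sprintf("parameter(s) %s must be zero for model '%s'",
                 paste(bad, collapse = ", "), kind))
  }
  invisible(TRUE)
}
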