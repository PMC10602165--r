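#' Factorial simulation design grids
#'
#' The three factorial designs over which the bias and power studies run.
#' Design 1 (DoC) varies `g1`, `ra`, `rc` (8 cells); Design 2 (MR-DoC) adds
#' `b1` and `b2` (32 cells); Design 3 (MR-DoC2) varies `b1`, `b3`, `g1`,
#' `g2`, `ra`, `rc` with `re` and `rf` held at 0.2 (64 cells). In every
#' design the residual ACE variances are `VA = VC = 0.10` per trait with
#' `VE = 1 - VA - VC = 0.80`, so each phenotype has unit residual variance,
#' and the polygenic scores have unit variance.
#'
#' @param design_id 1, 2 or 3.
#' @return Object of class `design_grid`: `design_id`, `kind` (generating
#'   model), `factors` (named list of levels), `fixed` (named list), and
#'   `cells` (data frame, one row per cell of the Cartesian product, with a
#'   `cell_index` column).
#' @examples
#' design_grid(3)$cells[1, ]
#' @export
design_grid <- function(design_id) {
  stopifnot(design_id %in% 1:3)
  factors <- switch(design_id,
    `1` = list(g1 = c(0.02, 0.04), ra = c(0, 0.2), rc = c(0, 0.2)),
    `2` = list(b1 = c(0.025, 0.05), b2 = c(0.025, 0.05),
               g1 = c(0.02, 0.04), ra = c(0, 0.2), rc = c(0, 0.2)),
    `3` = list(b1 = c(0.025, 0.05), b3 = c(0.025, 0.05),
               g1 = c(0.02, 0.04), g2 = c(0.02, 0.04),
               ra = c(0, 0.2), rc = c(0, 0.2))
  )
  fixed <- list(
    VA1 = 0.10, VC1 = 0.10, VE1 = 0.80,
    VA2 = 0.10, VC2 = 0.10, VE2 = 0.80,
    vP1 = 1, vP2 = 1,
    g2 = 0, b1 = 0, b2 = 0, b3 = 0, re = 0, rf = 0
  )
  if (design_id == 3) {
    fixed$re <- 0.2
    fixed$rf <- 0.2
  }
  fixed <- fixed[setdiff(names(fixed), names(factors))]
  cells <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE)
  for (nm in names(fixed)) cells[[nm]] <- fixed[[nm]]
  cells <- cbind(cell_index = seq_len(nrow(cells)), cells)
  structure(
    list(design_id = design_id,
         kind = c("doc", "mrdoc", "mrdoc2")[design_id],
         factors = factors, fixed = fixed, cells = cells),
    class = "design_grid"
  )
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("Design %d (%s): %d cells\n", x$design_id, x$kind,
              nrow(x$cells)))
  for (nm in names(x$factors)) {
    cat(sprintf("  %-3s in {%s}\n", nm, paste(x$factors[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# Parameter object for one grid cell, with optional overrides (e.g. the
# re = +/-0.3 misspecification factor).
cell_params <- function(grid, i, overrides = NULL) {
  row <- as.list(grid$cells[i, setdiff(names(grid$cells), "cell_index")])
  if (!is.null(overrides)) row[names(overrides)] <- overrides
  do.call(mrdoc_params, row)
}
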