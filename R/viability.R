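# Viability imputation from four-parameter log-logistic dose-response
# parameters, and the growth-enhancement filter.

#' Four-parameter log-logistic curve
#'
#' Relative viability at concentration `x` for parameters slope `b`, lower
#' asymptote `c`, upper asymptote `d` and inflection concentration `e`:
#' `c + (d - c) / (1 + exp(b * (ln x - ln e)))`. Natural logarithms are used
#' throughout; the curve is invariant to log base given a matching slope.
#' With `b > 0` and `d > c` the curve decreases from `d` toward `c`; at
#' `x = e` it passes through `(c + d) / 2`.
#'
#' @param x Concentration(s), molar, strictly positive.
#' @param b,c,d,e Curve parameters; `e` must be > 0.
#' @return Viability value(s), vectorized over `x`.
#' @export
#' @examples
#' ll4(3e-6, b = 1, c = 0, d = 1, e = 1e-6)  # 1 / (1 + 3) = 0.25
ll4 <- function(x, b, c, d, e) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("concentrations must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(e) || e <= 0) stop("'e' must be > 0", call. = FALSE)
  if (!is.finite(b)) stop("'b' must be finite", call. = FALSE)
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Impute relative viability at a concentration grid
#'
#' Evaluates each (cell line, compound) dose-response curve at every grid
#' concentration, producing one viability record per combination and
#' concentration: 0 means complete cell death, 1 no effect. Combinations
#' with non-finite parameters are skipped with a log entry. Clipping is off
#' by default (fitted curves legitimately exceed 1); pass `clip = c(0, 1.2)`
#' to bound the records.
#'
#' @param params data.frame with cell_line, compound, b, c, d, e.
#' @param doseGrid Molar concentrations to evaluate.
#' @param clip `NULL` (no clipping) or a length-2 numeric bound.
#' @return data.frame with cell_line, compound, concentration,
#'   imputed_viability; skipped combinations attached as the `"skipped"`
#'   attribute.
#' @export
imputeViability <- function(params, doseGrid, clip = NULL) {
  stopifnot(all(c("cell_line", "compound", "b", "c", "d", "e") %in%
                colnames(params)))
  doseGrid <- as.numeric(doseGrid)
  ok <- is.finite(params$b) & is.finite(params$c) & is.finite(params$d) &
    is.finite(params$e) & params$e > 0
  if (any(!ok)) {
    .log("skipping %d combinations with non-finite curve parameters",
         sum(!ok))
  }
  good <- params[ok, , drop = FALSE]
  nD <- length(doseGrid)
  n <- nrow(good)
  # Vectorized over combinations: rows combos, cols doses.
  v <- if (n) {
    lx <- matrix(log(doseGrid), n, nD, byrow = TRUE)
    good$c + (good$d - good$c) /
      (1 + exp(good$b * (lx - log(good$e))))
  } else {
    matrix(numeric(0), 0, nD)
  }
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] < clip[2])
    v <- pmin(pmax(v, clip[1]), clip[2])
    .log("clipped imputed viabilities to [%g, %g]", clip[1], clip[2])
  }
  out <- data.frame(
    cell_line = rep(good$cell_line, each = nD),
    compound = rep(good$compound, each = nD),
    concentration = rep(doseGrid, times = n),
    imputed_viability = if (n) as.vector(t(v)) else numeric(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- params[!ok, c("cell_line", "compound"),
                                 drop = FALSE]
  out
}

#' Remove growth-enhancing dose-response curves
#'
#' A (cell line, compound) combination indicates enhanced growth with
#' increasing compound concentration when its curve evaluates higher at the
#' top of the grid than at the bottom; such parameter sets are removed.
#' Endpoint comparison is monotone-consistent for log-logistic curves, which
#' are monotone in concentration.
#'
#' @param params data.frame with cell_line, compound, b, c, d, e.
#' @param doseGrid Molar concentration grid.
#' @return List with `kept` and `removed` data.frames partitioning the
#'   input.
#' @export
filterGrowthEnhancing <- function(params, doseGrid) {
  stopifnot(length(doseGrid) >= 1L)
  doseGrid <- as.numeric(doseGrid)
  lo <- min(doseGrid); hi <- max(doseGrid)
  vLo <- params$c + (params$d - params$c) /
    (1 + exp(params$b * (log(lo) - log(params$e))))
  vHi <- params$c + (params$d - params$c) /
    (1 + exp(params$b * (log(hi) - log(params$e))))
  growing <- vHi > vLo
  .log("removed %d growth-enhancing parameter sets", sum(growing))
  list(kept = params[!growing, , drop = FALSE],
       removed = params[growing, , drop = FALSE])
}
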