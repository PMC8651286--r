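# Spike-in mixture design and linear recovery calibration: leukocyte DNA
# diluted into an immune-null background (e.g. HEK-293 embryonic kidney
# line DNA) at known proportions, measured with the panel, and regressed
# observed vs expected to obtain per-cell-type calibration coefficients.

#' Spike-in mixture design
#'
#' @param leukocyte_fractions Numeric vector of leukocyte proportions of the
#'   mixture points, in \[0,1\]. The default series spans 100% leukocyte DNA
#'   down to 5% (a 20-fold dilution).
#' @param composition Named per-cell-type fractions of the leukocyte DNA,
#'   summing to 1.
#' @param background Label of the immune-null background DNA.
#' @return A list of class `mixture_design`.
#' @export
mixture_design <- function(leukocyte_fractions = c(1, 0.5, 0.25, 0.1, 0.05),
                           composition = c(neutrophil = 0.55, monocyte = 0.10,
                                           eosinophil = 0.05, tcell = 0.15,
                                           bcell = 0.08, cd8 = 0.05,
                                           treg = 0.02),
                           background = "HEK293") {
  .check(all(leukocyte_fractions >= 0 & leukocyte_fractions <= 1),
         "leukocyte_fractions must lie in [0,1]")
  .check(abs(sum(composition) - 1) <= 1e-9, "composition must sum to 1")
  structure(list(leukocyte_fractions = leukocyte_fractions,
                 composition = composition, background = background),
            class = "mixture_design")
}

#' Expected cell-type fractions of a mixture design
#'
#' expected(cell type, point) = leukocyte fraction x leukocyte composition.
#'
#' @param design A [mixture_design()].
#' @return Long data.frame: `point`, `leukocyte_fraction`, `cell_type`,
#'   `expected`.
#' @export
expected_fractions <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  lf <- design$leukocyte_fractions
  comp <- design$composition
  out <- expand.grid(point = seq_along(lf), cell_type = names(comp),
                     stringsAsFactors = FALSE)
  out$leukocyte_fraction <- lf[out$point]
  out$expected <- out$leukocyte_fraction * comp[out$cell_type]
  out[, c("point", "leukocyte_fraction", "cell_type", "expected")]
}

#' Fit the linear recovery of observed vs expected fractions
#'
#' Ordinary least squares of observed on expected, as used to calibrate the
#' methylation markers against known mixtures (or against CBC-derived
#' expected fractions through the same interface).
#'
#' @param observed,expected Paired numeric vectors (n >= 2, expected not all
#'   equal).
#' @param cell_type Optional label carried into the result.
#' @return A list of class `recovery_fit`: `cell_type`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_recovery <- function(observed, expected, cell_type = NA_character_) {
  keep <- !is.na(observed) & !is.na(expected)
  observed <- observed[keep]; expected <- expected[keep]
  .check(length(observed) >= 2, "need at least 2 points")
  .check(stats::var(expected) > 0, "degenerate design: expected values all equal")
  fit <- stats::lm(observed ~ expected)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(cell_type = cell_type,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(observed)),
            class = "recovery_fit")
}

#' Derive a calibration table from recovery fits
#'
#' The fitted slope becomes the per-cell-type divisor (a slope of 0.69 for
#' neutrophils reproduces the published divisor). Intercepts are reported as
#' a QC metric but never subtracted, so corrected fractions stay
#' non-negative.
#'
#' @param fits A list of [fit_recovery()] results with `cell_type` set.
#' @return A [calibration_table()] whose `note` records intercept and r².
#' @export
derive_coefficients <- function(fits) {
  cts <- vapply(fits, `[[`, character(1), "cell_type")
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  bad <- slopes <= 0
  .check(!any(bad), "non-positive recovery slope for cell type %s",
         paste(cts[bad], collapse = ", "))
  notes <- vapply(fits, function(f)
    sprintf("spike-in fit: intercept=%.4g r2=%.4f n=%d",
            f$intercept, f$r_squared, f$n_points), character(1))
  names(slopes) <- cts
  names(notes) <- cts
  calibration_table(slopes, notes)
}
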