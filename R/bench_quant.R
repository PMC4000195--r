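#' Relative qPCR expression normalized to a reference gene
#'
#' Computes relative expression of a target gene against a housekeeping
#' reference (e.g. Gapdh) from threshold cycles. The default convention is
#' the standard 2^-(Ct_gene - Ct_ref), scaled by `scale` (default 100), so
#' that a lower target Ct (more transcript) gives a higher value. The
#' `as_printed` convention computes 2^+(Ct_gene - Ct_ref) instead, keeping
#' the sign exactly as some Methods sections print the formula; the default
#' is the convention whose output increases with expression.
#'
#' @param ct_gene,ct_reference Positive finite threshold cycles
#'   (vectorized).
#' @param scale Multiplier for presentation (default 100).
#' @param sign_convention "delta_ct_negated" (default) or "as_printed".
#' @return Nonnegative numeric vector.
#' @export
relative_expression <- function(ct_gene, ct_reference, scale = 100,
                                sign_convention = c("delta_ct_negated",
                                                    "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(all(is.finite(ct_gene) & ct_gene > 0),
            all(is.finite(ct_reference) & ct_reference > 0))
  dct <- ct_gene - ct_reference
  if (sign_convention == "delta_ct_negated") dct <- -dct
  scale * 2^dct
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' volume = 0.5 * length * width^2 (mm^3), the standard caliper formula for
#' subcutaneous tumors. Warns (without failing) when width exceeds length,
#' since the convention takes length as the larger dimension.
#'
#' @param length_mm,width_mm Nonnegative dimensions in mm (vectorized).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0 | width_mm < 0)) stop("dimensions must be nonnegative")
  if (any(width_mm > length_mm)) {
    warning("width exceeds length; check measurement convention")
  }
  0.5 * length_mm * width_mm^2
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of absorbance on concentration, as used to
#' quantify nitrite (Griess assay against a sodium nitrite dilution series)
#' or urea. Use [interpolate_concentration()] to invert it for test samples.
#'
#' @param concentrations Nonnegative standards (>= 2 distinct values);
#'   state the unit (e.g. mM) in downstream reporting.
#' @param absorbances Matching absorbance readings.
#' @return A `standard_curve`: concentrations, absorbances, slope,
#'   intercept, r_squared.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  stopifnot(length(concentrations) == length(absorbances),
            length(concentrations) >= 2L,
            all(concentrations >= 0))
  if (length(unique(concentrations)) < 2L) {
    stop("singular fit: all concentrations identical")
  }
  fit <- stats::lm(absorbances ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(concentrations = concentrations,
                 absorbances = absorbances,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = max(0, min(1, r2))),
            class = "standard_curve")
}

#' Interpolate concentration from absorbance on a standard curve
#'
#' Inverts the fitted line. Readings outside the calibrated absorbance
#' range are still converted but flagged with a warning (extrapolation).
#'
#' @param curve A `standard_curve`.
#' @param absorbance Absorbance reading(s).
#' @return Concentration(s) on the standards' scale.
#' @export
interpolate_concentration <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("flat standard curve: cannot invert")
  fitted_rng <- range(curve$intercept + curve$slope * curve$concentrations)
  if (any(absorbance < fitted_rng[1] | absorbance > fitted_rng[2])) {
    warning("absorbance outside calibrated range: extrapolating")
  }
  (absorbance - curve$intercept) / curve$slope
}

#' Arginase activity in enzyme units
#'
#' One unit is the amount of enzyme catalyzing the formation of 1 umol urea
#' per minute.
#'
#' @param urea_umol Nonnegative urea formed (umol).
#' @param minutes Positive incubation time (min).
#' @return Activity in units.
#' @export
arginase_units <- function(urea_umol, minutes) {
  if (any(minutes <= 0)) stop("minutes must be > 0")
  if (any(urea_umol < 0)) stop("urea_umol must be nonnegative")
  urea_umol / minutes
}
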