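#' Garbowski T2* to liver iron concentration calibration
#'
#' The calibration is the power law \eqn{LIC = a \cdot T2*^{b}} with
#' published coefficients a = 31.94 and b = -1.014, mapping an effective
#' transverse relaxation time in milliseconds to a liver iron concentration
#' (LIC) in mg per g dry weight. The coefficients are configuration, not
#' constants, so alternative calibrations can be swapped in.
#'
#' @param coefficient multiplicative coefficient a (mg/g dry weight).
#' @param exponent power-law exponent b (dimensionless, negative).
#' @return An object of class `garbowski_calibration`.
#' @export
garbowski_calibration <- function(coefficient = 31.94, exponent = -1.014) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient), coefficient > 0,
            is.numeric(exponent), length(exponent) == 1L,
            is.finite(exponent), exponent < 0)
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "garbowski_calibration")
}

#' Convert T2* to liver iron concentration
#'
#' @param t2star T2* value(s) in ms; must be strictly positive.
#' @param calibration a [garbowski_calibration()] object.
#' @return LIC in mg/g dry weight; strictly decreasing in `t2star`.
#' @examples
#' t2star_to_lic(1.0)  # 31.94
#' @export
t2star_to_lic <- function(t2star, calibration = garbowski_calibration()) {
  if (!is.numeric(t2star) || any(!is.finite(t2star)) || any(t2star <= 0)) {
    stop("t2star must be finite and > 0", call. = FALSE)
  }
  calibration$coefficient * t2star^calibration$exponent
}

#' Invert the calibration: liver iron concentration to T2*
#'
#' Algebraic inverse of [t2star_to_lic()]: \eqn{T2* = (a / LIC)^{-1/b}}.
#' Round-trips with the forward conversion to better than 1e-9 relative.
#'
#' @param lic LIC value(s) in mg/g dry weight; must be strictly positive.
#' @inheritParams t2star_to_lic
#' @return T2* in ms.
#' @export
lic_to_t2star <- function(lic, calibration = garbowski_calibration()) {
  if (!is.numeric(lic) || any(!is.finite(lic)) || any(lic <= 0)) {
    stop("lic must be finite and > 0", call. = FALSE)
  }
  (lic / calibration$coefficient)^(1 / calibration$exponent)
}

#' Five-level iron-burden grade scale
#'
#' Boundaries (mg/g dry weight) split LIC into normal / slight / mild /
#' moderate / severe. Interval convention: normal is `lic < b1`; slight,
#' mild are lower-inclusive, upper-exclusive; moderate includes both 7.0
#' and 15.0; severe is strictly `lic > b4`. The extreme bounds are printed
#' as strict inequalities in the source grading table, which forces
#' moderate to carry 15.0; the interior shared endpoints go to the higher
#' grade.
#'
#' @param boundaries increasing numeric vector of 4 LIC cut points.
#' @return An object of class `grade_scale` with the ordered labels.
#' @export
grade_scale <- function(boundaries = c(1.8, 3.2, 7.0, 15.0)) {
  stopifnot(is.numeric(boundaries), length(boundaries) == 4L,
            all(is.finite(boundaries)), all(diff(boundaries) > 0),
            boundaries[1] > 0)
  structure(list(
    labels = c("normal", "slight", "mild", "moderate", "severe"),
    boundaries = boundaries
  ), class = "grade_scale")
}

#' Assign the iron-burden grade for a liver iron concentration
#'
#' @param lic LIC value(s) in mg/g dry weight, strictly positive.
#' @param scale a [grade_scale()].
#' @return factor with the five ordered grade levels.
#' @examples
#' lic_grade(c(0.6, 1.8, 15.0, 36.2))
#' @export
lic_grade <- function(lic, scale = grade_scale()) {
  if (!is.numeric(lic) || any(!is.finite(lic)) || any(lic <= 0)) {
    stop("lic must be finite and > 0", call. = FALSE)
  }
  b <- scale$boundaries
  idx <- ifelse(lic < b[1], 1L,
         ifelse(lic < b[2], 2L,
         ifelse(lic < b[3], 3L,
         ifelse(lic <= b[4], 4L, 5L))))
  factor(scale$labels[idx], levels = scale$labels, ordered = TRUE)
}

#' LIC interval covered by each grade
#'
#' Half-open interval bounds per grade, used by the cohort generator to
#' sample reference LIC values within a grade. `moderate` is closed at its
#' upper end; `severe` is open at 15.0 and unbounded above.
#'
#' @param scale a [grade_scale()].
#' @return data.frame with columns grade, lower, upper, and inclusion flags.
#' @keywords internal
grade_intervals <- function(scale = grade_scale()) {
  b <- scale$boundaries
  data.frame(
    grade = scale$labels,
    lower = c(0, b[1], b[2], b[3], b[4]),
    upper = c(b[1], b[2], b[3], b[4], Inf),
    lower_open = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    upper_open = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
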