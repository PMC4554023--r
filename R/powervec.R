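# Double-angle (Jackson) power-vector algebra for astigmatism.
#
# Conventions: cylinders are stored in positive-cylinder form with the axis
# being the FLAT meridian; all public angles are degrees; the double-angle
# Cartesian components are J0 (0/90 degree astigmatism) and J45 (oblique).

#' Normalize a meridian angle to [0, 180)
#'
#' Meridians are undirected, so angles are equivalent modulo 180 degrees.
#'
#' @param angle Numeric vector of angles in degrees; must be finite.
#' @return Numeric vector in `[0, 180)`, congruent to `angle` mod 180.
#' @examples
#' normalize_axis(c(190, -45, 180))  # 10, 135, 0
#' @export
normalize_axis <- function(angle) {
  if (!is.numeric(angle)) {
    stop("`angle` must be numeric", call. = FALSE)
  }
  if (anyNA(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite", call. = FALSE)
  }
  a <- angle %% 180
  # x %% 180 can return exactly 180 for tiny negative x in floating point
  a[a >= 180] <- 0
  a
}

#' Cylinder-form astigmatism (magnitude and flat-meridian axis)
#'
#' Constructs a vectorized record of astigmatism in positive-cylinder form.
#' The axis is the flat (least-power) meridian. Zero-magnitude entries store
#' axis 0 by convention, since their axis is undefined.
#'
#' @param magnitude Cylinder magnitude in diopters; must be `>= 0`.
#' @param axis Flat-meridian axis in degrees, in `[0, 180)`. Use
#'   [normalize_axis()] first if your angles fall outside that range.
#' @return A data frame of class `"cyl_astig"` with columns `magnitude`, `axis`.
#' @examples
#' cyl_astig(c(0.4, 1.0), c(0, 45))
#' @export
cyl_astig <- function(magnitude, axis = 0) {
  n <- max(length(magnitude), length(axis))
  magnitude <- rep_len(as.numeric(magnitude), n)
  axis <- rep_len(as.numeric(axis), n)
  if (anyNA(magnitude) || any(!is.finite(magnitude))) {
    stop("cylinder `magnitude` must be finite", call. = FALSE)
  }
  if (any(magnitude < 0)) {
    stop("cylinder `magnitude` must be >= 0 (positive-cylinder convention)",
         call. = FALSE)
  }
  if (anyNA(axis) || any(!is.finite(axis))) {
    stop("`axis` must be finite", call. = FALSE)
  }
  if (any(axis < 0 | axis >= 180)) {
    stop("`axis` must lie in [0, 180); use normalize_axis()", call. = FALSE)
  }
  axis[magnitude == 0] <- 0
  structure(data.frame(magnitude = magnitude, axis = axis),
            class = c("cyl_astig", "data.frame"))
}

#' Power-vector (J0, J45) astigmatism
#'
#' @param j0 J0 component in diopters (0/90-degree astigmatism).
#' @param j45 J45 component in diopters (45/135-degree astigmatism).
#' @return A data frame of class `"power_vector"` with columns `j0`, `j45`.
#' @export
power_vector <- function(j0, j45) {
  n <- max(length(j0), length(j45))
  j0 <- rep_len(as.numeric(j0), n)
  j45 <- rep_len(as.numeric(j45), n)
  if (anyNA(j0) || anyNA(j45) || any(!is.finite(j0)) || any(!is.finite(j45))) {
    stop("power-vector components must be finite", call. = FALSE)
  }
  structure(data.frame(j0 = j0, j45 = j45),
            class = c("power_vector", "data.frame"))
}

#' Convert cylinder form to a power vector
#'
#' Jackson decomposition: `J0 = (C/2) cos(2A)`, `J45 = (C/2) sin(2A)`, with
#' `C` the positive cylinder and `A` the flat meridian in degrees.
#'
#' @param x A [cyl_astig()] record.
#' @return A [power_vector()] with one row per input row.
#' @examples
#' cyl_to_pv(cyl_astig(0.40, 0))  # J0 = 0.20, J45 = 0
#' @export
cyl_to_pv <- function(x) {
  stopifnot(inherits(x, "cyl_astig"))
  half <- x$magnitude / 2
  # cospi/sinpi keep the cardinal axes exact (cos 90deg == 0, not 6e-17)
  power_vector(half * cospi(x$axis / 90), half * sinpi(x$axis / 90))
}

#' Convert a power vector back to cylinder form
#'
#' Inverse of [cyl_to_pv()]: `C = 2 sqrt(J0^2 + J45^2)` and the flat meridian
#' is `atan2(J45, J0) / 2`, normalized to `[0, 180)`. The zero vector maps to
#' `(C = 0, A = 0)` by convention.
#'
#' @param pv A [power_vector()].
#' @return A [cyl_astig()] record.
#' @export
pv_to_cyl <- function(pv) {
  stopifnot(inherits(pv, "power_vector"))
  mag <- 2 * sqrt(pv$j0^2 + pv$j45^2)
  ax <- normalize_axis(atan2(pv$j45, pv$j0) * 90 / pi)
  ax[mag == 0] <- 0
  cyl_astig(mag, ax)
}

#' Difference magnitude between two power vectors
#'
#' The Euclidean distance in double-angle space,
#' `sqrt((J0a - J0b)^2 + (J45a - J45b)^2)`. This is the quantity used both
#' for the inter-modality discrepancy between keratometry methods and for
#' ocular residual astigmatism; note it is half the cylinder that would
#' express the same astigmatic difference.
#'
#' @param a,b [power_vector()] records (recycled to a common length).
#' @return Numeric vector of non-negative difference magnitudes in diopters.
#' @examples
#' pv_difference_magnitude(cyl_to_pv(cyl_astig(1, 0)), cyl_to_pv(cyl_astig(1, 90)))
#' @export
pv_difference_magnitude <- function(a, b) {
  stopifnot(inherits(a, "power_vector"), inherits(b, "power_vector"))
  sqrt((a$j0 - b$j0)^2 + (a$j45 - b$j45)^2)
}

#' Steep meridian of an astigmatic cylinder
#'
#' The stored axis is the flat meridian; the steep (most-power) meridian is
#' orthogonal to it. Undefined for zero cylinders.
#'
#' @param x A [cyl_astig()] record with all magnitudes `> 0`.
#' @return Steep-meridian angle(s) in degrees, in `[0, 180)`.
#' @export
steep_axis <- function(x) {
  stopifnot(inherits(x, "cyl_astig"))
  if (any(x$magnitude <= 0)) {
    stop("steep axis is undefined for zero-magnitude cylinders", call. = FALSE)
  }
  normalize_axis(x$axis + 90)
}

#' Classify astigmatism as with-the-rule or against-the-rule
#'
#' With-the-rule (WTR) when the steep meridian lies between 45 and 135
#' degrees inclusive; against-the-rule (ATR) otherwise. Zero-cylinder eyes
#' have no axis and are refused; callers must exclude them.
#'
#' @param x A [cyl_astig()] record with all magnitudes `> 0`.
#' @return Character vector of `"WTR"` / `"ATR"` labels.
#' @examples
#' classify_wtr_atr(cyl_astig(c(1, 1), c(0, 90)))  # "WTR" "ATR"
#' @export
classify_wtr_atr <- function(x) {
  s <- steep_axis(x)
  ifelse(s >= 45 & s <= 135, "WTR", "ATR")
}
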