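# Manifest refraction handling: spherocylinder notation, vertex-distance
# transport between spectacle and corneal planes, surgically induced
# astigmatism (SIA) modeling and ocular residual astigmatism (ORA).

#' Spherocylindrical refraction
#'
#' A manifest refraction (sphere / cylinder x axis) with an explicit
#' cylinder-sign convention. The two principal meridian powers are `sphere`
#' (along `axis`) and `sphere + cylinder` (orthogonal); transposition between
#' notations preserves that pair.
#'
#' @param sphere Sphere in diopters.
#' @param cylinder Cylinder in diopters; `>= 0` under `"pos"` notation,
#'   `<= 0` under `"neg"`.
#' @param axis Cylinder axis in degrees, in `[0, 180)`.
#' @param notation `"pos"` or `"neg"` cylinder convention (recycled).
#' @return A data frame of class `"sphero_cylinder"` with columns `sphere`,
#'   `cylinder`, `axis`, `notation`.
#' @export
sphero_cylinder <- function(sphere, cylinder, axis, notation = "neg") {
  n <- max(length(sphere), length(cylinder), length(axis), length(notation))
  sphere <- rep_len(as.numeric(sphere), n)
  cylinder <- rep_len(as.numeric(cylinder), n)
  axis <- rep_len(as.numeric(axis), n)
  notation <- rep_len(as.character(notation), n)
  if (anyNA(sphere) || anyNA(cylinder) || anyNA(axis) ||
      any(!is.finite(sphere)) || any(!is.finite(cylinder)) ||
      any(!is.finite(axis))) {
    stop("sphere, cylinder and axis must be finite", call. = FALSE)
  }
  if (any(axis < 0 | axis >= 180)) {
    stop("`axis` must lie in [0, 180)", call. = FALSE)
  }
  if (!all(notation %in% c("pos", "neg"))) {
    stop('`notation` must be "pos" or "neg"', call. = FALSE)
  }
  bad <- (notation == "pos" & cylinder < 0) | (notation == "neg" & cylinder > 0)
  if (any(bad)) {
    stop("cylinder sign inconsistent with notation for ",
         sum(bad), " record(s)", call. = FALSE)
  }
  structure(data.frame(sphere = sphere, cylinder = cylinder, axis = axis,
                       notation = notation, stringsAsFactors = FALSE),
            class = c("sphero_cylinder", "data.frame"))
}

#' Transpose a spherocylinder between cylinder-sign notations
#'
#' `S / C x A` becomes `(S + C) / (-C) x (A + 90)`; the principal meridian
#' powers `{S, S + C}` are unchanged.
#'
#' @param sc A [sphero_cylinder()].
#' @return The equivalent refraction in the opposite notation.
#' @export
transpose_cyl <- function(sc) {
  stopifnot(inherits(sc, "sphero_cylinder"))
  sphero_cylinder(sc$sphere + sc$cylinder,
                  -sc$cylinder,
                  normalize_axis(sc$axis + 90),
                  ifelse(sc$notation == "pos", "neg", "pos"))
}

as_positive_cyl <- function(sc) {
  stopifnot(inherits(sc, "sphero_cylinder"))
  neg <- sc$notation == "neg" & sc$cylinder != 0
  if (!any(neg)) {
    out <- sc
    out$notation <- "pos"
    return(out)
  }
  flipped <- transpose_cyl(sc)
  out <- sc
  out[neg, ] <- flipped[neg, ]
  out$notation <- "pos"
  out
}

#' Vertex-distance correction of a single refractive power
#'
#' Transports a power measured at the spectacle plane to the corneal plane:
#' `Fc = F / (1 - d * F)` with the vertex distance `d` in meters (0.012 m
#' for the conventional 12 mm). The inverse transport is obtained with `-d`.
#'
#' @param f Power(s) in diopters at the source plane.
#' @param vertex_distance Vertex distance in meters; default `0.012`.
#' @return Corrected power(s) in diopters.
#' @examples
#' vertex_correct_power(-10)  # -8.9286
#' @export
vertex_correct_power <- function(f, vertex_distance = 0.012) {
  if (anyNA(f) || any(!is.finite(f))) {
    stop("`f` must be finite", call. = FALSE)
  }
  denom <- 1 - vertex_distance * f
  if (any(abs(denom) < 1e-9)) {
    stop("singular vertex conversion: 1 - d*F is zero", call. = FALSE)
  }
  f / denom
}

vertex_transport_sc <- function(sc, d) {
  stopifnot(inherits(sc, "sphero_cylinder"))
  m1 <- vertex_correct_power(sc$sphere, d)
  m2 <- vertex_correct_power(sc$sphere + sc$cylinder, d)
  sphero_cylinder(m1, m2 - m1, sc$axis, sc$notation)
}

#' Transport a manifest refraction to the corneal plane
#'
#' Each principal meridian power is vertex-corrected independently with
#' [vertex_correct_power()] and the spherocylinder reassembled in the input
#' notation with the same axis. With `vertex_distance = 0` this is the
#' identity.
#'
#' @param sc A [sphero_cylinder()] at the spectacle plane.
#' @param vertex_distance Vertex distance in meters; default `0.012`.
#' @return A [sphero_cylinder()] at the corneal plane.
#' @export
refraction_to_corneal_plane <- function(sc, vertex_distance = 0.012) {
  vertex_transport_sc(sc, vertex_distance)
}

#' Transport a corneal-plane refraction back to the spectacle plane
#'
#' Exact inverse of [refraction_to_corneal_plane()] (meridian-wise
#' `F = Fc / (1 + d * Fc)`).
#'
#' @inheritParams refraction_to_corneal_plane
#' @param sc A [sphero_cylinder()] at the corneal plane.
#' @return A [sphero_cylinder()] at the spectacle plane.
#' @export
refraction_to_spectacle_plane <- function(sc, vertex_distance = 0.012) {
  vertex_transport_sc(sc, -vertex_distance)
}

#' Astigmatic power vector of a refraction
#'
#' Transposes to the positive-cylinder convention (axis = flat meridian) and
#' applies the Jackson decomposition to the cylinder component.
#'
#' @param sc A [sphero_cylinder()].
#' @return A [power_vector()].
#' @export
refraction_astig_pv <- function(sc) {
  pos <- as_positive_cyl(sc)
  cyl_to_pv(cyl_astig(pos$cylinder, pos$axis))
}

#' Flattening vector of a surgically induced astigmatism
#'
#' A cataract incision of SIA magnitude `m` flattening the meridian at
#' `incision_axis` contributes the power vector of the cylinder `m @
#' incision_axis`; a 0.40 D temporal incision on the horizontal meridian
#' gives `(J0 = 0.20, J45 = 0)`.
#'
#' @param magnitude SIA magnitude in diopters, `>= 0`.
#' @param incision_axis Flattened meridian in degrees, in `[0, 180)`;
#'   default 0 (temporal incision, horizontal meridian).
#' @return A [power_vector()].
#' @export
sia_flattening_vector <- function(magnitude, incision_axis = 0) {
  if (any(magnitude < 0)) {
    stop("SIA `magnitude` must be >= 0", call. = FALSE)
  }
  cyl_to_pv(cyl_astig(magnitude, incision_axis))
}

#' Apply an assumed SIA to a refractive-astigmatism power vector
#'
#' Componentwise `ra + sign * sia`. The default `sign = +1` restores the
#' incision's flattening effect onto the postoperative refraction so it can
#' be compared with preoperative keratometry on the same basis; `sign = -1`
#' is exposed for sensitivity analysis.
#'
#' @param ra_pv Postoperative refractive astigmatism as a [power_vector()].
#' @param sia_pv SIA flattening vector from [sia_flattening_vector()].
#' @param sign `+1` or `-1`.
#' @return A [power_vector()].
#' @export
adjust_ra_for_sia <- function(ra_pv, sia_pv, sign = 1) {
  stopifnot(inherits(ra_pv, "power_vector"), inherits(sia_pv, "power_vector"))
  if (!sign %in% c(1, -1)) {
    stop("`sign` must be +1 or -1", call. = FALSE)
  }
  power_vector(ra_pv$j0 + sign * sia_pv$j0, ra_pv$j45 + sign * sia_pv$j45)
}

#' Ocular residual astigmatism between keratometry and refraction
#'
#' The power-vector difference magnitude between a preoperative corneal
#' astigmatism measurement and the (SIA-adjusted, corneal-plane)
#' postoperative refractive astigmatism.
#'
#' @param keratometry_pv Corneal astigmatism as a [power_vector()].
#' @param ra_adjusted_pv SIA-adjusted refractive astigmatism [power_vector()].
#' @param as_cylinder If `TRUE`, double the result to express it as an
#'   equivalent cylinder; default `FALSE` (plain J-space magnitude).
#' @return Non-negative ORA value(s) in diopters.
#' @export
compute_ora <- function(keratometry_pv, ra_adjusted_pv, as_cylinder = FALSE) {
  d <- pv_difference_magnitude(keratometry_pv, ra_adjusted_pv)
  if (as_cylinder) 2 * d else d
}

ora_variant_names <- function(k) {
  if (k < 1) stop("need at least one SIA magnitude", call. = FALSE)
  c("ra", if (k > 1) paste0("ra", seq_len(k - 1)))
}

#' Per-eye ORA under each keratometry source and assumed SIA
#'
#' For every eye: the manifest refraction is transported to the corneal
#' plane, each assumed SIA magnitude (default 0, 0.20, 0.40 D, the RA / RA1
#' / RA2 variants) is applied, and the ORA against each keratometry source
#' (AK, TCRP3, TCRP4) is computed — nine values per eye under the defaults.
#'
#' @param cohort Cohort data frame in the [cohort_columns()] schema.
#' @param sia_magnitudes Assumed SIA magnitudes in diopters; names the
#'   variants `ra`, `ra1`, `ra2`, ... by position.
#' @param vertex_distance Vertex distance in meters; default `0.012`.
#' @param incision_axis Flattened meridian in degrees; default 0.
#' @param sia_sign `+1` (default) or `-1`, see [adjust_ra_for_sia()].
#' @param as_cylinder Report ORA doubled to cylinder scale; default `FALSE`.
#' @return Data frame with `eye_id` and one `ora_<source>_<variant>` column
#'   per combination, e.g. `ora_tcrp3_ra2`.
#' @export
compute_ora_set <- function(cohort, sia_magnitudes = c(0, 0.20, 0.40),
                            vertex_distance = 0.012, incision_axis = 0,
                            sia_sign = 1, as_cylinder = FALSE) {
  needed <- c("ak_cyl_d", "ak_axis_deg", "tcrp3_cyl_d", "tcrp3_axis_deg",
              "tcrp4_cyl_d", "tcrp4_axis_deg", "ra_sphere_d", "ra_cyl_d",
              "ra_axis_deg", "ra_notation")
  check_fields(cohort, needed)

  sc <- sphero_cylinder(cohort$ra_sphere_d, cohort$ra_cyl_d,
                        cohort$ra_axis_deg, cohort$ra_notation)
  ra_pv <- refraction_astig_pv(refraction_to_corneal_plane(sc, vertex_distance))

  src_pv <- list(
    ak = cyl_to_pv(cyl_astig(cohort$ak_cyl_d, cohort$ak_axis_deg)),
    tcrp3 = cyl_to_pv(cyl_astig(cohort$tcrp3_cyl_d, cohort$tcrp3_axis_deg)),
    tcrp4 = cyl_to_pv(cyl_astig(cohort$tcrp4_cyl_d, cohort$tcrp4_axis_deg))
  )

  variants <- ora_variant_names(length(sia_magnitudes))
  out <- data.frame(eye_id = cohort$eye_id, stringsAsFactors = FALSE)
  for (i in seq_along(sia_magnitudes)) {
    sia_pv <- sia_flattening_vector(sia_magnitudes[i], incision_axis)
    ra_i <- adjust_ra_for_sia(ra_pv, sia_pv, sia_sign)
    for (src in names(src_pv)) {
      out[[paste0("ora_", src, "_", variants[i])]] <-
        compute_ora(src_pv[[src]], ra_i, as_cylinder)
    }
  }
  out
}

# Shared missing-field guard: errors name the offending field and eye.
check_fields <- function(cohort, needed) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("missing field(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    bad <- is.na(cohort[[col]])
    if (any(bad)) {
      ids <- if ("eye_id" %in% names(cohort)) {
        paste(utils::head(cohort$eye_id[bad], 3), collapse = ", ")
      } else {
        paste(utils::head(which(bad), 3), collapse = ", ")
      }
      stop("missing field `", col, "` for eye(s) ", ids, call. = FALSE)
    }
  }
  invisible(TRUE)
}
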