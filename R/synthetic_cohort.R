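# Synthetic per-eye cataract cohort generator.
#
# Emulates the joint structure the analysis assumes: age drives the corneal
# irregularity index (log-linearly) and the odds of against-the-rule
# astigmatism (logistically); the discrepancy between ray-traced (TCRP) and
# automated (AK) keratometry grows log-linearly with age, IR and AK
# magnitude; the postoperative refraction is generated from a designated
# "true cornea" minus the incision's flattening vector plus IR-scaled noise,
# then transported to the spectacle plane.

#' Simulation parameters for a synthetic cohort
#'
#' Defaults describe an elderly cataract-surgery population: age
#' 68.25 +/- 11.33 years, corneal irregularity index (IR) averaging about
#' 0.042 +/- 0.019 mm and increasing with age, against-the-rule eyes about
#' 8 years older than with-the-rule eyes, corneal astigmatism around 1 D,
#' a mean TCRP3-AK discrepancy near 0.43 D, and a true surgically induced
#' astigmatism of 0.40 D flattening the horizontal meridian (temporal
#' incision).
#'
#' @param n Number of eyes, `>= 0`.
#' @param seed Integer seed fixing the whole cohort.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated to
#'   `age_range` by resampling.
#' @param ir_log_intercept,ir_log_age_slope,ir_log_noise_sd Log-linear IR
#'   model: `ln(IR) = intercept + slope * age + N(0, sd^2)`, IR in mm.
#' @param ir_min Lower physical bound on IR (mm), enforced by resampling.
#' @param atr_logistic Named vector `c(intercept, slope)`:
#'   `P(ATR | age) = plogis(intercept + slope * age)`.
#' @param ak_meanlog,ak_sdlog,ak_range Log-normal AK cylinder magnitude (D),
#'   truncated to `ak_range` by resampling.
#' @param axis_jitter_sd Angular SD (degrees) of the flat-meridian jitter
#'   around 0 (WTR) or 90 (ATR); draws that would flip the intended class
#'   are resampled.
#' @param delta_model Named vector `c(intercept, age, ir, ak, noise_sd)` for
#'   the log-scale TCRP3-AK discrepancy magnitude:
#'   `ln(delta) = intercept + age * Age + ir * IR + ak * AK + N(0, noise_sd^2)`.
#' @param tcrp4_damping TCRP4 discrepancy as a fraction of the TCRP3 one.
#' @param ora_noise_sd Residual astigmatic noise SD (D per J component) of
#'   the postoperative refraction, scaled by `(1 + ir_scale * IR)`.
#' @param ir_scale Multiplier linking IR to the residual noise SD.
#' @param sia_true_magnitude,sia_true_axis True SIA (D) and flattened
#'   meridian (degrees) used to generate the postoperative refraction.
#' @param se_postop_mean,se_postop_sd Corneal-plane postoperative spherical
#'   equivalent distribution (D).
#' @param ant_radius_mean,ant_radius_sd Anterior corneal radius (mm).
#' @param ap_ratio_intercept,ap_ratio_ir_slope,ap_ratio_noise_sd Anterior /
#'   posterior radius ratio model: `ratio = intercept + slope * IR +
#'   N(0, sd^2)` (slope negative: irregular corneas have a lower ratio).
#' @param ia_log_intercept,ia_log_ir_slope,ia_log_noise_sd Irregular
#'   astigmatism (um): `ln(IA) = intercept + slope * ln(IR) + N(0, sd^2)`.
#' @param sa_mean_wtr,sa_shift_atr,sa_sd Corneal spherical aberration (um),
#'   truncated at 0; ATR eyes shifted upward by `sa_shift_atr`.
#' @param truth_source `"tcrp3"` (default) or `"ak"`: which keratometry is
#'   the generative truth for the postoperative refraction.
#' @param vertex_distance Vertex distance (m) used to transport the
#'   generated refraction to the spectacle plane.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n = 207, seed = 1,
                       age_mean = 68.25, age_sd = 11.33,
                       age_range = c(40, 95),
                       ir_log_intercept = -4.41, ir_log_age_slope = 0.0168,
                       ir_log_noise_sd = 0.387, ir_min = 0.005,
                       atr_logistic = c(intercept = -4.2315, slope = 0.062),
                       ak_meanlog = log(0.9), ak_sdlog = 0.5,
                       ak_range = c(0.1, 6),
                       axis_jitter_sd = 15,
                       delta_model = c(intercept = -2.14, age = 0.01,
                                       ir = 4.0, ak = 0.25, noise_sd = 0.6),
                       tcrp4_damping = 0.9,
                       ora_noise_sd = 0.20, ir_scale = 5,
                       sia_true_magnitude = 0.40, sia_true_axis = 0,
                       se_postop_mean = -0.25, se_postop_sd = 0.40,
                       ant_radius_mean = 7.70, ant_radius_sd = 0.25,
                       ap_ratio_intercept = 1.25, ap_ratio_ir_slope = -1.2,
                       ap_ratio_noise_sd = 0.02,
                       ia_log_intercept = 2.6, ia_log_ir_slope = 0.8,
                       ia_log_noise_sd = 0.5,
                       sa_mean_wtr = 0.326, sa_shift_atr = 0.081,
                       sa_sd = 0.20,
                       truth_source = c("tcrp3", "ak"),
                       vertex_distance = 0.012) {
  truth_source <- match.arg(truth_source)
  p <- list(n = n, seed = seed, age_mean = age_mean, age_sd = age_sd,
            age_range = age_range, ir_log_intercept = ir_log_intercept,
            ir_log_age_slope = ir_log_age_slope,
            ir_log_noise_sd = ir_log_noise_sd, ir_min = ir_min,
            atr_logistic = atr_logistic, ak_meanlog = ak_meanlog,
            ak_sdlog = ak_sdlog, ak_range = ak_range,
            axis_jitter_sd = axis_jitter_sd, delta_model = delta_model,
            tcrp4_damping = tcrp4_damping, ora_noise_sd = ora_noise_sd,
            ir_scale = ir_scale, sia_true_magnitude = sia_true_magnitude,
            sia_true_axis = sia_true_axis, se_postop_mean = se_postop_mean,
            se_postop_sd = se_postop_sd, ant_radius_mean = ant_radius_mean,
            ant_radius_sd = ant_radius_sd,
            ap_ratio_intercept = ap_ratio_intercept,
            ap_ratio_ir_slope = ap_ratio_ir_slope,
            ap_ratio_noise_sd = ap_ratio_noise_sd,
            ia_log_intercept = ia_log_intercept,
            ia_log_ir_slope = ia_log_ir_slope,
            ia_log_noise_sd = ia_log_noise_sd,
            sa_mean_wtr = sa_mean_wtr, sa_shift_atr = sa_shift_atr,
            sa_sd = sa_sd, truth_source = truth_source,
            vertex_distance = vertex_distance)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  check_scalar <- function(name, ok) {
    v <- p[[name]]
    if (anyNA(v) || any(!is.finite(v)) || !ok(v)) {
      stop("invalid simulation parameter `", name, "`", call. = FALSE)
    }
  }
  check_scalar("n", function(v) length(v) == 1 && v >= 0 && v == round(v))
  check_scalar("seed", function(v) length(v) == 1 && v == round(v))
  for (nm in c("age_sd", "ir_log_noise_sd", "ak_sdlog", "axis_jitter_sd",
               "ora_noise_sd", "se_postop_sd", "ant_radius_sd",
               "ap_ratio_noise_sd", "ia_log_noise_sd", "sa_sd",
               "sia_true_magnitude")) {
    check_scalar(nm, function(v) length(v) == 1 && v >= 0)
  }
  check_scalar("sia_true_axis",
               function(v) length(v) == 1 && v >= 0 && v < 180)
  check_scalar("delta_model",
               function(v) length(v) == 5 && v[["noise_sd"]] >= 0)
  check_scalar("atr_logistic", function(v) length(v) == 2)
  check_scalar("age_range",
               function(v) length(v) == 2 && v[1] < v[2])
  check_scalar("ak_range",
               function(v) length(v) == 2 && 0 < v[1] && v[1] < v[2])
  invisible(TRUE)
}

#' Generative truth of a parameter set
#'
#' Returns the exact generative values (regression coefficients, logistic
#' axis model, SIA, truth source) for parameter-recovery assertions.
#'
#' @param params A [sim_params()] object.
#' @return A named list of the generative parameters.
#' @export
known_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  list(delta_model = params$delta_model,
       ir_model = c(intercept = params$ir_log_intercept,
                    age = params$ir_log_age_slope,
                    noise_sd = params$ir_log_noise_sd),
       atr_logistic = params$atr_logistic,
       tcrp4_damping = params$tcrp4_damping,
       sia_true = c(magnitude = params$sia_true_magnitude,
                    axis = params$sia_true_axis),
       truth_source = params$truth_source,
       vertex_distance = params$vertex_distance)
}

# Truncation by resampling; `draw` takes the indices still to fill.
resample_until <- function(n, draw, keep, max_iter = 1000) {
  x <- draw(seq_len(n))
  for (i in seq_len(max_iter)) {
    bad <- which(!keep(x))
    if (!length(bad)) return(x)
    x[bad] <- draw(bad)
  }
  stop("truncation resampling failed to converge", call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `params$seed`. Generation order: age, IR, axis class
#' and flat meridian, AK magnitude and power vector, a TCRP-AK discrepancy
#' vector (log-linear magnitude, uniform double-angle direction) giving
#' TCRP3 and a damped TCRP4, then the postoperative corneal-plane refractive
#' astigmatism as the designated true cornea minus the true SIA flattening
#' vector plus IR-scaled bivariate noise, transported to the spectacle plane
#' and stored in negative-cylinder notation; radii, irregular astigmatism
#' and spherical aberration fill the remaining columns.
#'
#' @param params A [sim_params()] object.
#' @return Cohort data frame in the [cohort_columns()] schema.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- as.integer(p$n)
  set.seed(as.integer(p$seed))

  if (n == 0) {
    cols <- lapply(cohort_columns(), function(col) {
      if (col %in% c("eye_id", "ra_notation")) character(0) else numeric(0)
    })
    names(cols) <- cohort_columns()
    return(do.call(data.frame,
                   c(cols, list(stringsAsFactors = FALSE))))
  }

  age <- resample_until(n,
    function(i) stats::rnorm(length(i), p$age_mean, p$age_sd),
    function(x) x >= p$age_range[1] & x <= p$age_range[2])

  ir_mu <- p$ir_log_intercept + p$ir_log_age_slope * age
  ir <- resample_until(n,
    function(i) exp(ir_mu[i] + stats::rnorm(length(i), 0, p$ir_log_noise_sd)),
    function(x) x >= p$ir_min)

  p_atr <- stats::plogis(p$atr_logistic[["intercept"]] +
                           p$atr_logistic[["slope"]] * age)
  is_atr <- stats::runif(n) < p_atr
  flat_center <- ifelse(is_atr, 90, 0)
  want <- ifelse(is_atr, "ATR", "WTR")
  ak_axis <- resample_until(n,
    function(i) normalize_axis(flat_center[i] +
                                 stats::rnorm(length(i), 0, p$axis_jitter_sd)),
    function(x) {
      s <- normalize_axis(x + 90)
      ifelse(s >= 45 & s <= 135, "WTR", "ATR") == want
    })

  ak_mag <- resample_until(n,
    function(i) stats::rlnorm(length(i), p$ak_meanlog, p$ak_sdlog),
    function(x) x >= p$ak_range[1] & x <= p$ak_range[2])
  ak_pv <- cyl_to_pv(cyl_astig(ak_mag, ak_axis))

  dm <- p$delta_model
  delta <- exp(dm[["intercept"]] + dm[["age"]] * age + dm[["ir"]] * ir +
                 dm[["ak"]] * ak_mag +
                 stats::rnorm(n, 0, dm[["noise_sd"]]))
  phi <- stats::runif(n, 0, 2 * pi)
  disc_j0 <- delta * cos(phi)
  disc_j45 <- delta * sin(phi)

  tcrp3_pv <- power_vector(ak_pv$j0 + disc_j0, ak_pv$j45 + disc_j45)
  tcrp4_pv <- power_vector(ak_pv$j0 + p$tcrp4_damping * disc_j0,
                           ak_pv$j45 + p$tcrp4_damping * disc_j45)
  tcrp3 <- pv_to_cyl(tcrp3_pv)
  tcrp4 <- pv_to_cyl(tcrp4_pv)

  truth_pv <- if (p$truth_source == "tcrp3") tcrp3_pv else ak_pv
  sia_pv <- sia_flattening_vector(p$sia_true_magnitude, p$sia_true_axis)
  noise_sd <- p$ora_noise_sd * (1 + p$ir_scale * ir)
  ra_pv <- power_vector(
    truth_pv$j0 - sia_pv$j0 + stats::rnorm(n, 0, noise_sd),
    truth_pv$j45 - sia_pv$j45 + stats::rnorm(n, 0, noise_sd))

  se_corneal <- stats::rnorm(n, p$se_postop_mean, p$se_postop_sd)
  ra_cyl <- pv_to_cyl(ra_pv)
  ra_corneal <- sphero_cylinder(se_corneal - ra_cyl$magnitude / 2,
                                ra_cyl$magnitude, ra_cyl$axis, "pos")
  ra_spec <- refraction_to_spectacle_plane(ra_corneal, p$vertex_distance)
  ra_spec_neg <- transpose_cyl(ra_spec)

  ant <- resample_until(n,
    function(i) stats::rnorm(length(i), p$ant_radius_mean, p$ant_radius_sd),
    function(x) x > 6 & x < 9.5)
  ap_ratio <- resample_until(n,
    function(i) p$ap_ratio_intercept + p$ap_ratio_ir_slope * ir[i] +
      stats::rnorm(length(i), 0, p$ap_ratio_noise_sd),
    function(x) x > 1.0)
  post <- ant / ap_ratio

  ia <- exp(p$ia_log_intercept + p$ia_log_ir_slope * log(ir) +
              stats::rnorm(n, 0, p$ia_log_noise_sd))

  sa_mean <- p$sa_mean_wtr + ifelse(is_atr, p$sa_shift_atr, 0)
  sa <- resample_until(n,
    function(i) stats::rnorm(length(i), sa_mean[i], p$sa_sd),
    function(x) x >= 0)

  data.frame(
    eye_id = sprintf("eye%04d", seq_len(n)),
    age_years = age,
    ak_cyl_d = ak_mag, ak_axis_deg = ak_axis,
    tcrp3_cyl_d = tcrp3$magnitude, tcrp3_axis_deg = tcrp3$axis,
    tcrp4_cyl_d = tcrp4$magnitude, tcrp4_axis_deg = tcrp4$axis,
    ir_mm = ir, irregular_astig_um = ia,
    ant_radius_mm = ant, post_radius_mm = post,
    ra_sphere_d = ra_spec_neg$sphere, ra_cyl_d = ra_spec_neg$cylinder,
    ra_axis_deg = ra_spec_neg$axis, ra_notation = "neg",
    sa_um = sa,
    stringsAsFactors = FALSE)
}
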