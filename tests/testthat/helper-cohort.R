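# Shared fixtures built in code.

# Minimal hand-built cohort; keratometry and refraction are set explicitly
# so derived quantities can be verified by hand.
toy_cohort <- function(n = 3,
                       ak_cyl = rep(1, n), ak_axis = rep(0, n),
                       tcrp3_cyl = ak_cyl, tcrp3_axis = ak_axis,
                       tcrp4_cyl = ak_cyl, tcrp4_axis = ak_axis,
                       ir = seq(0.02, 0.08, length.out = n),
                       ra_sphere = rep(0, n), ra_cyl = rep(0, n),
                       ra_axis = rep(0, n), ra_notation = rep("neg", n)) {
  data.frame(
    eye_id = sprintf("toy%02d", seq_len(n)),
    age_years = seq(50, 80, length.out = n),
    ak_cyl_d = ak_cyl, ak_axis_deg = ak_axis,
    tcrp3_cyl_d = tcrp3_cyl, tcrp3_axis_deg = tcrp3_axis,
    tcrp4_cyl_d = tcrp4_cyl, tcrp4_axis_deg = tcrp4_axis,
    ir_mm = ir, irregular_astig_um = rep(1, n),
    ant_radius_mm = rep(7.7, n), post_radius_mm = rep(6.4, n),
    ra_sphere_d = ra_sphere, ra_cyl_d = ra_cyl,
    ra_axis_deg = ra_axis, ra_notation = ra_notation,
    sa_um = rep(0.35, n),
    stringsAsFactors = FALSE)
}

# Random cylinder draws used by the property tests.
random_cyls <- function(n, seed, zero_frac = 0) {
  set.seed(seed)
  mag <- stats::runif(n, 0, 6)
  if (zero_frac > 0) mag[seq_len(ceiling(n * zero_frac))] <- 0
  cyl_astig(mag, stats::runif(n, 0, 180))
}

# Angular distance between meridians, modulo 180.
axis_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Independent brute-force oracle: half-power meridional profile on a
# 1-degree grid; RMS of 2*(dF)^2 over the grid.
profile_diff_oracle <- function(cyl_a, cyl_b) {
  theta <- 0:179
  prof <- function(cc, i) {
    (cc$magnitude[i] / 2) * cos(2 * (theta - cc$axis[i]) * pi / 180)
  }
  vapply(seq_len(nrow(cyl_a)), function(i) {
    df <- prof(cyl_a, i) - prof(cyl_b, i)
    sqrt(mean(2 * df^2))
  }, numeric(1))
}
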