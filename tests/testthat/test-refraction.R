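test_that("vertex correction reproduces hand-evaluated powers", {
  expect_equal(vertex_correct_power(0), 0)
  expect_equal(vertex_correct_power(-10), -10 / 1.12, tolerance = 1e-12)
  expect_equal(vertex_correct_power(-10), -8.9286, tolerance = 1e-4)
  expect_equal(vertex_correct_power(10), 10 / 0.88, tolerance = 1e-12)
  expect_equal(vertex_correct_power(10), 11.3636, tolerance = 1e-4)
  expect_error(vertex_correct_power(1 / 0.012), "singular")
})

test_that("vertex transport round-trips for |F| <= 25", {
  f <- seq(-25, 25, by = 0.25)
  fc <- vertex_correct_power(f, 0.012)
  back <- vertex_correct_power(fc, -0.012)
  expect_lt(max(abs(back - f)), 1e-9)
})

test_that("spherocylinder transposition preserves meridian powers", {
  sc <- sphero_cylinder(-10, -2, 30, "neg")
  tp <- transpose_cyl(sc)
  expect_equal(tp$sphere, -12)
  expect_equal(tp$cylinder, 2)
  expect_equal(tp$axis, 120)
  expect_equal(tp$notation, "pos")
  expect_equal(sort(c(tp$sphere, tp$sphere + tp$cylinder)),
               sort(c(sc$sphere, sc$sphere + sc$cylinder)))
  expect_error(sphero_cylinder(0, -1, 0, "pos"), "inconsistent")
})

test_that("refraction transport to the corneal plane is meridian-wise", {
  plano <- sphero_cylinder(0, 0, 0, "neg")
  expect_equal(refraction_to_corneal_plane(plano)$sphere, 0)
  one <- refraction_to_corneal_plane(sphero_cylinder(-10, 0, 0, "neg"))
  expect_equal(one$sphere, -8.9286, tolerance = 1e-4)
  # meridians -10 -> -8.9286 and -8 -> -7.2993; cylinder is the difference
  sc <- refraction_to_corneal_plane(sphero_cylinder(-10, 2, 0, "pos"))
  expect_equal(sc$sphere, -8.9286, tolerance = 1e-4)
  expect_equal(sc$cylinder, 1.6293, tolerance = 1e-4)
  expect_equal(sc$axis, 0)
})

test_that("corneal transport commutes with transposition and has inverses", {
  set.seed(5)
  sc <- sphero_cylinder(stats::runif(50, -12, 6), -stats::runif(50, 0, 4),
                        stats::runif(50, 0, 179.9), "neg")
  a <- transpose_cyl(refraction_to_corneal_plane(sc))
  b <- refraction_to_corneal_plane(transpose_cyl(sc))
  expect_equal(a$sphere, b$sphere, tolerance = 1e-10)
  expect_equal(a$cylinder, b$cylinder, tolerance = 1e-10)
  expect_equal(a$axis, b$axis)
  # vertex distance 0 is the identity
  id <- refraction_to_corneal_plane(sc, vertex_distance = 0)
  expect_equal(id$sphere, sc$sphere)
  expect_equal(id$cylinder, sc$cylinder)
  # spectacle transport inverts corneal transport
  back <- refraction_to_spectacle_plane(refraction_to_corneal_plane(sc))
  expect_lt(max(abs(back$sphere - sc$sphere)), 1e-9)
  expect_lt(max(abs(back$cylinder - sc$cylinder)), 1e-9)
})

test_that("SIA flattening vector matches the published worked example", {
  # 0.40 D temporal incision, horizontal meridian
  sia <- sia_flattening_vector(0.40, 0)
  expect_equal(sia$j0, 0.20)
  expect_equal(sia$j45, 0)
  zero <- sia_flattening_vector(0, 77)
  expect_equal(c(zero$j0, zero$j45), c(0, 0))
  # linear in magnitude at fixed axis
  for (ax in c(0, 30, 120)) {
    half <- sia_flattening_vector(0.20, ax)
    full <- sia_flattening_vector(0.40, ax)
    expect_equal(2 * half$j0, full$j0)
    expect_equal(2 * half$j45, full$j45)
  }
  expect_error(sia_flattening_vector(-0.1, 0), ">= 0")
})

test_that("SIA adjustment is a signed componentwise sum", {
  ra <- power_vector(0.10, 0.05)
  sia <- power_vector(0.20, 0)
  plus <- adjust_ra_for_sia(ra, sia, 1)
  expect_equal(c(plus$j0, plus$j45), c(0.30, 0.05))
  minus <- adjust_ra_for_sia(power_vector(0.30, 0), sia, -1)
  expect_equal(c(minus$j0, minus$j45), c(0.10, 0))
  same <- adjust_ra_for_sia(ra, power_vector(0, 0))
  expect_equal(c(same$j0, same$j45), c(ra$j0, ra$j45))
  expect_error(adjust_ra_for_sia(ra, sia, 2), "sign")
})

test_that("compute_ora is the power-vector difference magnitude", {
  k <- power_vector(0.5, 0)
  expect_equal(compute_ora(k, k), 0)
  expect_equal(compute_ora(k, power_vector(0, 0)), 0.5)
  expect_equal(compute_ora(k, power_vector(0.2, 0.4)), 0.5)
  expect_equal(compute_ora(k, power_vector(0, 0), as_cylinder = TRUE), 1.0)
})

test_that("compute_ora_set yields all nine combinations per eye", {
  # refraction chosen so its corneal-plane astigmatism equals AK exactly:
  # corneal positive cyl 1 @ 0 transported to the spectacle plane
  corneal <- sphero_cylinder(0, 1, 0, "pos")
  spec <- transpose_cyl(refraction_to_spectacle_plane(corneal))
  ch <- toy_cohort(2, ak_cyl = c(1, 1), ak_axis = c(0, 0),
                   ra_sphere = rep(spec$sphere, 2),
                   ra_cyl = rep(spec$cylinder, 2),
                   ra_axis = rep(spec$axis, 2))
  o <- compute_ora_set(ch)
  expect_setequal(setdiff(names(o), "eye_id"),
                  as.vector(outer(c("ora_ak", "ora_tcrp3", "ora_tcrp4"),
                                  c("ra", "ra1", "ra2"), paste, sep = "_")))
  # with SIA 0 the matched eye has zero ORA for every keratometry source
  expect_lt(max(o$ora_ak_ra), 1e-9)
  expect_lt(max(o$ora_tcrp3_ra), 1e-9)
  # with an assumed SIA the ORA equals that SIA's flattening magnitude
  expect_equal(o$ora_ak_ra1, rep(0.10, 2), tolerance = 1e-9)
  expect_equal(o$ora_ak_ra2, rep(0.20, 2), tolerance = 1e-9)
})

test_that("compute_ora_set names the missing field in its error", {
  ch <- toy_cohort(2)
  ch$tcrp4_cyl_d[2] <- NA
  expect_error(compute_ora_set(ch), "tcrp4_cyl_d")
  expect_error(compute_ora_set(ch[, setdiff(names(ch), "tcrp3_axis_deg")]),
               "tcrp3_axis_deg")
})

test_that("ORA with zero SIA equals the plain corneal/refraction distance", {
  p <- sim_params(n = 40, seed = 9)
  ch <- generate_cohort(p)
  o <- compute_ora_set(ch, sia_magnitudes = 0)
  sc <- sphero_cylinder(ch$ra_sphere_d, ch$ra_cyl_d, ch$ra_axis_deg,
                        ch$ra_notation)
  ra_pv <- refraction_astig_pv(refraction_to_corneal_plane(sc))
  ak_pv <- cyl_to_pv(cyl_astig(ch$ak_cyl_d, ch$ak_axis_deg))
  expect_equal(o$ora_ak_ra, pv_difference_magnitude(ak_pv, ra_pv))
})
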