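test_that("the feature schema has exactly 571 unique, stable names", {
  fn <- feature_names()
  expect_length(fn, 571)
  expect_false(anyDuplicated(fn) > 0)
  expect_identical(fn[1], "aneurysm.curvature.max")
  expect_true("ratio.aneurysm-first_proximal.curvature.mean" %in% fn)
  expect_true("global.solidity_3d" %in% fn)
  expect_equal(sum(startsWith(fn, "ratio.")), 200)
  expect_equal(sum(startsWith(fn, "global.")), 21)
})

test_that("aneurysm detection matches the closed-form threshold crossing", {
  sq <- analytic_sequences(gauss_bulge_r)
  lay <- detect_aneurysm(sq, threshold_factor = 1.5)
  L_true <- gauss_bulge_L()            # ~ 10.367 mm
  expect_equal(lay$L, L_true, tolerance = 2 * 0.25 / L_true)
  expect_equal(lay$s_proximal, 20 - L_true / 2, tolerance = 0.05)
  # all five full segments have length L; halves have L/2
  seg <- lay$segments
  for (nm in c("aneurysm", "first_proximal", "second_proximal",
               "first_distal", "second_distal"))
    expect_equal(diff(seg[[nm]]), lay$L, tolerance = 1e-9)
  expect_equal(diff(seg$aneurysm_proximal_half), lay$L / 2)

  # constant-radius tube: no aneurysm
  expect_error(detect_aneurysm(analytic_sequences(function(s) rep(2, length(s)))),
               "no aneurysm")

  # bulge near the proximal end: truncated layout with a warning
  sq2 <- analytic_sequences(function(s) gauss_bulge_r(s, center = 10))
  expect_warning(lay2 <- detect_aneurysm(sq2), NA)
  expect_true(lay2$truncated[["second_proximal"]])
})

test_that("segment statistics reproduce hand-computed values", {
  s <- seq(0, 10, by = 0.1)
  cols <- c("curvature", "torsion", "d_max", "d_min", "d_eq", "area",
            "area_rate", "eccentricity", "solidity", "extent")
  M <- matrix(0, length(s), 10, dimnames = list(NULL, cols))
  M[, "solidity"] <- 1          # integral over 10 mm = 10 mm
  M[, "area"] <- 7              # constant: max = mean = 7, sd = 0, var = 0
  M[, "d_max"] <- s             # linear: integral 50, variation 10, max 10
  sq <- structure(list(s = s, flagged = rep(FALSE, length(s)), seq = M,
                       centroid_offset = rep(0, length(s)),
                       perimeter = rep(1, length(s)),
                       poly3d = vector("list", length(s))),
                  class = "geometry_sequences")
  lay <- list(segments = list(
    aneurysm = c(0, 10), aneurysm_proximal_half = c(0, 5),
    aneurysm_distal_half = c(5, 10), first_proximal = c(-10, 0),
    second_proximal = c(-20, -10), first_distal = c(10, 20),
    second_distal = c(20, 30)))
  st <- segment_statistics(sq, lay)
  expect_length(st, 350)
  expect_equal(unname(st["aneurysm.solidity.integral"]), 10, tolerance = 0.01)
  expect_equal(unname(st["aneurysm.area.max"]), 7)
  expect_equal(unname(st["aneurysm.area.mean"]), 7)
  expect_equal(unname(st["aneurysm.area.sd"]), 0)
  expect_equal(unname(st["aneurysm.area.variation"]), 0)
  expect_equal(unname(st["aneurysm.d_max.integral"]), 50, tolerance = 0.01)
  expect_equal(unname(st["aneurysm.d_max.variation"]), 10, tolerance = 0.01)
  expect_equal(unname(st["aneurysm.d_max.max"]), 10, tolerance = 0.01)
  # out-of-support segments are missing
  expect_true(all(is.na(st[grep("^second_distal", names(st))])))

  rt <- ratio_features(st)
  expect_length(rt, 200)
  # constant area: proximal-half/distal-half mean-area ratio is 1
  expect_equal(unname(
    rt["ratio.aneurysm_proximal_half-aneurysm_distal_half.area.mean"]), 1)
  # sd of a constant sequence is 0: the ratio with that denominator is NA
  expect_true(is.na(
    rt["ratio.aneurysm_proximal_half-aneurysm_distal_half.area.sd"]))
})

test_that("feature assembly enforces the 571 contract", {
  st <- stats::setNames(numeric(350), feature_names()[1:350])
  rt <- stats::setNames(numeric(200), feature_names()[351:550])
  gl <- stats::setNames(numeric(21), feature_names()[551:571])
  expect_length(assemble_features(st, rt, gl), 571)
  expect_error(assemble_features(st[-1], rt, gl), "assembly error")
  names(gl)[1] <- "global.wrong_name"
  expect_error(assemble_features(st, rt, gl), "assembly error")
})

test_that("3D hull volumes match closed forms", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  set.seed(2)
  inner <- matrix(runif(300, 1, 9), ncol = 3)
  expect_equal(hull3d_volume(rbind(cube, inner)), 1000, tolerance = 1e-9)

  th <- runif(400, 0, 2 * pi); z <- runif(400, -1, 1)
  sph <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z) * 5
  v <- hull3d_volume(sph)
  expect_lt(v, 4 / 3 * pi * 125)           # inscribed polytope
  expect_gt(v, 0.95 * 4 / 3 * pi * 125)
  expect_equal(hull3d_volume(cbind(runif(10), runif(10), 0)), 0)  # coplanar
})

test_that("the full pipeline emits 571 features with sane global values", {
  fv <- phantom_features_025()
  expect_length(fv, 571)
  expect_identical(names(fv), feature_names())
  lay <- attr(fv, "layout")
  # straight centerline: neck tangents parallel, chord ~ L
  expect_lt(fv[["global.neck_tangent_angle"]], 1)
  expect_equal(fv[["global.neck_tangent_distance"]], lay$L,
               tolerance = 2 * 0.25 / lay$L)
  # axisymmetric bulge: near-zero asymmetry, solid (convex) sections
  expect_lt(fv[["global.asymmetry_factor"]], 0.05)
  # the Gaussian bulge profile is concave near the necks, so the solid is
  # slightly non-convex even without a dimple
  expect_gt(fv[["global.solidity_3d"]], 0.85)
  expect_lte(fv[["global.solidity_3d"]], 1)
  expect_equal(fv[["global.width_length_ratio"]],
               fv[["global.width"]] / fv[["global.length"]])
  # aneurysm volume close to the analytic profile integral; the curve's
  # s-origin is shifted relative to the generator's, so map the detected
  # necks onto the profile via the (symmetric) bulge center
  s0 <- 20 - (lay$s_proximal + lay$L / 2)
  vol_true <- integrate(function(s) pi * gauss_bulge_r(s + s0)^2,
                        lay$s_proximal, lay$s_distal)$value
  expect_equal(fv[["global.aneurysm_volume"]], vol_true, tolerance = 0.03)
})
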