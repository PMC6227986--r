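test_that("section indices match closed forms for disc, ellipse, notched disc", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  disc <- cbind(2 * cos(th), 2 * sin(th))
  i <- section_indices(disc)
  expect_equal(i$d_max, 4, tolerance = 0.001)
  expect_equal(i$d_min, 4, tolerance = 0.001)
  expect_equal(i$d_eq, 4, tolerance = 0.001)
  expect_equal(i$eccentricity, 0, tolerance = 0.01)
  expect_equal(i$solidity, 1, tolerance = 1e-6)
  expect_equal(i$extent, pi / 4, tolerance = 0.001)

  ell <- cbind(3 * cos(th), 1.5 * sin(th))
  i <- section_indices(ell)
  expect_equal(i$area, 4.5 * pi, tolerance = 0.001)
  expect_equal(i$d_eq, sqrt(18), tolerance = 0.001)
  expect_equal(i$eccentricity, sqrt(1 - 0.25), tolerance = 0.001)
  expect_equal(i$extent, pi / 4, tolerance = 0.001)

  # disc of radius 2 minus a 90-degree wedge: hull closes the wedge with a
  # 2 mm^2 triangle, so solidity = 3pi / (3pi + 2)
  th2 <- seq(pi / 2, 2 * pi, length.out = 541)
  notch <- rbind(c(0, 0), cbind(2 * cos(th2), 2 * sin(th2)))
  i <- section_indices(notch)
  expect_equal(i$area, 3 * pi, tolerance = 0.001)
  expect_equal(i$solidity, 3 * pi / (3 * pi + 2), tolerance = 0.001)

  expect_error(section_indices(cbind(c(0, 1), c(0, 0))), "degenerate")
})

test_that("index inequalities hold on random lumen-like polygons", {
  # mildly irregular star-shaped contours, the regime of vessel lumina
  # (the d_min <= d_eq inequality is a property of near-convex regions,
  # not of arbitrary polygons: a Reuleaux-like set already violates it)
  set.seed(7)
  for (rep in 1:25) {
    th <- seq(0, 2 * pi, length.out = 181)[-181]
    aspect <- runif(1, 1, 2)
    amp <- runif(1, 0, 0.05)
    mode <- sample(2:4, 1)
    phi <- runif(1, 0, 2 * pi)
    rot <- runif(1, 0, pi)
    r <- 2.3 * (1 + amp * sin(mode * th + phi))
    xy <- cbind(aspect * r * cos(th), r * sin(th))
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    poly <- xy %*% R
    i <- section_indices(poly)
    expect_lte(i$d_min, i$d_eq + 1e-9)
    expect_lte(i$d_eq, i$d_max + 1e-9)
    expect_true(i$eccentricity >= 0 && i$eccentricity < 1)
    expect_true(i$solidity > 0 && i$solidity <= 1)
    expect_true(i$extent > 0 && i$extent <= 1)
  }
})

test_that("mesh-plane slices select the component containing the axis point", {
  m <- tube_mesh(analytic_centerline("straight", length = 30),
                 radius_profile(r0 = 2), angular_res = 64, axial_res = 80)
  # perpendicular slice of the cylinder: circle of radius 2
  sec <- vafamorph:::slice_plane(m, origin = c(0, 0, 15),
                                 normal = c(0, 0, 1),
                                 U = c(1, 0, 0), V = c(0, 1, 0))
  i <- section_indices(sec)
  expect_equal(i$area, 4 * pi, tolerance = 0.01)

  # elliptical tube (cylinder scaled x by 1.5): semi-axes 3 and 1.5
  me <- surface_mesh(m$vertices %*% diag(c(1.5, 0.75, 1)), m$faces)
  sece <- vafamorph:::slice_plane(me, origin = c(0, 0, 15),
                                  normal = c(0, 0, 1),
                                  U = c(1, 0, 0), V = c(0, 1, 0))
  ie <- section_indices(sece)
  expect_equal(ie$area, 3 * 1.5 * pi, tolerance = 0.01)

  # two parallel tubes welded into one mesh: only the tube containing the
  # queried axis point is returned
  m2 <- transform_mesh(m, translation = c(10, 0, 0))
  both <- surface_mesh(rbind(m$vertices, m2$vertices),
                       rbind(m$faces, m2$faces + nrow(m$vertices)))
  s1 <- vafamorph:::slice_plane(both, origin = c(0, 0, 15),
                                normal = c(0, 0, 1),
                                U = c(1, 0, 0), V = c(0, 1, 0))
  expect_equal(abs(vafamorph:::polygon_area_signed(s1$poly)), 4 * pi,
               tolerance = 0.01)
  expect_lt(max(abs(s1$poly3d[, 1])), 3)   # stayed on the first tube
  expect_error(
    vafamorph:::slice_plane(both, origin = c(5, 0, 15), normal = c(0, 0, 1),
                            U = c(1, 0, 0), V = c(0, 1, 0)),
    "outside every intersection component")
})

test_that("sequence sweeps honor constant, conical and bulged profiles", {
  # constant tube: A constant, dA/ds ~ 0
  m <- tube_mesh(analytic_centerline("straight", length = 30),
                 radius_profile(r0 = 2), angular_res = 48, axial_res = 100)
  cv <- vessel_centerline(m, spacing = 0.4)
  sq <- sweep_sequences(m, cv)
  ok <- !sq$flagged & !is.na(sq$seq[, "area"])
  expect_equal(unname(sq$seq[ok, "area"]), rep(4 * pi, sum(ok)),
               tolerance = 0.01)
  expect_lt(max(abs(sq$seq[ok, "area_rate"])),
            0.02 * mean(sq$seq[ok, "area"]))
  # per-station diameter inequalities on a real sweep
  expect_true(all(sq$seq[ok, "d_min"] <= sq$seq[ok, "d_eq"] + 1e-9))
  expect_true(all(sq$seq[ok, "d_eq"] <= sq$seq[ok, "d_max"] + 1e-9))

  # cone-like tube r(s) = 1 + 0.1 s: dA/ds = 0.2 pi r
  mc <- tube_mesh(analytic_centerline("straight", length = 30),
                  function(s, theta = NULL) 1 + 0.1 * s,
                  angular_res = 48, axial_res = 100)
  cvc <- vessel_centerline(mc, spacing = 0.4)
  sqc <- sweep_sequences(mc, cvc)
  okc <- which(!sqc$flagged & !is.na(sqc$seq[, "area_rate"]))
  okc <- okc[-c(1, length(okc))]
  r_here <- sqrt(sqc$seq[okc, "area"] / pi)
  expect_equal(unname(sqc$seq[okc, "area_rate"]),
               unname(2 * pi * r_here * 0.1), tolerance = 0.05)

  # Gaussian bulge: area maximum at the bulge center
  mb <- fusiform_phantom(axial_res = 150)
  cvb <- vessel_centerline(mb, spacing = 0.4)
  sqb <- sweep_sequences(mb, cvb)
  smax <- sqb$s[which.max(sqb$seq[, "area"])]
  p_at_max <- centerline_eval(cvb, smax)
  expect_equal(p_at_max[1, 3], 20, tolerance = 0.4 + 0.01)
})

test_that("section indices are invariant to rigid motion", {
  m <- fusiform_phantom(axial_res = 120)
  ang <- 0.7
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3)
  mt <- transform_mesh(m, rotation = Rx %*% Rz, translation = c(5, -3, 7))
  cv <- vessel_centerline(m, spacing = 0.4)
  cvt <- vessel_centerline(mt, spacing = 0.4)
  sq <- sweep_sequences(m, cv)
  sqt <- sweep_sequences(mt, cvt)
  for (nm in c("area", "d_max", "solidity")) {
    a <- max(sq$seq[, nm], na.rm = TRUE)
    b <- max(sqt$seq[, nm], na.rm = TRUE)
    expect_equal(a, b, tolerance = 0.01)
  }
})
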