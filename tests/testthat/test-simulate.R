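test_that("analytic centerlines reproduce closed-form differential geometry", {
  s <- seq(0, 40, by = 0.5)
  straight <- analytic_centerline("straight", length = 40)
  expect_equal(straight$kappa(s), rep(0, length(s)))
  expect_equal(straight$tau(s), rep(0, length(s)))

  arc <- analytic_centerline("arc", length = 15, radius = 10)
  sa <- seq(0, 15, by = 0.5)
  expect_equal(arc$kappa(sa), rep(0.1, length(sa)))
  expect_equal(arc$tau(sa), rep(0, length(sa)))

  hel <- analytic_centerline("helix", length = 40, a = 3, b = 1)
  expect_equal(hel$kappa(s), rep(0.3, length(s)))
  expect_equal(hel$tau(s), rep(0.1, length(s)))

  # unit tangents and strictly increasing arc length for all three
  for (crv in list(straight, arc, hel)) {
    Tg <- crv$tangent(seq(0, crv$length, length.out = 50))
    expect_equal(sqrt(rowSums(Tg^2)), rep(1, 50), tolerance = 1e-9)
    p <- crv$point(seq(0, crv$length, length.out = 200))
    arclen <- cumsum(c(0, sqrt(rowSums(diff(p)^2))))
    expect_true(all(diff(arclen) > 0))
    # chord-sum converges to the nominal arc length
    expect_equal(arclen[200], crv$length, tolerance = 1e-3)
  }
  expect_error(analytic_centerline("arc", radius = -1), "radius")
  expect_error(analytic_centerline("straight", length = 0), "length")
})

test_that("swept tube meshes are watertight with the correct volume", {
  crv <- analytic_centerline("straight", length = 40)
  m <- tube_mesh(crv, radius_profile(r0 = 2), angular_res = 64,
                 axial_res = 120)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), pi * 4 * 40, tolerance = 0.01)

  hel <- analytic_centerline("helix", length = 30, a = 3, b = 1)
  mh <- tube_mesh(hel, radius_profile(r0 = 1.2), angular_res = 24,
                  axial_res = 80)
  expect_true(is_watertight(mh))

  # Gaussian bulge: maximum diameter ~ 2 * (r0 + amplitude) at the center
  mb <- fusiform_phantom(angular_res = 64, axial_res = 220)
  rad <- sqrt(mb$vertices[, 1]^2 + mb$vertices[, 2]^2)
  expect_equal(2 * max(rad), 8, tolerance = 0.005)
  expect_equal(mb$vertices[which.max(rad), 3], 20, tolerance = 0.2)

  expect_error(tube_mesh(crv, radius_profile(r0 = 2), angular_res = 8),
               "angular_res")
  expect_error(tube_mesh(crv, radius_profile(r0 = 2), axial_res = 10),
               "axial_res")
})

test_that("too-large bulges on curved centerlines raise a located geometry error", {
  arc <- analytic_centerline("arc", length = 20, radius = 5)  # kappa = 0.2
  # radius exceeds the 5 mm radius of curvature mid-bulge
  expect_error(
    tube_mesh(arc, radius_profile(r0 = 2, amplitude = 4, center = 10,
                                  width = 3)),
    "self-intersects near s")
})

test_that("rotation-minimizing frames stay orthonormal and flip-free", {
  hel <- analytic_centerline("helix", length = 40, a = 3, b = 1)
  s <- seq(0, 40, by = 0.25)
  P <- hel$point(s); Tg <- hel$tangent(s)
  fr <- rotation_minimizing_frame(P, Tg)
  expect_equal(rowSums(fr$U^2), rep(1, length(s)), tolerance = 1e-9)
  expect_equal(rowSums(fr$U * Tg), rep(0, length(s)), tolerance = 1e-9)
  expect_equal(rowSums(fr$U * fr$V), rep(0, length(s)), tolerance = 1e-9)
  # minimal rotation: successive U vectors rotate at most by ~kappa*ds
  expect_true(all(rowSums(fr$U[-1, ] * fr$U[-length(s), ]) > cos(2 * 0.3 * 0.25)))
})

test_that("STL files round-trip in both dialects to single precision", {
  m <- tube_mesh(analytic_centerline("straight", length = 20),
                 radius_profile(r0 = 2), angular_res = 16, axial_res = 50)
  fb <- tempfile(fileext = ".stl"); fa <- tempfile(fileext = ".stl")
  write_stl(m, fb, binary = TRUE)
  write_stl(m, fa, binary = FALSE)
  mb <- read_stl(fb); ma <- read_stl(fa)
  expect_true(is_watertight(mb))
  expect_true(is_watertight(ma))
  expect_equal(nrow(mb$faces), nrow(m$faces))
  # every written-and-read vertex matches an original to single precision
  nn_err <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    max(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  expect_lt(nn_err(mb$vertices, m$vertices), 1e-5)
  expect_lt(nn_err(ma$vertices, m$vertices), 1e-5)
  expect_equal(mesh_volume(mb), mesh_volume(m), tolerance = 1e-5)
  unlink(c(fb, fa))
})
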