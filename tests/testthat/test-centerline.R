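test_that("skeletons of straight tubes lie on the true axis", {
  m <- tube_mesh(analytic_centerline("straight", length = 40),
                 radius_profile(r0 = 2), angular_res = 48, axial_res = 120)
  h <- 0.5
  g <- voxelize_mesh(m, spacing = h)
  pts <- skeletonize_and_order(g)
  expect_lte(sqrt(mean(pts[, 1]^2 + pts[, 2]^2)), h)   # RMS distance to axis
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  # thinning retracts about one radius from each capped end
  expect_equal(arc, 40, tolerance = 0.15)
  expect_gt(length(attr(pts, "radius")), 0)
})

test_that("skeletons of curved tubes recover the bend radius", {
  m <- tube_mesh(analytic_centerline("arc", length = 20, radius = 10),
                 radius_profile(r0 = 2), angular_res = 48, axial_res = 120)
  pts <- skeletonize_and_order(voxelize_mesh(m, spacing = 0.4))
  # Kasa circle fit in the arc's plane (z = 0)
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  R <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_equal(unname(R), 10, tolerance = 0.05)
  expect_lt(max(abs(pts[, 3])), 0.4)     # stays in the bend plane
})

test_that("a one-voxel-thick skeleton passes through unchanged up to ordering", {
  n <- 30
  idx <- cbind(rep(5, n), rep(5, n), seq_len(n) + 2)
  g <- grid_from_indices(idx, dims = c(10, 10, 40), spacing = 0.5)
  pts <- skeletonize_and_order(g)
  expect_equal(nrow(pts), n)
  expect_true(all(diff(pts[, 3]) > 0) || all(diff(pts[, 3]) < 0))
  expect_equal(sort(pts[, 3]), sort((idx[, 3] - 1) * 0.5))
})

test_that("disconnected occupancy is rejected", {
  idx <- rbind(cbind(2:5, 5, 5), cbind(12:15, 5, 5))
  g <- grid_from_indices(idx, dims = c(20, 10, 10), spacing = 0.5)
  expect_error(skeletonize_and_order(g), "single connected component")
})

test_that("centerline fitting interpolates exact samples and rejects short input", {
  hel <- analytic_centerline("helix", length = 30, a = 3, b = 1)
  s <- seq(0, 30, by = 0.5)
  P <- hel$point(s)
  cv <- fit_centerline(P, smoothing = 0)
  fitted <- centerline_eval(cv, cv$s)
  # compare at the resampled stations against the true helix
  truth <- hel$point(cv$s)
  expect_lt(max(abs(fitted - truth)), 5e-3)
  # and interpolation residual at the input samples themselves
  tq <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  res <- vafamorph:::pspline_eval(cv$fit, tq) - P
  expect_lt(max(abs(res)), 1e-6)
  expect_error(fit_centerline(P[1:7, ]), "at least 8 points")
})

test_that("smoothing recovers curvature from noisy circle samples", {
  set.seed(4)
  th <- seq(0, 1.8 * pi, length.out = 240)
  P <- cbind(10 * cos(th), 10 * sin(th), 0) + matrix(rnorm(720, 0, 0.1), 240)
  cv <- fit_centerline(P, smoothing = 0.2)
  i <- which(cv$s > 0.1 * cv$total_length & cv$s < 0.9 * cv$total_length)
  # 0.1 mm point noise limits pointwise curvature precision; the recovered
  # curvature is within 5% in the mean and within 10% for 90% of stations
  expect_equal(mean(cv$kappa[i]), 0.1, tolerance = 0.05)
  expect_lt(unname(quantile(abs(cv$kappa[i] - 0.1), 0.9)), 0.1 * 0.1)
})

test_that("Frenet quantities respect orientation and degeneracy conventions", {
  hel <- analytic_centerline("helix", length = 30, a = 3, b = 1)
  s <- seq(0, 30, by = 0.25)
  P <- hel$point(s)
  fwd <- fit_centerline(P, smoothing = 0)
  rev_ <- fit_centerline(P[rev(seq_len(nrow(P))), ], smoothing = 0)
  mir <- fit_centerline(P %*% diag(c(-1, 1, 1)), smoothing = 0)
  i <- which(fwd$s > 3 & fwd$s < 27)
  expect_equal(mean(fwd$kappa[i]), 0.3, tolerance = 0.01)
  expect_equal(mean(fwd$tau[i]), 0.1, tolerance = 0.01)
  # torsion measures chirality: invariant under traversal reversal,
  # negated under mirror reflection
  j <- which(rev_$s > 3 & rev_$s < 27)
  expect_equal(mean(rev_$kappa[j]), 0.3, tolerance = 0.01)
  expect_equal(mean(rev_$tau[j]), 0.1, tolerance = 0.01)
  k <- which(mir$s > 3 & mir$s < 27)
  expect_equal(mean(mir$tau[k]), -0.1, tolerance = 0.01)

  # straight line: kappa ~ 0, tau flagged zero
  line <- cbind(0, 0, seq(0, 20, by = 0.5))
  lf <- fit_centerline(line, smoothing = 0)
  fr <- frenet_kappa_tau(lf)
  expect_lt(max(fr$kappa), 1e-6)
  expect_true(all(fr$tau == 0))
  expect_true(all(fr$tau_flagged))
})

test_that("kappa and tau converge toward closed forms as h shrinks", {
  m <- tube_mesh(analytic_centerline("arc", length = 25, radius = 10),
                 radius_profile(r0 = 2), angular_res = 48, axial_res = 150)
  err <- vapply(c(0.5, 0.3), function(h) {
    cv <- vessel_centerline(m, spacing = h)
    i <- which(cv$s > 0.15 * cv$total_length & cv$s < 0.85 * cv$total_length)
    max(abs(cv$kappa[i] - 0.1)) / 0.1
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.01)   # no degradation under refinement
})

test_that("centerline export writes one row per station", {
  line <- cbind(0, 0, seq(0, 20, by = 0.5))
  cv <- fit_centerline(line, smoothing = 0)
  f <- tempfile(fileext = ".csv")
  export_centerline(cv, f)
  df <- read.csv(f)
  expect_identical(names(df), c("s", "x", "y", "z", "kappa", "tau"))
  expect_equal(nrow(df), length(cv$s))
  unlink(f)
})
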