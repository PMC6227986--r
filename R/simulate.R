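#' Analytic centerline with closed-form differential geometry
#'
#' Provides exact point, tangent, curvature and torsion evaluators for
#' three test-curve families, used as ground truth when validating the
#' centerline-extraction and Frenet-Serret stages.
#'
#' * `"straight"`: a line of the given `length` along +z; kappa = tau = 0.
#' * `"arc"`: a circular arc of radius `radius` (kappa = 1/R, tau = 0)
#'   spanning `length` of arc.
#' * `"helix"`: x = a cos t, y = a sin t, z = b t, with
#'   kappa = a/(a^2+b^2) and tau = b/(a^2+b^2), of total arc `length`.
#'
#' @param kind one of `"straight"`, `"arc"`, `"helix"`.
#' @param length total arc length (mm).
#' @param radius arc radius R (mm), for `kind = "arc"`.
#' @param a,b helix radius and pitch parameters (mm), for `kind = "helix"`.
#' @return An `analytic_curve` with functions `point(s)`, `tangent(s)`,
#'   `kappa(s)`, `tau(s)` taking arc length `s` in `[0, length]`.
#' @export
analytic_centerline <- function(kind = c("straight", "arc", "helix"),
                                length = 40, radius = 10, a = 3, b = 1) {
  kind <- match.arg(kind)
  if (length <= 0) stop("length must be positive")
  if (kind == "straight") {
    crv <- list(
      point = function(s) cbind(0 * s, 0 * s, s),
      tangent = function(s) cbind(0 * s, 0 * s, 1 + 0 * s),
      kappa = function(s) 0 * s,
      tau = function(s) 0 * s)
  } else if (kind == "arc") {
    if (radius <= 0) stop("arc radius must be positive")
    R <- radius
    crv <- list(
      point = function(s) cbind(R * cos(s / R) - R, R * sin(s / R), 0 * s),
      tangent = function(s) cbind(-sin(s / R), cos(s / R), 0 * s),
      kappa = function(s) rep(1 / R, length(s)),
      tau = function(s) 0 * s)
  } else {
    if (a <= 0) stop("helix radius a must be positive")
    c2 <- a^2 + b^2
    w <- 1 / sqrt(c2)                     # dt/ds
    crv <- list(
      point = function(s) cbind(a * cos(w * s) - a, a * sin(w * s), b * w * s),
      tangent = function(s) cbind(-a * w * sin(w * s), a * w * cos(w * s),
                                  rep(b * w, length(s))),
      kappa = function(s) rep(a / c2, length(s)),
      tau = function(s) rep(b / c2, length(s)))
  }
  structure(c(crv, list(kind = kind, length = length)),
            class = "analytic_curve")
}

#' Radius profile of a synthetic fusiform vessel
#'
#' Describes the lumen radius as a function of arc length `s` (and
#' circumferential angle `theta` when a dimple is present):
#'
#' `r(s, theta) = r0 + amplitude * exp(-(s - center)^2 / (2 width^2)) *
#'                [1 + skew * tanh((s - center)/width)] - dimple(s, theta)`
#'
#' A positive `skew` enlarges the distal half of the bulge, which lowers
#' the proximal/distal cross-sectional area ratio; the dimple is an inward
#' radial displacement on a compact angular x axial window, the controlled
#' way to lower cross-section solidity.
#'
#' @param r0 baseline vessel radius (mm).
#' @param amplitude bulge amplitude (mm); 0 gives a constant-radius tube.
#' @param center bulge center s_c along the centerline (mm).
#' @param width bulge Gaussian sigma-like width w (mm).
#' @param skew unitless asymmetry; > 0 enlarges the distal half.
#' @param dimple_depth inward dimple depth (mm), 0 for none.
#' @param dimple_theta,dimple_theta_width dimple angular center and
#'   half-width (radians); the default width 0.35 is narrow enough that a
#'   >= 0.5 mm dimple on a 4 mm-radius bulge makes the contour locally
#'   concave (a wide shallow dimple merely flattens it).
#' @param dimple_s,dimple_s_width dimple axial center and half-width (mm);
#'   `dimple_s = NULL` places it at the bulge center.
#' @return A `radius_profile`; callable as `r(s, theta)`.
#' @export
radius_profile <- function(r0 = 2, amplitude = 0, center = 20, width = 3,
                           skew = 0, dimple_depth = 0, dimple_theta = 0,
                           dimple_theta_width = 0.35, dimple_s = NULL,
                           dimple_s_width = 2.5) {
  if (r0 <= 0) stop("baseline radius must be positive")
  if (is.null(dimple_s)) dimple_s <- center
  f <- function(s, theta = NULL) {
    # the skew modulates the bulge only, never the parent-vessel caliber:
    # scaling the baseline too would turn the whole distal vessel into a
    # super-threshold "aneurysm" during detection
    base <- r0 + amplitude * exp(-(s - center)^2 / (2 * width^2)) *
      (1 + skew * tanh((s - center) / width))
    if (dimple_depth > 0 && !is.null(theta)) {
      dth <- atan2(sin(theta - dimple_theta), cos(theta - dimple_theta))
      win <- exp(-dth^2 / (2 * dimple_theta_width^2)) *
        exp(-(s - dimple_s)^2 / (2 * dimple_s_width^2))
      base <- base - dimple_depth * win
    }
    if (any(base <= 0)) stop("radius profile must stay positive")
    base
  }
  structure(list(r = f, r0 = r0, amplitude = amplitude, center = center,
                 width = width, skew = skew, dimple_depth = dimple_depth),
            class = "radius_profile")
}

#' Rotation-minimizing frames along a curve (double-reflection method)
#'
#' Given points and unit tangents sampled along a curve, propagates an
#' initial in-plane frame (U, V) with minimal rotation, avoiding the frame
#' flips of the Frenet frame where curvature vanishes.
#'
#' @param points `n x 3` curve points.
#' @param tangents `n x 3` unit tangents.
#' @return List of `U`, `V`: `n x 3` unit in-plane frame vectors.
#' @export
rotation_minimizing_frame <- function(points, tangents) {
  n <- nrow(points)
  U <- matrix(0, n, 3); V <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  seed <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * t1) * t1
  u <- u / sqrt(sum(u^2))
  U[1, ] <- u
  V[1, ] <- c(t1[2] * u[3] - t1[3] * u[2],
              t1[3] * u[1] - t1[1] * u[3],
              t1[1] * u[2] - t1[2] * u[1])
  for (i in seq_len(n - 1)) {
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-300) { U[i + 1, ] <- U[i, ]; V[i + 1, ] <- V[i, ]; next }
    uL <- U[i, ] - (2 / c1) * sum(v1 * U[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    u2 <- if (c2 < 1e-300) uL else uL - (2 / c2) * sum(v2 * uL) * v2
    u2 <- u2 - sum(u2 * tangents[i + 1, ]) * tangents[i + 1, ]
    u2 <- u2 / sqrt(sum(u2^2))
    U[i + 1, ] <- u2
    tn <- tangents[i + 1, ]
    V[i + 1, ] <- c(tn[2] * u2[3] - tn[3] * u2[2],
                    tn[3] * u2[1] - tn[1] * u2[3],
                    tn[1] * u2[2] - tn[2] * u2[1])
  }
  list(U = U, V = V)
}

#' Sweep a watertight tube mesh along a centerline
#'
#' Circular cross-sections (optionally modulated by a dimple) are swept in
#' a rotation-minimizing frame and the two ends are closed with triangle
#' fans, yielding a watertight, consistently oriented mesh.
#'
#' @param curve an `analytic_curve` (or any list with `point`, `tangent`,
#'   `kappa` evaluators and a `length`).
#' @param profile a `radius_profile`, or a function `r(s)` / `r(s, theta)`.
#' @param angular_res number of circumferential vertices (>= 12).
#' @param axial_res number of axial stations (>= 50).
#' @return A `surface_mesh`.
#' @export
tube_mesh <- function(curve, profile, angular_res = 64, axial_res = 200) {
  if (angular_res < 12) stop("angular_res must be at least 12")
  if (axial_res < 50) stop("axial_res must be at least 50")
  rfun <- if (inherits(profile, "radius_profile")) profile$r
          else profile
  s <- seq(0, curve$length, length.out = axial_res)
  P <- curve$point(s)
  Tg <- curve$tangent(s)
  # guard against local self-intersection of the sweep
  kap <- curve$kappa(s)
  rmax <- vapply(s, function(si) max(rfun(si, seq(0, 2 * pi, length.out = 17))),
                 numeric(1))
  bad <- which(kap * rmax >= 1)
  if (length(bad))
    stop(sprintf("tube self-intersects near s = %.2f mm (radius %.2f exceeds radius of curvature %.2f)",
                 s[bad[1]], rmax[bad[1]], 1 / kap[bad[1]]))
  fr <- rotation_minimizing_frame(P, Tg)
  theta <- seq(0, 2 * pi, length.out = angular_res + 1)[-(angular_res + 1)]
  nv <- axial_res * angular_res
  verts <- matrix(0, nv + 2, 3)
  for (i in seq_len(axial_res)) {
    r <- rfun(s[i], theta)
    ring <- P[rep(i, angular_res), , drop = FALSE] +
      outer(r * cos(theta), fr$U[i, ]) + outer(r * sin(theta), fr$V[i, ])
    verts[(i - 1) * angular_res + seq_len(angular_res), ] <- ring
  }
  verts[nv + 1, ] <- P[1, ]                 # proximal cap apex
  verts[nv + 2, ] <- P[axial_res, ]         # distal cap apex
  # side quads -> two triangles, outward orientation
  faces <- vector("list", axial_res + 1)
  idx <- function(i, j) (i - 1) * angular_res + ((j - 1) %% angular_res) + 1
  for (i in seq_len(axial_res - 1)) {
    j <- seq_len(angular_res)
    a <- idx(i, j); b <- idx(i + 1, j); c_ <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    faces[[i]] <- rbind(cbind(a, c_, b), cbind(a, d, c_))
  }
  j <- seq_len(angular_res)
  faces[[axial_res]] <- cbind(nv + 1, idx(1, j + 1), idx(1, j))
  faces[[axial_res + 1]] <- cbind(nv + 2, idx(axial_res, j), idx(axial_res, j + 1))
  mesh <- surface_mesh(verts, do.call(rbind, faces))
  attr(mesh, "stations") <- s
  mesh
}

#' Standard synthetic fusiform-aneurysm phantom
#'
#' Convenience constructor for the validation phantom used throughout the
#' package: a Gaussian bulge, optionally skewed and dimpled, on a straight
#' or gently curved parent vessel.
#'
#' @param length vessel length (mm).
#' @param kind centerline kind, see [analytic_centerline()].
#' @param r0,amplitude,center,width,skew,dimple_depth see [radius_profile()].
#' @param angular_res,axial_res sweep resolutions, see [tube_mesh()].
#' @param ... further arguments passed to [radius_profile()].
#' @return A `surface_mesh` with the generating `radius_profile` attached
#'   as attribute `"profile"` and the true curve as `"curve"`.
#' @export
fusiform_phantom <- function(length = 40, kind = "straight", r0 = 2,
                             amplitude = 2, center = length / 2, width = 3,
                             skew = 0, dimple_depth = 0,
                             angular_res = 64, axial_res = 220, ...) {
  crv <- analytic_centerline(kind, length = length)
  prof <- radius_profile(r0 = r0, amplitude = amplitude, center = center,
                         width = width, skew = skew,
                         dimple_depth = dimple_depth, ...)
  mesh <- tube_mesh(crv, prof, angular_res = angular_res, axial_res = axial_res)
  attr(mesh, "profile") <- prof
  attr(mesh, "curve") <- crv
  mesh
}
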