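#' Fit a smooth centerline curve through ordered skeleton points
#'
#' Fits penalized quintic B-splines (one per coordinate) against the
#' cumulative chord-length parameter, then reparameterizes to arc length.
#' The penalty weight is chosen automatically as the strongest smoothing
#' whose maximum deviation from the input points stays within the
#' smoothing tolerance; `smoothing = 0` requests (numerical)
#' interpolation.  Quintic splines give continuous analytic derivatives up
#' to third order, as required for curvature and torsion.
#'
#' @param points `n x 3` ordered points (mm), `n >= 8`.
#' @param smoothing tolerance (mm): maximum allowed deviation of the fit
#'   from the input points.  Defaults to the median consecutive point
#'   spacing (the voxelization noise floor when points come from a
#'   skeleton).
#' @param ds resampling step for the arc-length grid (mm); defaults to the
#'   median consecutive point spacing.
#' @param end_trim stations within `end_trim` (mm) of either curve end are
#'   flagged; flagged stations are excluded from downstream feature
#'   segments (end effects of thinning and slicing).
#' @param knot_spacing inner knot spacing (mm); `NULL` for the default
#'   (~2 mm).  Wide knots give a heavily smoothed curve useful for
#'   stable slicing frames.
#' @param method penalty-weight selection: `"tolerance"` (strongest
#'   smoothing whose per-coordinate RMS deviation stays within
#'   `smoothing`; right for noise-floor-limited inputs such as raw
#'   skeletons) or `"gcv"` (generalized cross-validation; right for
#'   variance-limited inputs such as section centroids).
#' @return A `centerline_curve`: arc-length grid `s`, `points`, unit
#'   `tangents`, `kappa` (1/mm, >= 0), `tau` (1/mm, signed), logical
#'   `flagged`, plus the spline representation.
#' @export
fit_centerline <- function(points, smoothing = NULL, ds = NULL, end_trim = 0,
                           knot_spacing = NULL,
                           method = c("tolerance", "gcv")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) < 8) stop("need at least 8 points to fit a centerline")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(points)^2))
  }
  tpar <- c(0, cumsum(seg))
  step <- stats::median(seg)
  if (is.null(smoothing)) smoothing <- step
  if (is.null(ds)) ds <- step
  tol <- max(smoothing, 1e-9)

  fit <- pspline_fit3(tpar, points, tol, interpolate = smoothing == 0,
                      knot_spacing = knot_spacing, method = method)

  # reparameterize to arc length
  tfine <- seq(tpar[1], tpar[length(tpar)], length.out = max(200L, 5L * length(tpar)))
  d1 <- pspline_eval(fit, tfine, deriv = 1)
  speed <- sqrt(rowSums(d1^2))
  sfine <- cumtrapz(tfine, speed)
  total <- sfine[length(sfine)]
  t_of_s <- stats::splinefun(sfine, tfine, method = "hyman")
  s <- seq(0, total, by = ds)
  if (s[length(s)] < total - 1e-9) s <- c(s, total)
  tq <- t_of_s(pmin(s, total))

  curve <- structure(list(fit = fit, s = s, t = tq, total_length = total,
                          t_of_s = t_of_s, ds = ds, smoothing = smoothing),
                     class = "centerline_curve")
  geo <- frenet_at(curve, s)
  curve$points <- geo$points
  curve$tangents <- geo$tangents
  curve$kappa <- geo$kappa
  curve$tau <- geo$tau
  curve$tau_flagged <- geo$tau_flagged
  curve$flagged <- s < end_trim | s > total - end_trim
  curve$frame <- rotation_minimizing_frame(curve$points, curve$tangents)
  curve
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("centerline_curve: length %.2f mm, %d stations (ds = %.3g mm)\n",
              x$total_length, length(x$s), x$ds))
  cat(sprintf("  kappa range [%.4g, %.4g] 1/mm; tau range [%.4g, %.4g] 1/mm\n",
              min(x$kappa), max(x$kappa), min(x$tau), max(x$tau)))
  invisible(x)
}

#' Evaluate a centerline curve
#' @param curve a `centerline_curve`.
#' @param s arc-length positions (mm).
#' @param deriv derivative order 0..3 (with respect to the internal chord
#'   parameter for orders > 0).
#' @return `length(s) x 3` matrix.
#' @export
centerline_eval <- function(curve, s, deriv = 0) {
  tq <- curve$t_of_s(pmin(pmax(s, 0), curve$total_length))
  pspline_eval(curve$fit, tq, deriv = deriv)
}

#' Frenet-Serret curvature and torsion along a centerline
#'
#' Computes kappa = |P' x P''| / |P'|^3 and
#' tau = (P' x P'') . P''' / |P' x P''|^2 from the analytic spline
#' derivatives (parameterization-invariant formulas).  Where
#' kappa < 1e-6 / mm the Frenet frame is degenerate and tau is reported
#' as 0 and flagged.
#'
#' @param curve a `centerline_curve`.
#' @param s stations (mm); defaults to the curve's grid.
#' @return List with `s`, `kappa`, `tau`, and logical `tau_flagged`.
#' @export
frenet_kappa_tau <- function(curve, s = curve$s) {
  geo <- frenet_at(curve, s)
  list(s = s, kappa = geo$kappa, tau = geo$tau, tau_flagged = geo$tau_flagged)
}

frenet_at <- function(curve, s, kappa_min = 1e-6) {
  tq <- curve$t_of_s(pmin(pmax(s, 0), curve$total_length))
  p0 <- pspline_eval(curve$fit, tq, 0)
  p1 <- pspline_eval(curve$fit, tq, 1)
  p2 <- pspline_eval(curve$fit, tq, 2)
  p3 <- pspline_eval(curve$fit, tq, 3)
  cr <- cross3(p1, p2)
  ncr <- sqrt(rowSums(cr^2))
  sp <- sqrt(rowSums(p1^2))
  kappa <- ncr / sp^3
  tau <- rep(0, length(s))
  ok <- kappa >= kappa_min & ncr > 0
  tau[ok] <- rowSums(cr[ok, , drop = FALSE] * p3[ok, , drop = FALSE]) /
    ncr[ok]^2
  list(points = p0, tangents = p1 / sp, kappa = kappa, tau = tau,
       tau_flagged = !ok)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

# ---- penalized quintic B-spline fit ---------------------------------------

pspline_fit3 <- function(tpar, Y, tol, interpolate = FALSE,
                         knot_spacing = NULL, method = "tolerance") {
  ord <- 6L
  t0 <- tpar[1]; t1 <- tpar[length(tpar)]
  span <- t1 - t0
  if (interpolate) {
    inner <- tpar
    knots <- c(rep(t0, ord - 1), inner, rep(t1, ord - 1))
    B <- splines::splineDesign(knots, tpar, ord = ord)
    D <- diff(diag(ncol(B)), differences = 3)
    BtB <- crossprod(B); DtD <- crossprod(D)
    lam <- 1e-12 * sum(diag(BtB)) / max(sum(diag(DtD)), 1e-300)
    coef <- solve(BtB + lam * DtD, crossprod(B, Y))
    return(list(knots = knots, ord = ord, coef = coef, trange = c(t0, t1)))
  }
  # knots every ~2 mm; the penalty weight is either the strongest
  # smoothing whose RMS deviation from the points stays within the
  # tolerance (noise-floor-driven data such as raw skeletons), or the GCV
  # optimum (variance-limited data such as section centroids)
  delta0 <- if (is.null(knot_spacing)) max(2.0, 4 * stats::median(diff(tpar)))
            else knot_spacing
  m <- max(4L, ceiling(span / delta0) + 1L)
  inner <- seq(t0, t1, length.out = m)
  knots <- c(rep(t0, ord - 1), inner, rep(t1, ord - 1))
  B <- splines::splineDesign(knots, tpar, ord = ord)
  D <- diff(diag(ncol(B)), differences = 3)
  BtB <- crossprod(B); DtD <- crossprod(D); BtY <- crossprod(B, Y)
  n <- nrow(B)
  lam_ref <- sum(diag(BtB)) / max(sum(diag(DtD)), 1e-300)
  grid <- lam_ref * 10^seq(-8, 4, by = 0.5)
  best <- NULL; fallback <- NULL
  for (lam in grid) {
    A <- BtB + lam * DtD
    coef <- try(solve(A, BtY), silent = TRUE)
    if (inherits(coef, "try-error")) next
    R <- Y - B %*% coef
    dev <- sqrt(mean(R^2))          # per-coordinate RMS deviation
    edf <- sum(diag(solve(A, BtB)))
    gcv <- n * sum(R^2) / (n - edf)^2
    if (is.null(fallback) || gcv < fallback$gcv)
      fallback <- list(coef = coef, gcv = gcv)  # unconstrained GCV optimum
    # ascending lambda grid: keep the last fit within tolerance
    if (method == "tolerance" && dev <= tol) best <- coef
  }
  if (is.null(best)) best <- fallback$coef
  list(knots = knots, ord = ord, coef = best, trange = c(t0, t1))
}

pspline_eval <- function(fit, tq, deriv = 0) {
  tq <- pmin(pmax(tq, fit$trange[1]), fit$trange[2])
  B <- splines::splineDesign(fit$knots, tq, ord = fit$ord,
                             derivs = rep(deriv, length(tq)))
  B %*% fit$coef
}

#' Full centerline extraction from a surface mesh
#'
#' Orchestrates voxelization, thinning, ordering, spline fitting and an
#' optional recentering pass in which the curve is refined through the
#' centroids of exact mesh cross-sections -- skeleton voxels carry
#' quantization noise of order h, while section centroids localize the
#' axis of a tubular vessel much more precisely.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param spacing voxel size h (mm).
#' @param smoothing spline tolerance (mm), default `spacing`.
#' @param ds arc-length resampling step (mm), default `spacing`.
#' @param recenter logical; run the section-centroid refinement pass.
#' @param end_trim_factor flagged end zone as a multiple of the local
#'   vessel radius (default 2).
#' @return A `centerline_curve`.
#' @export
vessel_centerline <- function(mesh, spacing = 0.25, smoothing = spacing,
                              ds = spacing, recenter = TRUE,
                              end_trim_factor = 2) {
  grid <- voxelize_mesh(mesh, spacing = spacing, fill = TRUE)
  pts <- skeletonize_and_order(grid)
  rad <- attr(pts, "radius")
  n <- length(rad)
  trim <- end_trim_factor * max(stats::median(rad[c(seq_len(min(10, n)),
                                                    seq(max(1, n - 9), n))]),
                                spacing)
  curve <- fit_centerline(pts, smoothing = smoothing, ds = ds, end_trim = trim)
  if (recenter) {
    # slicing frames come from a wide-knot (heavily smoothed) copy of the
    # curve: slice normals then cannot inherit the small-scale wiggles of
    # the detailed fit, so the centroid update does not feed noise back
    # into itself; two passes refine the heavy frames once
    input <- pts
    trim_i <- trim
    cen_ok <- NULL
    for (pass in 1:2) {
      heavy <- fit_centerline(input, smoothing = smoothing, ds = ds,
                              end_trim = trim_i, knot_spacing = 8)
      interior <- which(!heavy$flagged)
      cen <- matrix(NA_real_, length(interior), 3)
      for (i in seq_along(interior)) {
        sec <- try(slice_section(mesh, heavy, heavy$s[interior[i]]),
                   silent = TRUE)
        if (!inherits(sec, "try-error")) cen[i, ] <- sec$centroid3d
      }
      ok <- stats::complete.cases(cen)
      if (sum(ok) < 8) break
      cen_ok <- cen[ok, , drop = FALSE]
      input <- cen_ok
      trim_i <- 2 * ds
    }
    if (!is.null(cen_ok)) {
      curve <- fit_centerline(cen_ok, smoothing = spacing / 8, ds = ds,
                              end_trim = 2 * ds, method = "gcv")
      # final polish: one centroid pass with the detailed curve's own
      # frames, which are already accurate enough not to bias the slices
      interior <- which(curve$s >= 2 * ds &
                          curve$s <= curve$total_length - 2 * ds)
      cen <- matrix(NA_real_, length(interior), 3)
      for (i in seq_along(interior)) {
        sec <- try(slice_section(mesh, curve, curve$s[interior[i]]),
                   silent = TRUE)
        if (!inherits(sec, "try-error")) cen[i, ] <- sec$centroid3d
      }
      ok <- stats::complete.cases(cen)
      if (sum(ok) >= 8)
        curve <- fit_centerline(cen[ok, , drop = FALSE],
                                smoothing = spacing / 8, ds = ds,
                                end_trim = 2 * ds, method = "gcv")
    }
  }
  curve
}

#' Export a centerline as CSV (s, x, y, z, kappa, tau)
#' @param curve a `centerline_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_centerline <- function(curve, path) {
  df <- data.frame(s = curve$s, x = curve$points[, 1], y = curve$points[, 2],
                   z = curve$points[, 3], kappa = curve$kappa, tau = curve$tau)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
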