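#' Exact planar cross-section of a mesh at a centerline station
#'
#' Intersects the triangulated surface with the plane through the
#' centerline point `P(s)` with normal `T(s)`.  Intersection segments are
#' chained into closed loops; the connected component containing the
#' centerline point is returned as a simple polygon in the in-plane 2D
#' frame given by the curve's rotation-minimizing frame.
#'
#' @param mesh a `surface_mesh`.
#' @param curve a `centerline_curve`.
#' @param s station (mm) in the interior of the curve.
#' @return A `cross_section`: polygon `poly` (`k x 2`, counter-clockwise,
#'   mm), station `s`, in-plane frame (`origin`, `U`, `V`, `normal`),
#'   3D boundary points `poly3d` and the 3D region centroid `centroid3d`.
#' @export
slice_section <- function(mesh, curve, s) {
  fr <- frame_at(curve, s)
  sec <- slice_plane(mesh, fr$origin, fr$normal, fr$U, fr$V)
  sec$s <- s
  sec
}

frame_at <- function(curve, s) {
  if (is.null(curve$frame))
    stop("curve carries no rotation-minimizing frame")
  i <- which.min(abs(curve$s - s))
  geo <- frenet_at(curve, s)
  Tn <- geo$tangents[1, ]
  U <- curve$frame$U[i, ]
  U <- U - sum(U * Tn) * Tn
  U <- U / sqrt(sum(U^2))
  V <- c(Tn[2] * U[3] - Tn[3] * U[2],
         Tn[3] * U[1] - Tn[1] * U[3],
         Tn[1] * U[2] - Tn[2] * U[1])
  list(origin = geo$points[1, ], normal = Tn, U = U, V = V)
}

slice_plane <- function(mesh, origin, normal, U, V) {
  Vx <- mesh$vertices; Fc <- mesh$faces
  d <- as.vector((Vx - matrix(origin, nrow(Vx), 3, byrow = TRUE)) %*% normal)
  scale <- max(abs(d), 1)
  d[d == 0] <- 1e-12 * scale           # nudge coplanar vertices off the plane
  s1 <- d[Fc[, 1]]; s2 <- d[Fc[, 2]]; s3 <- d[Fc[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) stop("plane does not intersect the mesh")
  fidx <- which(crossing)
  # canonical edge intersection points, computed once per undirected edge
  edge_pts <- new.env(hash = TRUE)
  edge_point <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    p <- edge_pts[[key]]
    if (is.null(p)) {
      a <- min(i, j); b <- max(i, j)
      t <- d[a] / (d[a] - d[b])
      p <- Vx[a, ] + t * (Vx[b, ] - Vx[a, ])
      edge_pts[[key]] <- p
    }
    list(key = key, p = p)
  }
  seg_a <- character(0); seg_b <- character(0)
  pts <- list()
  for (f in fidx) {
    vi <- Fc[f, ]; dv <- d[vi]
    keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (dv[e[1]] * dv[e[2]] < 0) {
        ep <- edge_point(vi[e[1]], vi[e[2]])
        keys <- c(keys, ep$key)
        pts[[ep$key]] <- ep$p
      }
    }
    if (length(keys) == 2) { seg_a <- c(seg_a, keys[1]); seg_b <- c(seg_b, keys[2]) }
  }
  # chain segments into loops: each intersected edge joins exactly two faces
  nodes <- unique(c(seg_a, seg_b))
  adj <- new.env(hash = TRUE)
  addadj <- function(a, b) adj[[a]] <- c(adj[[a]], b)
  for (i in seq_along(seg_a)) { addadj(seg_a[i], seg_b[i]); addadj(seg_b[i], seg_a[i]) }
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (start in nodes) {
    if (!is.null(visited[[start]])) next
    loop <- character(0); cur <- start; prev <- NA_character_
    repeat {
      visited[[cur]] <- TRUE
      loop <- c(loop, cur)
      nxts <- setdiff(adj[[cur]], c(prev, NA))
      nxts <- nxts[is.null_safe(visited, nxts)]
      if (length(nxts) == 0) break
      prev <- cur; cur <- nxts[1]
    }
    if (length(loop) >= 3 && loop[1] %in% adj[[loop[length(loop)]]])
      loops[[length(loops) + 1]] <- loop
  }
  if (!length(loops)) stop("plane intersection produced no closed loop")
  # project to the in-plane frame and select the component containing P(s)
  for (loop in loops) {
    P3 <- do.call(rbind, lapply(loop, function(k) pts[[k]]))
    rel <- P3 - matrix(origin, nrow(P3), 3, byrow = TRUE)
    poly <- cbind(rel %*% U, rel %*% V)
    if (point_in_polygon(c(0, 0), poly)) {
      if (polygon_area_signed(poly) < 0) {
        poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
        P3 <- P3[rev(seq_len(nrow(P3))), , drop = FALSE]
      }
      cen2 <- polygon_centroid(poly)
      cen3 <- origin + cen2[1] * U + cen2[2] * V
      return(structure(list(poly = poly, poly3d = P3, origin = origin,
                            U = U, V = V, normal = normal,
                            centroid2d = cen2, centroid3d = cen3),
                       class = "cross_section"))
    }
  }
  stop("centerline point lies outside every intersection component")
}

is.null_safe <- function(env, keys) {
  vapply(keys, function(k) is.null(env[[k]]), logical(1))
}

# ---- polygon geometry ------------------------------------------------------

polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

polygon_perimeter <- function(poly) {
  dx <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(dx^2)))
}

point_in_polygon <- function(p, poly) {
  # even-odd ray crossing
  x <- poly[, 1] - p[1]; y <- poly[, 2] - p[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > 0) != (yn > 0)) & ((x * yn - xn * y) / (yn - y) > 0)
  sum(crosses, na.rm = TRUE) %% 2 == 1
}

polygon_second_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central moments
  list(A = A,
       mxx = Iyy / A - cx^2,   # variance in x
       myy = Ixx / A - cy^2,   # variance in y
       mxy = Ixy / A - cx * cy)
}

min_caliper_width <- function(hull) {
  # rotating calipers on a convex polygon: width = min over edges of the
  # maximum vertex distance to the edge's supporting line
  n <- nrow(hull)
  widths <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
    e <- b - a; len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    max(abs((hull[, 1] - a[1]) * nrm[1] + (hull[, 2] - a[2]) * nrm[2]))
  }, numeric(1))
  min(widths)
}

#' The eight cross-sectional shape indices of a planar region
#'
#' Computes, from a simple polygon: maximum diameter (largest pairwise
#' boundary distance), minimum diameter (minimum caliper width), equivalent
#' diameter `sqrt(4A/pi)`, area, eccentricity of the second-moment
#' equivalent ellipse `sqrt(1 - (b/a)^2)`, solidity (area over convex-hull
#' area) and extent (area over the axis-aligned bounding-box area in the
#' in-plane frame).  The eighth index, the area change rate dA/ds, is a
#' property of the sweep and is computed by [sweep_sequences()].
#'
#' @param section a `cross_section`, or a `k x 2` polygon matrix (mm).
#' @return Named list: `d_max`, `d_min`, `d_eq`, `area`, `eccentricity`,
#'   `solidity`, `extent` (plus `perimeter`).
#' @export
section_indices <- function(section) {
  poly <- if (inherits(section, "cross_section")) section$poly else as.matrix(section)
  if (nrow(poly) < 3) stop("degenerate polygon")
  A <- abs(polygon_area_signed(poly))
  if (A <= 0) stop("degenerate polygon with zero area")
  hidx <- grDevices::chull(poly)
  hull <- poly[hidx, , drop = FALSE]
  dh <- as.matrix(stats::dist(hull))
  d_max <- max(dh)
  d_min <- min_caliper_width(hull)
  hullA <- abs(polygon_area_signed(hull))
  m <- polygon_second_moments(poly)
  ev <- eigen(matrix(c(m$mxx, m$mxy, m$mxy, m$myy), 2, 2),
              symmetric = TRUE, only.values = TRUE)$values
  lam1 <- max(ev); lam2 <- max(min(ev), 0)
  ecc <- if (lam1 <= 0) 0 else sqrt(max(0, 1 - lam2 / lam1))
  bbox <- apply(poly, 2, range)
  bba <- (bbox[2, 1] - bbox[1, 1]) * (bbox[2, 2] - bbox[1, 2])
  list(d_max = d_max, d_min = d_min, d_eq = sqrt(4 * A / pi), area = A,
       eccentricity = ecc, solidity = min(A / hullA, 1),
       extent = min(A / bba, 1), perimeter = polygon_perimeter(poly))
}

#' Sweep cross-sections along the centerline: the ten geometry sequences
#'
#' Slices the mesh at every centerline station and assembles the ten
#' per-station sequences on the common arc-length grid: curvature,
#' torsion, and the eight cross-sectional indices (the area change rate
#' dA/ds by central differences, one-sided at run boundaries).  Stations
#' inside the flagged end zones are excluded from downstream use.
#'
#' @param mesh a `surface_mesh`.
#' @param curve a `centerline_curve`.
#' @param stations stations to use (mm); default the curve's grid.
#' @return A `geometry_sequences`: `s`, logical `flagged`, matrix `seq`
#'   (stations x 10 named sequences), per-station `centroid_offset` (mm),
#'   `perimeter` (mm) and 3D boundary polygons `poly3d`.
#' @export
sweep_sequences <- function(mesh, curve, stations = curve$s) {
  ns <- length(stations)
  flagged <- if (!is.null(curve$flagged) && identical(stations, curve$s))
    curve$flagged else rep(FALSE, ns)
  cols <- c("curvature", "torsion", "d_max", "d_min", "d_eq", "area",
            "area_rate", "eccentricity", "solidity", "extent")
  M <- matrix(NA_real_, ns, length(cols), dimnames = list(NULL, cols))
  centroid_offset <- rep(NA_real_, ns)
  perim <- rep(NA_real_, ns)
  poly3d <- vector("list", ns)
  geo <- frenet_at(curve, stations)
  M[, "curvature"] <- geo$kappa
  M[, "torsion"] <- geo$tau
  failed <- integer(0)
  for (i in seq_len(ns)) {
    sec <- try(slice_section(mesh, curve, stations[i]), silent = TRUE)
    if (inherits(sec, "try-error")) { failed <- c(failed, i); next }
    idx <- section_indices(sec)
    M[i, c("d_max", "d_min", "d_eq", "area", "eccentricity", "solidity",
           "extent")] <-
      c(idx$d_max, idx$d_min, idx$d_eq, idx$area, idx$eccentricity,
        idx$solidity, idx$extent)
    centroid_offset[i] <- sqrt(sum(sec$centroid2d^2))
    perim[i] <- idx$perimeter
    poly3d[[i]] <- sec$poly3d
  }
  hard_fail <- setdiff(failed, which(flagged))
  if (length(hard_fail) > 0.05 * max(1, sum(!flagged)))
    stop(sprintf("slicing failed at %d of %d interior stations (s = %s ...)",
                 length(hard_fail), sum(!flagged),
                 paste(round(stations[utils::head(hard_fail, 5)], 2),
                       collapse = ", ")))
  flagged[failed] <- TRUE
  # dA/ds on contiguous valid runs
  valid <- !is.na(M[, "area"])
  M[valid, "area_rate"] <- run_gradient(stations, M[, "area"], valid)
  structure(list(s = stations, flagged = flagged, seq = M,
                 centroid_offset = centroid_offset, perimeter = perim,
                 poly3d = poly3d),
            class = "geometry_sequences")
}

run_gradient <- function(s, y, valid) {
  idx <- which(valid)
  out <- numeric(0)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  for (r in runs) {
    n <- length(r)
    g <- rep(NA_real_, n)
    if (n >= 2) {
      g[1] <- (y[r[2]] - y[r[1]]) / (s[r[2]] - s[r[1]])
      g[n] <- (y[r[n]] - y[r[n - 1]]) / (s[r[n]] - s[r[n - 1]])
      if (n > 2) {
        mid <- 2:(n - 1)
        g[mid] <- (y[r[mid + 1]] - y[r[mid - 1]]) / (s[r[mid + 1]] - s[r[mid - 1]])
      }
    } else g[1] <- 0
    out <- c(out, g)
  }
  out
}

#' @export
print.geometry_sequences <- function(x, ...) {
  cat(sprintf("geometry_sequences: %d stations over %.1f mm (%d flagged)\n",
              length(x$s), diff(range(x$s)), sum(x$flagged)))
  invisible(x)
}

#' Export geometry sequences as CSV (one row per station)
#' @param seqs a `geometry_sequences`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_sequences <- function(seqs, path) {
  df <- data.frame(s = seqs$s, seqs$seq, flagged = seqs$flagged,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
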