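SEGMENT_NAMES <- c("aneurysm", "aneurysm_proximal_half", "aneurysm_distal_half",
                   "first_proximal", "second_proximal",
                   "first_distal", "second_distal")
SEQUENCE_NAMES <- c("curvature", "torsion", "d_max", "d_min", "d_eq", "area",
                    "area_rate", "eccentricity", "solidity", "extent")
STATISTIC_NAMES <- c("max", "mean", "sd", "integral", "variation")
RATIO_PAIRS <- list(c("aneurysm_proximal_half", "aneurysm_distal_half"),
                    c("aneurysm", "first_proximal"),
                    c("aneurysm", "first_distal"),
                    c("first_proximal", "first_distal"))
GLOBAL_NAMES <- c("length", "width", "width_length_ratio",
                  "neck_tangent_angle", "neck_tangent_distance",
                  "asymmetry_factor", "aneurysm_volume",
                  "aneurysm_surface_area", "hull_volume", "solidity_3d",
                  "bulge_ratio_proximal", "bulge_ratio_distal",
                  "max_area_location", "curvature_integral",
                  "abs_torsion_integral", "chord_deviation_mean",
                  "chord_deviation_max", "tortuosity_aneurysm",
                  "tortuosity_span", "neck_d_eq_proximal", "neck_d_eq_distal")

#' Canonical names of the 571 geometric features
#'
#' The feature schema is fixed and versioned: 7 segments x 10 sequences x
#' 5 statistics = 350 per-segment features named
#' `<segment>.<sequence>.<statistic>`; 4 segment pairs x 10 x 5 = 200
#' ratio features named `ratio.<segA>-<segB>.<sequence>.<statistic>`; and
#' 21 whole-lesion features named `global.<name>`.
#'
#' @return Character vector of length 571, in canonical order.
#' @export
feature_names <- function() {
  seg <- as.vector(t(outer(SEGMENT_NAMES,
                           as.vector(t(outer(SEQUENCE_NAMES, STATISTIC_NAMES,
                                             paste, sep = "."))),
                           paste, sep = ".")))
  rat <- unlist(lapply(RATIO_PAIRS, function(p)
    paste0("ratio.", p[1], "-", p[2], ".",
           as.vector(t(outer(SEQUENCE_NAMES, STATISTIC_NAMES, paste,
                             sep = "."))))))
  glob <- paste0("global.", GLOBAL_NAMES)
  out <- c(seg, rat, glob)
  stopifnot(length(out) == 571, !anyDuplicated(out))
  out
}

#' Detect the aneurysm extent and lay out the seven feature segments
#'
#' The aneurysm is the longest contiguous run of stations whose
#' cross-sectional area exceeds `threshold_factor` times a reference area
#' `A_ref`, the median area over a proximal reference window.  The run
#' boundaries (the necks) are refined by linear interpolation of the
#' threshold crossing; the aneurysm length `L` is the run length, and two
#' proximal and two distal segments of length `L` are tiled outward from
#' the necks (the aneurysm itself is additionally split into proximal and
#' distal halves).
#'
#' @param seqs a `geometry_sequences`.
#' @param threshold_factor bulge detection factor (default 1.5).
#' @param ref_frac fraction of the interior stations, from the proximal
#'   end, used as the reference window (default 0.15, at least 5
#'   stations).
#' @return A `segment_layout`: `L` (mm), neck stations `s_proximal`,
#'   `s_distal`, a named list `segments` of `[start, end)` intervals and a
#'   logical `truncated` flag per segment.
#' @export
detect_aneurysm <- function(seqs, threshold_factor = 1.5, ref_frac = 0.15) {
  ok <- !seqs$flagged & !is.na(seqs$seq[, "area"])
  s <- seqs$s[ok]; A <- seqs$seq[ok, "area"]
  if (length(s) < 10) stop("too few valid stations for aneurysm detection")
  nref <- max(5L, ceiling(ref_frac * length(s)))
  A_ref <- stats::median(A[seq_len(nref)])
  thr <- threshold_factor * A_ref
  above <- A > thr
  if (!any(above)) stop("no aneurysm: no station exceeds the area threshold")
  runs <- split(which(above), cumsum(c(1, diff(which(above)) != 1)))
  rl <- vapply(runs, function(r) s[r[length(r)]] - s[r[1]], numeric(1))
  run <- runs[[which.max(rl)]]
  i0 <- run[1]; i1 <- run[length(run)]
  truncated_run <- FALSE
  s_p <- if (i0 > 1)
    s[i0 - 1] + (thr - A[i0 - 1]) / (A[i0] - A[i0 - 1]) * (s[i0] - s[i0 - 1])
  else { truncated_run <- TRUE; s[1] }
  s_d <- if (i1 < length(s))
    s[i1] + (thr - A[i1]) / (A[i1 + 1] - A[i1]) * (s[i1 + 1] - s[i1])
  else { truncated_run <- TRUE; s[length(s)] }
  if (truncated_run)
    warning("aneurysm run touches the end of the analyzed vessel; layout truncated")
  L <- s_d - s_p
  segs <- list(
    aneurysm = c(s_p, s_d),
    aneurysm_proximal_half = c(s_p, s_p + L / 2),
    aneurysm_distal_half = c(s_p + L / 2, s_d),
    first_proximal = c(s_p - L, s_p),
    second_proximal = c(s_p - 2 * L, s_p - L),
    first_distal = c(s_d, s_d + L),
    second_distal = c(s_d + L, s_d + 2 * L))
  lo <- s[1]; hi <- s[length(s)]
  truncated <- vapply(segs, function(iv) iv[1] < lo - 1e-9 | iv[2] > hi + 1e-9,
                      logical(1))
  structure(list(L = L, s_proximal = s_p, s_distal = s_d, A_ref = A_ref,
                 threshold_factor = threshold_factor, segments = segs,
                 truncated = truncated),
            class = "segment_layout")
}

#' @export
print.segment_layout <- function(x, ...) {
  cat(sprintf("segment_layout: L = %.2f mm, necks at %.2f / %.2f mm (A_ref = %.2f mm^2, factor %.2g)\n",
              x$L, x$s_proximal, x$s_distal, x$A_ref, x$threshold_factor))
  if (any(x$truncated))
    cat("  truncated:", paste(names(which(x$truncated)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-segment statistics of the ten geometry sequences (350 features)
#'
#' For each of the seven segments and each of the ten sequences computes
#' five statistics: maximum, mean, standard deviation, integral (trapezoid
#' over arc length, so e.g. "total solidity" carries mm and "total maximum
#' diameter" carries mm^2) and variation (total variation, the summed
#' absolute successive differences).  Segments with fewer than two valid
#' stations yield missing values, which are imputed downstream.
#'
#' @param seqs a `geometry_sequences`.
#' @param layout a `segment_layout`.
#' @return Named numeric vector of 350 features.
#' @export
segment_statistics <- function(seqs, layout) {
  out <- numeric(0)
  for (seg in SEGMENT_NAMES) {
    iv <- layout$segments[[seg]]
    sel <- which(seqs$s >= iv[1] - 1e-9 & seqs$s <= iv[2] + 1e-9 &
                   !seqs$flagged)
    for (sq in SEQUENCE_NAMES) {
      x <- seqs$seq[sel, sq]
      s <- seqs$s[sel]
      keep <- !is.na(x)
      x <- x[keep]; s <- s[keep]
      vals <- if (length(x) >= 2) {
        c(max(x), mean(x), stats::sd(x),
          sum(diff(s) * (x[-1] + x[-length(x)]) / 2),
          sum(abs(diff(x))))
      } else rep(NA_real_, 5)
      names(vals) <- paste(seg, sq, STATISTIC_NAMES, sep = ".")
      out <- c(out, vals)
    }
  }
  out
}

#' Ratio features between segments (200 features)
#'
#' Plain quotients of the per-segment statistics for four segment pairs:
#' aneurysm proximal half / distal half, aneurysm / first proximal,
#' aneurysm / first distal, and first proximal / first distal.
#' Near-zero denominators (|x| < 1e-9) yield missing values rather than
#' infinities.
#'
#' @param stats350 the output of [segment_statistics()].
#' @return Named numeric vector of 200 features.
#' @export
ratio_features <- function(stats350) {
  out <- numeric(0)
  for (p in RATIO_PAIRS) {
    for (sq in SEQUENCE_NAMES) {
      num <- stats350[paste(p[1], sq, STATISTIC_NAMES, sep = ".")]
      den <- stats350[paste(p[2], sq, STATISTIC_NAMES, sep = ".")]
      val <- ifelse(is.na(num) | is.na(den) | abs(den) < 1e-9, NA_real_,
                    num / den)
      names(val) <- paste0("ratio.", p[1], "-", p[2], ".", sq, ".",
                           STATISTIC_NAMES)
      out <- c(out, val)
    }
  }
  out
}

#' Whole-lesion global features (21 features)
#'
#' Size and shape descriptors of the detected aneurysm: length L and width
#' W (the largest maximum diameter over the aneurysm), the width--length
#' ratio, the angle and chord distance between the centerline tangent
#' vectors at the two necks, the asymmetry factor (largest in-plane
#' centroid offset from the centerline, normalized by the equivalent
#' diameter), aneurysm volume (integral of A over s), lateral surface
#' area (integral of the section perimeter), convex-hull volume of the
#' aneurysm boundary and the resulting 3D solidity, bulge ratios W/d_eq at
#' each neck, the normalized arc position of the area maximum, integrals
#' of curvature and |torsion| over the aneurysm, centerline deviation from
#' the neck-to-neck chord (mean and max), tortuosity (arc over chord) of
#' the aneurysm and of the full five-segment span, and d_eq at each neck.
#'
#' @param mesh a `surface_mesh` (currently unused beyond provenance;
#'   surface quantities come from the swept sections).
#' @param curve a `centerline_curve`.
#' @param seqs a `geometry_sequences`.
#' @param layout a `segment_layout`.
#' @return Named numeric vector of 21 features.
#' @export
global_features <- function(mesh, curve, seqs, layout) {
  s_p <- layout$s_proximal; s_d <- layout$s_distal; L <- layout$L
  an <- which(seqs$s >= s_p - 1e-9 & seqs$s < s_d - 1e-9 & !seqs$flagged &
                !is.na(seqs$seq[, "area"]))
  if (length(an) < 2) stop("aneurysm segment has too few valid stations")
  s <- seqs$s[an]
  A <- seqs$seq[an, "area"]
  W <- max(seqs$seq[an, "d_max"], na.rm = TRUE)
  geo_p <- frenet_at(curve, s_p); geo_d <- frenet_at(curve, s_d)
  cosang <- sum(geo_p$tangents[1, ] * geo_d$tangents[1, ])
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  chordv <- geo_d$points[1, ] - geo_p$points[1, ]
  chord <- sqrt(sum(chordv^2))
  asym <- max(seqs$centroid_offset[an] / seqs$seq[an, "d_eq"], na.rm = TRUE)
  vol <- trapz(s, A)
  surf <- trapz(s, seqs$perimeter[an])
  bpts <- do.call(rbind, seqs$poly3d[an])
  hullvol <- hull3d_volume(bpts)
  deq_interp <- stats::approxfun(seqs$s[!is.na(seqs$seq[, "d_eq"])],
                                 seqs$seq[!is.na(seqs$seq[, "d_eq"]), "d_eq"],
                                 rule = 2)
  kap <- seqs$seq[an, "curvature"]; tau <- seqs$seq[an, "torsion"]
  # deviation of the centerline from the neck-to-neck chord
  pts <- centerline_eval(curve, s)
  u <- chordv / max(chord, 1e-12)
  rel <- pts - matrix(geo_p$points[1, ], nrow(pts), 3, byrow = TRUE)
  proj <- rel %*% u
  dev <- sqrt(pmax(rowSums(rel^2) - proj^2, 0))
  arc_an <- s_d - s_p
  span_lo <- max(min(seqs$s[!seqs$flagged]), s_p - 2 * L)
  span_hi <- min(max(seqs$s[!seqs$flagged]), s_d + 2 * L)
  pspan <- centerline_eval(curve, c(span_lo, span_hi))
  span_chord <- sqrt(sum((pspan[2, ] - pspan[1, ])^2))
  out <- c(L, W, W / L, angle, chord, asym, vol, surf, hullvol,
           min(vol / hullvol, 1), W / deq_interp(s_p), W / deq_interp(s_d),
           (s[which.max(A)] - s_p) / L, trapz(s, kap), trapz(s, abs(tau)),
           mean(dev), max(dev), arc_an / max(chord, 1e-12),
           (span_hi - span_lo) / max(span_chord, 1e-12),
           deq_interp(s_p), deq_interp(s_d))
  names(out) <- paste0("global.", GLOBAL_NAMES)
  out
}

trapz <- function(x, y) {
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) return(NA_real_)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Assemble the full 571-element feature vector
#'
#' Concatenates the 350 per-segment statistics, the 200 ratio features and
#' the 21 global features, in the canonical [feature_names()] order.  The
#' total count of 571 uniquely named features is a hard contract: any
#' other count is an assembly error.
#'
#' @param stats350,ratios200,globals21 the three feature blocks.
#' @return Named numeric vector of exactly 571 features.
#' @export
assemble_features <- function(stats350, ratios200, globals21) {
  out <- c(stats350, ratios200, globals21)
  expected <- feature_names()
  if (length(out) != 571 || !identical(names(out), expected))
    stop("feature assembly error: expected 571 canonically named features")
  out
}

#' Full per-case feature extraction from a surface mesh
#'
#' Runs the complete pipeline for one case: voxelization, centerline
#' extraction, Frenet-Serret analysis, cross-section sweep, aneurysm
#' detection, and assembly of the named 571-element feature vector.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param spacing voxel size h (mm), default 0.25.
#' @param threshold_factor aneurysm detection factor, see
#'   [detect_aneurysm()].
#' @param ... further arguments to [vessel_centerline()].
#' @return Named numeric vector of 571 features, with the
#'   `segment_layout`, `geometry_sequences` and `centerline_curve`
#'   attached as attributes `"layout"`, `"sequences"` and `"curve"`.
#' @export
case_features <- function(mesh, spacing = 0.25, threshold_factor = 1.5, ...) {
  curve <- vessel_centerline(mesh, spacing = spacing, ...)
  seqs <- sweep_sequences(mesh, curve)
  layout <- detect_aneurysm(seqs, threshold_factor = threshold_factor)
  st <- segment_statistics(seqs, layout)
  rt <- ratio_features(st)
  gl <- global_features(mesh, curve, seqs, layout)
  fv <- assemble_features(st, rt, gl)
  attr(fv, "layout") <- layout
  attr(fv, "sequences") <- seqs
  attr(fv, "curve") <- curve
  fv
}

# ---- 3D convex hull volume (incremental) ----------------------------------

#' Volume of the 3D convex hull of a point set
#'
#' Incremental convex-hull construction with visibility horizons; used for
#' the whole-lesion 3D solidity feature.
#'
#' @param P `n x 3` matrix of points.
#' @return Hull volume (mm^3).
#' @export
hull3d_volume <- function(P) {
  P <- unique(as.matrix(P))
  n <- nrow(P)
  if (n < 4) return(0)
  # deterministic quasi-random insertion order: structured inputs (stacked
  # section rings) otherwise hit degenerate horizon configurations
  P <- P[order((seq_len(n) * 0.6180339887498949) %% 1), , drop = FALSE]
  scale <- max(apply(P, 2, function(x) diff(range(x))))
  eps <- 1e-9 * scale
  # initial tetrahedron from extreme points
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) return(0)
  e <- P[i2, ] - P[i1, ]
  d2 <- rowSums((P - matrix(P[i1, ], n, 3, byrow = TRUE))^2) -
    ((P - matrix(P[i1, ], n, 3, byrow = TRUE)) %*% e)^2 / sum(e^2)
  i3 <- which.max(d2)
  nrm <- cross3(matrix(P[i2, ] - P[i1, ], 1), matrix(P[i3, ] - P[i1, ], 1))[1, ]
  h <- abs((P - matrix(P[i1, ], n, 3, byrow = TRUE)) %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < eps * sqrt(sum(nrm^2))) return(0)   # coplanar set
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  c0 <- colMeans(P[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nn <- cross3(matrix(P[f[2], ] - P[f[1], ], 1),
                 matrix(P[f[3], ] - P[f[1], ], 1))[1, ]
    if (sum(nn * (P[f[1], ] - c0)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  normals_offsets <- function(faces) {
    nn <- cross3(P[faces[, 2], , drop = FALSE] - P[faces[, 1], , drop = FALSE],
                 P[faces[, 3], , drop = FALSE] - P[faces[, 1], , drop = FALSE])
    len <- sqrt(rowSums(nn^2)); len[len == 0] <- 1
    nn <- nn / len
    list(N = nn, d = rowSums(nn * P[faces[, 1], , drop = FALSE]))
  }
  no <- normals_offsets(faces)
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- which(no$N %*% P[p, ] - no$d > eps)
    if (!length(vis)) next
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, 1:2], visf[, 2:3], visf[, c(3, 1)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ek %in% names(which(table(ek) == 1)), , drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient))
    faces <- rbind(faces, newf)
    no <- normals_offsets(faces)
  }
  # self-check: every input point must lie inside (or on) the final hull
  no <- normals_offsets(faces)
  viol <- max(P %*% t(no$N) - matrix(no$d, n, nrow(faces), byrow = TRUE))
  if (viol > 1e-5 * scale)
    warning(sprintf("convex hull containment violated by %.2g; volume may be off", viol))
  a <- P[faces[, 1], , drop = FALSE]
  b <- P[faces[, 2], , drop = FALSE]
  cc <- P[faces[, 3], , drop = FALSE]
  am <- a - matrix(c0, nrow(a), 3, byrow = TRUE)
  bm <- b - matrix(c0, nrow(a), 3, byrow = TRUE)
  cm <- cc - matrix(c0, nrow(a), 3, byrow = TRUE)
  abs(sum(rowSums(am * cross3(bm, cm))) / 6)
}
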