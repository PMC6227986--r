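# Shared fixtures.  The expensive full-pipeline runs (voxelize + thin +
# fit + sweep at h = 0.25 mm) are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# lat-long sphere mesh (poles as triangle fans), watertight
sphere_mesh <- function(radius = 5, n_theta = 48, n_phi = 96) {
  th <- seq(0, pi, length.out = n_theta + 2)[2:(n_theta + 1)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(ph = ph, th = th)
  v <- cbind(radius * sin(grid$th) * cos(grid$ph),
             radius * sin(grid$th) * sin(grid$ph),
             radius * cos(grid$th))
  np <- nrow(v)
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  faces <- list()
  for (i in seq_len(n_theta - 1)) {
    j <- seq_len(n_phi)
    a <- idx(i, j); b <- idx(i + 1, j); c_ <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    faces[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  j <- seq_len(n_phi)
  faces[[n_theta]] <- cbind(np + 1, idx(1, j), idx(1, j + 1))        # north
  faces[[n_theta + 1]] <- cbind(np + 2, idx(n_theta, j + 1), idx(n_theta, j))
  surface_mesh(v, do.call(rbind, faces))
}

# unit-testable cube mesh [0, side]^3
cube_mesh <- function(side = 10) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# a voxel_grid built directly from voxel index coordinates (for synthetic
# skeleton inputs)
grid_from_indices <- function(idx, dims, spacing = 0.5, origin = c(0, 0, 0)) {
  occ <- array(FALSE, dim = dims)
  occ[idx] <- TRUE
  structure(list(occupancy = occ, origin = origin, spacing = spacing,
                 dims = as.integer(dims)),
            class = "voxel_grid")
}

phantom_mesh_025 <- function() fixture("phantom_mesh", function() fusiform_phantom())

phantom_features_025 <- function() {
  fixture("phantom_features", function()
    suppressWarnings(case_features(phantom_mesh_025(), spacing = 0.25)))
}

arc_centerline_025 <- function() {
  fixture("arc_centerline", function() {
    crv <- analytic_centerline("arc", length = 25, radius = 10)
    m <- tube_mesh(crv, radius_profile(r0 = 2), angular_res = 64,
                   axial_res = 150)
    vessel_centerline(m, spacing = 0.25)
  })
}

helix_centerline_025 <- function() {
  fixture("helix_centerline", function() {
    crv <- analytic_centerline("helix", length = 40, a = 3, b = 1)
    m <- tube_mesh(crv, radius_profile(r0 = 1.5), angular_res = 64,
                   axial_res = 200)
    vessel_centerline(m, spacing = 0.25)
  })
}

# geometry_sequences built directly from an analytic radius profile (no
# mesh in the loop): area = pi r(s)^2, the remaining sequences filled with
# simple consistent values
analytic_sequences <- function(r_fun, s = seq(0, 40, by = 0.25)) {
  r <- r_fun(s)
  cols <- c("curvature", "torsion", "d_max", "d_min", "d_eq", "area",
            "area_rate", "eccentricity", "solidity", "extent")
  M <- matrix(0, length(s), length(cols), dimnames = list(NULL, cols))
  M[, "d_max"] <- M[, "d_min"] <- M[, "d_eq"] <- 2 * r
  M[, "area"] <- pi * r^2
  M[, "area_rate"] <- c(0, diff(pi * r^2) / diff(s))
  M[, "solidity"] <- 1
  M[, "extent"] <- pi / 4
  structure(list(s = s, flagged = rep(FALSE, length(s)), seq = M,
                 centroid_offset = rep(0, length(s)),
                 perimeter = 2 * pi * r,
                 poly3d = vector("list", length(s))),
            class = "geometry_sequences")
}

gauss_bulge_r <- function(s, r0 = 2, amp = 2, center = 20, w2 = 18) {
  r0 + amp * exp(-(s - center)^2 / w2)
}

# closed-form aneurysm length of the Gaussian-bulge profile at factor 1.5:
# A/A_ref > 1.5  <=>  |s - center| < sqrt(w2 * log(amp / (r0 sqrt(1.5) - r0)))
gauss_bulge_L <- function(r0 = 2, amp = 2, w2 = 18, factor = 1.5) {
  2 * sqrt(w2 * log(amp / (r0 * (sqrt(factor) - 1))))
}
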