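# Shared fixtures: all built in code, no binary files.

# Canonical landmark set used in the worked geometry examples: IVC along the
# z-axis from (0,0,0) to (0,0,100).
canonical_landmarks <- function() {
  landmark_set(list(
    ivc_superior        = c(0, 0, 100),
    ivc_inferior        = c(0, 0, 0),
    middle_hepatic_vein = c(0, 10, 90),
    gallbladder_fossa   = c(0, 50, 10),
    right_hepatic_vein  = c(40, 10, 80),
    umbilical_fissure   = c(-25, 55, 15),
    right_portal_vein   = c(30, 20, 45),
    left_portal_vein    = c(-20, 15, 50)))
}

canonical_planes <- function(caudate_radius_mm = 30) {
  build_planes(canonical_landmarks(), caudate_radius_mm)
}

# Small randomized phantom spec (~20-30 voxels a side) with jittered
# landmarks and a perturbed surface; everything seeded.
small_spec <- function(seed) {
  ax <- withr_seed(seed, stats::runif(3, 8, 14))
  phantom_spec(semi_axes_mm = ax,
               center_mm = c(0, ax[2] / 3, ax[3] * 2 / 3),
               voxel_size_mm = c(1, 1, 1),
               margin_mm = 2,
               perturb_amplitude = 0.08,
               landmark_jitter_mm = 1,
               seed = seed)
}

# local-seed evaluation without touching the caller's RNG stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Random rigid transform (rotation with det +1, translation), seeded.
random_rigid <- function(seed) {
  withr_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(R = Q, t = stats::runif(3, -50, 50))
  })
}

apply_rigid_landmarks <- function(lms, rig) {
  pts <- lapply(landmark_names_fixture(), function(nm)
    as.numeric(rig$R %*% lms[[nm]] + rig$t))
  landmark_set(stats::setNames(pts, landmark_names_fixture()))
}

landmark_names_fixture <- function() {
  c("ivc_superior", "ivc_inferior", "middle_hepatic_vein", "gallbladder_fossa",
    "right_hepatic_vein", "umbilical_fissure", "right_portal_vein",
    "left_portal_vein")
}

apply_rigid_affine <- function(affine, rig) {
  T4 <- diag(4)
  T4[1:3, 1:3] <- rig$R
  T4[1:3, 4] <- rig$t
  T4 %*% affine
}

# Independent brute-force oracle for fit_axis_plane: sum of squared
# point-plane distances over a theta grid of normals orthogonal to the axis.
theta_grid_objective <- function(axis, targets, thetas) {
  d <- axis$direction / sqrt(sum(axis$direction^2))
  # any vector not parallel to d
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- a - sum(a * d) * d; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(d[2] * u1[3] - d[3] * u1[2],
          d[3] * u1[1] - d[1] * u1[3],
          d[1] * u1[2] - d[2] * u1[1])
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3, byrow = TRUE)
  off <- sweep(targets, 2, axis$point)
  vapply(thetas, function(th) {
    n <- cos(th) * u1 + sin(th) * u2
    sum((off %*% n)^2)
  }, numeric(1))
}

plane_objective <- function(plane, axis, targets) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3, byrow = TRUE)
  sum(signed_distance(plane, targets)^2)
}
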