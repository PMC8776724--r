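#' Synthetic liver phantom specification
#'
#' The phantom is a voxelized ellipsoid (optionally with a smooth, seeded
#' radial perturbation) with canonically placed anatomical landmarks and
#' per-segment constant quantitative-map values plus Gaussian noise. It is
#' geometric rather than anatomically realistic: its purpose is known ground
#' truth for every downstream computation, not visual realism.
#'
#' Defaults: semi-axes (90, 60, 75) mm — an adult-liver-scale ellipsoid of
#' about 1.7 L; voxel size (1.2, 1.2, 3.0) mm, the typical reconstructed
#' resolution of the 3D T1-weighted volume; cT1 map noise SD 50 ms and PDFF
#' noise SD 1 percentage point.
#'
#' @param semi_axes_mm ellipsoid semi-axes (a, b, c), mm.
#' @param center_mm ellipsoid center in world mm (RAS).
#' @param voxel_size_mm grid spacing, mm.
#' @param margin_mm empty border around the ellipsoid, mm.
#' @param perturb_amplitude relative amplitude of the smooth radial
#'   perturbation (0 = exact ellipsoid).
#' @param landmark_jitter_mm SD of seeded Gaussian jitter added to each
#'   canonical landmark (0 = exact canonical placement).
#' @param seed integer seed controlling every random element.
#' @param map_values named per-segment constants for each modality.
#' @param map_noise_sd named noise SDs (cT1 in ms, PDFF in percentage points).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(semi_axes_mm = c(90, 60, 75),
                         center_mm = c(0, 20, 50),
                         voxel_size_mm = c(1.2, 1.2, 3.0),
                         margin_mm = 6,
                         perturb_amplitude = 0,
                         landmark_jitter_mm = 0,
                         seed = 1,
                         map_values = NULL,
                         map_noise_sd = c(cT1 = 50, PDFF = 1)) {
  if (any(semi_axes_mm <= 0)) cn_stop("semi-axes must be positive",
                                      "couinaud_bad_spec")
  if (any(voxel_size_mm <= 0)) cn_stop("voxel sizes must be positive",
                                       "couinaud_bad_spec")
  if (is.null(map_values))
    map_values <- list(
      cT1 = stats::setNames(seq(750, 990, by = 30), segment_names()),
      PDFF = stats::setNames(seq(2, 10, by = 1), segment_names()))
  structure(list(semi_axes_mm = as.numeric(semi_axes_mm),
                 center_mm = as.numeric(center_mm),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 margin_mm = margin_mm,
                 perturb_amplitude = perturb_amplitude,
                 landmark_jitter_mm = landmark_jitter_mm,
                 seed = as.integer(seed),
                 map_values = map_values,
                 map_noise_sd = map_noise_sd),
            class = "phantom_spec")
}

# Run expr with a local RNG state; never disturbs the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

phantom_affine <- function(spec) {
  # Half-voxel lattice offset: the canonical landmarks sit at round world
  # coordinates, so without it entire decision planes would coincide with
  # voxel-center lattice planes and the tie rule would bias whole boundary
  # slabs to one side.
  origin <- spec$center_mm - spec$semi_axes_mm - spec$margin_mm +
    spec$voxel_size_mm / 2
  A <- diag(4)
  A[1:3, 1:3] <- diag(spec$voxel_size_mm)
  A[1:3, 4] <- origin
  A
}

phantom_dims <- function(spec) {
  as.integer(ceiling(2 * (spec$semi_axes_mm + spec$margin_mm) / spec$voxel_size_mm)) + 1L
}

# Smooth direction-dependent radial perturbation; coefficients are a pure
# function of the seed so mask and supersampled truth see the same surface.
perturb_coeffs <- function(spec) {
  with_seed(spec$seed * 7 + 3,
            list(c = stats::rnorm(3), p = stats::runif(2, 0, 2 * pi)))
}

ellipsoid_inside <- function(spec, x, y, z, coef) {
  dx <- (x - spec$center_mm[1]) / spec$semi_axes_mm[1]
  dy <- (y - spec$center_mm[2]) / spec$semi_axes_mm[2]
  dz <- (z - spec$center_mm[3]) / spec$semi_axes_mm[3]
  r2 <- dx * dx + dy * dy + dz * dz
  if (spec$perturb_amplitude == 0) return(r2 <= 1)
  r <- sqrt(pmax(r2, 1e-12))
  az <- atan2(dy, dx)
  ct <- dz / r
  st <- sqrt(pmax(1 - ct * ct, 0))
  g <- coef$c[1] * sin(az + coef$p[1]) * st +
       coef$c[2] * sin(2 * az + coef$p[2]) * st * st +
       coef$c[3] * ct
  R <- 1 + spec$perturb_amplitude * g / max(1e-9, max(abs(coef$c)) * 1.5)
  r2 <= R * R
}

#' Generate the phantom liver mask
#'
#' Voxelizes the (optionally perturbed) ellipsoid by voxel-center inclusion
#' on the spec grid. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return a [liver_mask()].
#' @export
make_phantom_mask <- function(spec) {
  dims <- phantom_dims(spec)
  A <- phantom_affine(spec)
  coef <- perturb_coeffs(spec)
  xs <- A[1, 4] + (seq_len(dims[1]) - 1) * A[1, 1]
  ys <- A[2, 4] + (seq_len(dims[2]) - 1) * A[2, 2]
  zs <- A[3, 4] + (seq_len(dims[3]) - 1) * A[3, 3]
  grid <- array(0L, dim = dims)
  for (k in seq_len(dims[3])) {
    inside <- ellipsoid_inside(spec,
                               matrix(xs, dims[1], dims[2]),
                               matrix(ys, dims[1], dims[2], byrow = TRUE),
                               zs[k], coef)
    grid[, , k] <- as.integer(inside)
  }
  liver_mask(grid, A)
}

# Canonical landmark offsets in mm, relative to the canonical center
# (0, 20, 50) and canonical semi-axes (90, 60, 75); scaled to the spec's
# geometry. IVC runs along the posterior-midline vertical chord; MHV and
# gallbladder fossa sit near the midplane superiorly/inferiorly; RHV
# right-posterior-superior; umbilical fissure left-anterior-inferior; portal
# branch points at mid-height.
canonical_offsets <- function() {
  rbind(ivc_superior        = c(0, -20, 50),
        ivc_inferior        = c(0, -20, -50),
        middle_hepatic_vein = c(0, -10, 40),
        gallbladder_fossa   = c(0, 30, -40),
        right_hepatic_vein  = c(40, -10, 30),
        umbilical_fissure   = c(-25, 35, -35),
        right_portal_vein   = c(30, 0, -5),
        left_portal_vein    = c(-20, -5, 0))
}

#' Place the eight canonical landmarks for a phantom
#'
#' Deterministic anatomy-shaped placement, scaled to the spec's ellipsoid;
#' optional seeded Gaussian jitter (`landmark_jitter_mm`).
#'
#' @inheritParams make_phantom_mask
#' @return a [landmark_set()].
#' @export
place_landmarks <- function(spec) {
  scale <- spec$semi_axes_mm / c(90, 60, 75)
  pts <- sweep(canonical_offsets(), 2, scale, `*`)
  pts <- sweep(pts, 2, spec$center_mm, `+`)
  if (spec$landmark_jitter_mm > 0) {
    jit <- with_seed(spec$seed * 13 + 1,
                     matrix(stats::rnorm(24, 0, spec$landmark_jitter_mm), 8, 3))
    pts <- pts + jit
  }
  landmark_set(pts)
}

#' Generate a synthetic multislice quantitative map for a labelled phantom
#'
#' Five slices with the standard acquisition geometry — cT1: 8 mm thick with
#' a 12 mm gap (20 mm plane spacing); PDFF: 20 mm thick, contiguous — centered
#' on the liver's axial extent. Slice pixels share the volume's in-plane grid;
#' each pixel takes the per-segment constant of the label under it plus
#' seeded Gaussian noise (clamped to the modality's physical range), NA
#' outside the liver.
#'
#' @inheritParams make_phantom_mask
#' @param labels `segment_labels` of the phantom.
#' @param modality "cT1" or "PDFF".
#' @param noise_sd noise SD; default from the spec.
#' @return a [quant_map()].
#' @export
make_quantmap <- function(spec, labels, modality = c("cT1", "PDFF"),
                          noise_sd = NULL) {
  modality <- match.arg(modality)
  if (is.null(noise_sd)) noise_sd <- unname(spec$map_noise_sd[modality])
  A <- labels$affine
  dims <- dim(labels$grid)
  thickness <- default_thickness(modality)
  kfg <- which(apply(labels$grid != 0L, 3, any))
  zs <- A[3, 4] + (kfg - 1) * A[3, 3]
  if (diff(range(zs)) < thickness)
    cn_warn("liver thinner than one slab", "couinaud_thin_liver")
  zmid <- mean(range(zs))
  plane_z <- zmid + (-2:2) * 20
  const <- spec$map_values[[modality]]
  code_of <- stats::setNames(segment_codes(), segment_names())
  lut <- rep(NA_real_, 64)
  lut[code_of + 1L] <- as.numeric(const[names(code_of)])
  slices <- with_seed(spec$seed * 31 + match(modality, c("cT1", "PDFF")), {
    lapply(plane_z, function(zp) {
      k <- as.integer(round((zp - A[3, 4]) / A[3, 3])) + 1L
      vals <- if (k >= 1 && k <= dims[3]) {
        v <- matrix(lut[labels$grid[, , k] + 1L], dims[1], dims[2])
        if (noise_sd > 0) {
          v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), dims[1], dims[2])
          v <- if (modality == "cT1") pmax(v, 0) else pmin(pmax(v, 0), 100)
        }
        v
      } else matrix(NA_real_, dims[1], dims[2])
      As <- A
      As[1:3, 4] <- c(A[1, 4], A[2, 4], zp)
      list(values = vals, affine = As, thickness = thickness)
    })
  })
  quant_map(modality, slices)
}

#' Simulated paired measurements under a multiplicative difference model
#'
#' Each subject's first reading is the truth; the second reading is low by
#' `bias_pct + eps` percent with `eps ~ Normal(0, sd_pct)`. This emulates a
#' repeatability design: the same quantity measured twice with a systematic
#' and a random component.
#'
#' @param true_values subject truths; NULL draws n values uniformly from
#'   1000-2000 mL (typical adult liver volumes); a single value is recycled.
#' @param bias_pct,sd_pct systematic and random percent-difference components.
#' @param n number of subjects (>= 3).
#' @param seed integer seed.
#' @return data frame with columns id, value_a, value_b.
#' @export
simulate_pairs <- function(true_values, bias_pct, sd_pct, n, seed = 1) {
  if (n < 3) cn_stop("need n >= 3 pairs", "couinaud_too_few_pairs")
  if (!is.numeric(sd_pct) || sd_pct < 0) cn_stop("sd_pct must be >= 0",
                                                 "couinaud_bad_input")
  with_seed(seed, {
    truth <- if (is.null(true_values)) stats::runif(n, 1000, 2000)
             else rep_len(as.numeric(true_values), n)
    eps <- if (sd_pct > 0) stats::rnorm(n, 0, sd_pct) else numeric(n)
    data.frame(id = seq_len(n),
               value_a = truth,
               value_b = truth * (1 - (bias_pct + eps) / 100))
  })
}

#' Supersampled ground-truth volumetry for a phantom
#'
#' Rebuilds the phantom surface and classification on a grid refined by
#' `factor` in every direction (sub-centers tile each voxel symmetrically)
#' and counts sub-voxels per segment. This is the volumetry oracle: the same
#' geometry evaluated at a resolution where discretization error is
#' `factor`-fold smaller per axis.
#'
#' @inheritParams make_phantom_mask
#' @param factor per-axis refinement (default 3).
#' @param caudate_radius_mm passed to [build_planes()].
#' @return data frame: segment, code, volume_ml; plus a whole_liver row.
#' @export
phantom_truth <- function(spec, factor = 3, caudate_radius_mm = 30) {
  dims <- phantom_dims(spec) * factor
  v <- spec$voxel_size_mm / factor
  A0 <- phantom_affine(spec)
  origin <- A0[1:3, 4] - spec$voxel_size_mm / 2 + v / 2
  coef <- perturb_coeffs(spec)
  planes <- build_planes(place_landmarks(spec), caudate_radius_mm)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * v[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * v[2]
  counts <- stats::setNames(numeric(9), segment_codes())
  xm <- matrix(xs, dims[1], dims[2])
  ym <- matrix(ys, dims[1], dims[2], byrow = TRUE)
  for (k in seq_len(dims[3])) {
    z <- origin[3] + (k - 1) * v[3]
    inside <- ellipsoid_inside(spec, xm, ym, z, coef)
    if (!any(inside)) next
    P <- cbind(xm[inside], ym[inside], z)
    codes <- classify_points(P, planes)
    tb <- table(codes)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  vol <- counts * prod(v) / 1000
  data.frame(segment = c(segment_names(), "whole_liver"),
             code = c(segment_codes(), NA_integer_),
             volume_ml = c(unname(vol), sum(vol)),
             stringsAsFactors = FALSE)
}

#' Write a complete phantom fixture set to a directory
#'
#' Writes mask.nii.gz, landmarks.json, ct1.nii.gz, pdff.nii.gz and
#' truth.json (supersampled ground-truth segment volumes).
#'
#' @inheritParams phantom_truth
#' @param dir output directory (created if needed).
#' @return invisible named list of file paths.
#' @export
phantom_dataset <- function(spec, dir, factor = 3, caudate_radius_mm = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- make_phantom_mask(spec)
  lms <- place_landmarks(spec)
  planes <- build_planes(lms, caudate_radius_mm)
  labels <- assign_segments(mask, planes)
  paths <- list(mask = file.path(dir, "mask.nii.gz"),
                landmarks = file.path(dir, "landmarks.json"),
                ct1 = file.path(dir, "ct1.nii.gz"),
                pdff = file.path(dir, "pdff.nii.gz"),
                truth = file.path(dir, "truth.json"))
  write_mask(mask, paths$mask)
  write_landmarks(lms, paths$landmarks)
  write_quantmap(make_quantmap(spec, labels, "cT1"), paths$ct1)
  write_quantmap(make_quantmap(spec, labels, "PDFF"), paths$pdff)
  truth <- phantom_truth(spec, factor = factor,
                         caudate_radius_mm = caudate_radius_mm)
  jsonlite::write_json(list(seed = spec$seed, supersample_factor = factor,
                            volumes = truth),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
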