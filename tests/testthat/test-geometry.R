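test_that("IVC axis: unit direction from inferior toward superior", {
  lms <- canonical_landmarks()
  ax <- ivc_axis_of(lms)
  expect_equal(ax$point, c(0, 0, 0))
  expect_equal(ax$direction, c(0, 0, 1))

  lms345 <- canonical_landmarks()
  lms345$ivc_superior <- c(0, 3, 4)
  ax2 <- ivc_axis_of(lms345)
  expect_equal(ax2$direction, c(0, 0.6, 0.8))

  bad <- unclass(canonical_landmarks())
  bad$ivc_superior <- bad$ivc_inferior
  expect_error(landmark_set(bad[landmark_names_fixture()]),
               class = "couinaud_degenerate_axis")
})

test_that("fit_axis_plane: exact fit when targets are coplanar with the axis", {
  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  pl <- fit_axis_plane(ax, rbind(c(0, 10, 90), c(0, 50, 10)),
                       orient_toward = c(40, 10, 80))
  expect_equal(pl$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(signed_distance(pl, c(40, 10, 80)), 40, tolerance = 1e-12)
})

test_that("fit_axis_plane single target matches the closed-form cross product", {
  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  pl <- fit_axis_plane(ax, c(40, 10, 80), orient_toward = c(15, 50, 20))
  n_expect <- c(-10, 40, 0) / sqrt(100 + 1600)   # (0,0,1) x (40,10,80), unit
  expect_equal(pl$normal, n_expect, tolerance = 1e-9)
  expect_equal(signed_distance(pl, c(15, 50, 20)), 44.87, tolerance = 0.005)

  # brute-force dominance over a fine theta grid
  thetas <- seq(0, pi, length.out = 1e4)
  expect_lte(plane_objective(pl, ax, c(40, 10, 80)),
             min(theta_grid_objective(ax, c(40, 10, 80), thetas)) + 1e-9)
})

test_that("fit_axis_plane recovers the symmetry plane of mirrored targets", {
  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  tg <- rbind(c(10, 20, 50), c(-10, 20, 50))
  pl <- fit_axis_plane(ax, tg, orient_toward = c(30, 0, 0))
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-9)
  thetas <- seq(0, pi, length.out = 1e4)
  expect_lte(plane_objective(pl, ax, tg),
             min(theta_grid_objective(ax, tg, thetas)) + 1e-9)
})

test_that("fit_axis_plane dominates a 1e4-point theta grid on random targets", {
  thetas <- seq(0, pi, length.out = 1e4)
  for (s in 1:50) {
    cfg <- withr_seed(s, {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      k <- sample(1:4, 1)
      list(ax = list(point = stats::runif(3, -20, 20), direction = d),
           tg = matrix(stats::runif(3 * k, -60, 60), ncol = 3),
           orient = stats::runif(3, -60, 60))
    })
    pl <- tryCatch(fit_axis_plane(cfg$ax, cfg$tg, orient_toward = cfg$orient),
                   couinaud_ambiguous_orientation = function(e) NULL)
    if (is.null(pl)) next
    expect_lte(plane_objective(pl, cfg$ax, cfg$tg),
               min(theta_grid_objective(cfg$ax, cfg$tg, thetas)) + 1e-9)
  }
})

test_that("fit_axis_plane degenerate and ambiguous inputs raise named errors", {
  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  expect_error(fit_axis_plane(ax, c(0, 0, 50), orient_toward = c(1, 0, 0)),
               class = "couinaud_degenerate_plane")
  pl_target <- c(40, 10, 80)
  expect_error(fit_axis_plane(ax, pl_target, orient_toward = c(40, 10, 20)),
               class = "couinaud_ambiguous_orientation")
})

test_that("build_planes reproduces the canonical plane geometry", {
  pl <- canonical_planes()
  expect_equal(pl$main_plane$normal, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(pl$left_plane$normal, c(0.9103665, 0.4138029, 0), tolerance = 1e-6)
  expect_equal(signed_distance(pl$left_plane, c(0, 10, 90)), 4.138029,
               tolerance = 1e-5)
  # portal planes: perpendicular to the axis through the portal landmarks
  expect_equal(pl$right_portal_plane$normal, c(0, 0, 1))
  expect_equal(signed_distance(pl$right_portal_plane, c(30, 20, 45)), 0)
  expect_equal(signed_distance(pl$left_portal_plane, c(10, 10, 50)), 0)
  # vertical planes contain the axis
  for (nm in c("main_plane", "right_plane", "left_plane"))
    expect_lt(abs(sum(pl[[nm]]$normal * pl$axis_direction)), 1e-9)
  # unit normals
  for (nm in c("main_plane", "right_plane", "left_plane",
               "right_portal_plane", "left_portal_plane"))
    expect_equal(sqrt(sum(pl[[nm]]$normal^2)), 1, tolerance = 1e-9)
})

test_that("build_planes flags degenerate landmark configurations", {
  # umbilical fissure on the IVC axis -> left plane undefined
  lms <- unclass(canonical_landmarks())
  lms$umbilical_fissure <- c(0, 0, 15)
  expect_error(build_planes(landmark_set(lms[landmark_names_fixture()])),
               class = "couinaud_degenerate_plane")
  # right hepatic vein on the axis also sits on the main plane -> ambiguous
  lms2 <- unclass(canonical_landmarks())
  lms2$right_hepatic_vein <- c(0, 0, 80)
  expect_error(build_planes(landmark_set(lms2[landmark_names_fixture()])),
               class = "couinaud_ambiguous_orientation")
  expect_error(canonical_planes(caudate_radius_mm = -1),
               class = "couinaud_bad_radius")
})

test_that("signed distance is positive on the oriented side and zero on the plane", {
  pl <- canonical_planes()
  expect_equal(signed_distance(pl$main_plane, c(40, 30, 60)), 40)
  expect_equal(signed_distance(pl$main_plane, c(0, 99, -7)), 0)
  # vectorized form agrees with scalar
  pts <- matrix(stats::runif(30, -50, 50), ncol = 3)
  expect_equal(signed_distance(pl$left_plane, pts),
               apply(pts, 1, function(p) signed_distance(pl$left_plane, p)))
})

test_that("rigid transforms move planes consistently (signed distances preserved)", {
  lms <- canonical_landmarks()
  pl <- build_planes(lms)
  probe <- matrix(stats::runif(60, -80, 80), ncol = 3)
  for (s in 1:10) {
    rig <- random_rigid(s + 100)
    pl2 <- build_planes(apply_rigid_landmarks(lms, rig))
    probe2 <- t(rig$R %*% t(probe) + rig$t)
    for (nm in c("main_plane", "right_plane", "left_plane",
                 "right_portal_plane", "left_portal_plane"))
      expect_equal(signed_distance(pl2[[nm]], probe2),
                   signed_distance(pl[[nm]], probe), tolerance = 1e-9)
  }
})
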