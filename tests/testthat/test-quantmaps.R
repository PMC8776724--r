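# A tiny fully-labelled volume: 6 x 6 x 12 at 2 mm isotropic, all segment 5.
flat_labels <- function(nz = 12, dz = 2) {
  g <- array(5L, dim = c(6, 6, nz))
  A <- diag(c(2, 2, dz, 1))
  A[3, 4] <- -dz * (nz - 1) / 2          # z centers symmetric about 0
  couinaud:::segment_labels(g, A)
}

one_slice_map <- function(value = 800, z = 0, thickness = 8, n = 6) {
  A <- diag(c(2, 2, 1, 1)); A[3, 4] <- z
  quant_map("cT1", list(list(values = matrix(value, n, n), affine = A,
                             thickness = thickness)))
}

test_that("slab model: inside +/- thickness/2 gets the slice value, gaps are missing", {
  labels <- flat_labels(nz = 23, dz = 1)   # z centers -11..11
  vals <- resample_to_grid(one_slice_map(800, z = 0, thickness = 8), labels)
  z_of <- function(k) labels$affine[3, 4] + (k - 1)
  for (k in seq_len(dim(vals)[3])) {
    z <- z_of(k)
    if (abs(z) <= 4) expect_true(all(vals[, , k] == 800))
    else expect_true(all(is.na(vals[, , k])))
  }
  # voxel center exactly at the slab edge (z = 4) is included
  expect_true(all(vals[, , which(abs(sapply(seq_len(23), z_of) - 4) < 1e-9)] == 800))
  # z = 10 sits in the inter-slice gap -> missing
  expect_true(all(is.na(vals[, , which(abs(sapply(seq_len(23), z_of) - 10) < 1e-9)])))
})

test_that("overlapping slabs: nearer slice wins, tie goes to the earlier slice", {
  labels <- flat_labels(nz = 9, dz = 1)    # z centers -4..4
  A1 <- diag(c(2, 2, 1, 1)); A1[3, 4] <- -2
  A2 <- diag(c(2, 2, 1, 1)); A2[3, 4] <- 2
  map <- quant_map("cT1", list(
    list(values = matrix(100, 6, 6), affine = A1, thickness = 8),
    list(values = matrix(200, 6, 6), affine = A2, thickness = 8)))
  vals <- resample_to_grid(map, labels)
  zc <- -4:4
  v <- vals[1, 1, ]
  expect_equal(v[zc <= 0], rep(100, sum(zc <= 0)))  # z = 0 ties -> earlier
  expect_equal(v[zc > 0], rep(200, sum(zc > 0)))
})

test_that("non-overlapping geometry warns and returns all-missing", {
  labels <- flat_labels()
  expect_warning(vals <- resample_to_grid(one_slice_map(z = 500), labels),
                 class = "couinaud_no_overlap")
  expect_true(all(is.na(vals)))
})

test_that("segment medians: even-count midpoint, min_voxels flag, whole-liver union", {
  labels <- flat_labels(nz = 4, dz = 1)
  vals <- array(NA_real_, dim = dim(labels$grid))
  vals[1, 1, ] <- c(1, 2, 3, 4)
  med <- segment_medians(vals, labels, min_voxels = 4)
  expect_equal(med$median[med$segment == "5"], 2.5)
  expect_equal(med$n_voxels[med$segment == "5"], 4)
  expect_false(med$flagged[med$segment == "5"])
  # under min_voxels -> flagged missing
  med10 <- segment_medians(vals, labels, min_voxels = 10)
  expect_true(med10$flagged[med10$segment == "5"])
  expect_true(is.na(med10$median[med10$segment == "5"]))
  # whole-liver median computed over the union of segments
  expect_equal(med$median[med$segment == "whole_liver"], 2.5)
})

test_that("whole-liver median ignores segment boundaries", {
  spec <- small_spec(21)
  mask <- make_phantom_mask(spec)
  labels <- assign_segments(mask, build_planes(place_landmarks(spec), 4))
  vals <- array(NA_real_, dim = dim(labels$grid))
  fg <- labels$grid != 0L
  vals[fg] <- withr_seed(5, stats::runif(sum(fg), 700, 1100))
  med_a <- segment_medians(vals, labels)
  labels_all5 <- couinaud:::segment_labels(
    array(ifelse(fg, 5L, 0L), dim = dim(labels$grid)), labels$affine)
  med_b <- segment_medians(vals, labels_all5)
  expect_equal(med_a$median[med_a$segment == "whole_liver"],
               med_b$median[med_b$segment == "whole_liver"])
})

test_that("adding a constant shifts every median by that constant", {
  labels <- flat_labels()
  vals <- resample_to_grid(one_slice_map(800, z = 0), labels)
  shifted <- vals + 37.5
  m0 <- segment_medians(vals, labels)
  m1 <- segment_medians(shifted, labels)
  ok <- !is.na(m0$median)
  expect_equal(m1$median[ok], m0$median[ok] + 37.5)
})

test_that("quantmap NIfTI stack round-trips through write/read", {
  spec <- small_spec(8)
  mask <- make_phantom_mask(spec)
  labels <- assign_segments(mask, build_planes(place_landmarks(spec), 4))
  map <- make_quantmap(spec, labels, "cT1", noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_quantmap(map, f)
  map2 <- read_quantmap(f, "cT1")
  expect_equal(length(map2$slices), length(map$slices))
  for (i in seq_along(map$slices)) {
    expect_equal(map2$slices[[i]]$values, map$slices[[i]]$values,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(map2$slices[[i]]$affine[1:3, 4], map$slices[[i]]$affine[1:3, 4],
                 tolerance = 1e-6)
    expect_equal(map2$slices[[i]]$thickness, 8)
  }
})

test_that("map validation rejects out-of-range values and bad slices", {
  A <- diag(4)
  expect_error(quant_map("cT1", list(list(values = matrix(-5, 2, 2),
                                          affine = A, thickness = 8))),
               class = "couinaud_bad_map_values")
  expect_error(quant_map("PDFF", list(list(values = matrix(150, 2, 2),
                                           affine = A, thickness = 20))),
               class = "couinaud_bad_map_values")
  expect_error(quant_map("cT1", list()), class = "couinaud_no_slices")
})
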