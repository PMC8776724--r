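#' Sparse multislice quantitative map
#'
#' Container for a multislice quantitative MRI map: cT1 (iron-corrected T1,
#' ms) acquired as thin axial slices with gaps, or PDFF (proton density fat
#' fraction, %) acquired as thicker contiguous slices. Each slice is a 2D
#' value array, a 4x4 affine mapping in-plane pixel index (i, j, 0, 1) to
#' world mm, and a slab thickness.
#'
#' @param modality "cT1" or "PDFF".
#' @param slices list of `list(values = <2D array>, affine = <4x4>,
#'   thickness = <mm>)`.
#' @export
quant_map <- function(modality, slices) {
  modality <- match.arg(modality, c("cT1", "PDFF"))
  if (length(slices) < 1) cn_stop("quant map needs at least one slice",
                                  "couinaud_no_slices")
  for (s in slices) {
    if (length(dim(s$values)) != 2)
      cn_stop("slice values must be 2D", "couinaud_bad_slice")
    check_affine(s$affine)
    if (!is.numeric(s$thickness) || s$thickness <= 0)
      cn_stop("slice thickness must be positive", "couinaud_bad_slice")
    v <- s$values[!is.na(s$values)]
    if (modality == "cT1" && any(v < 0))
      cn_stop("cT1 values must be >= 0", "couinaud_bad_map_values")
    if (modality == "PDFF" && any(v < 0 | v > 100))
      cn_stop("PDFF values must lie in [0, 100]", "couinaud_bad_map_values")
  }
  structure(list(modality = modality, slices = slices), class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  cat(sprintf("<quant_map> %s, %d slices of %s px, thickness %.1f mm\n",
              x$modality, length(x$slices),
              paste(dim(x$slices[[1]]$values), collapse = " x "),
              x$slices[[1]]$thickness))
  invisible(x)
}

# Paper-standard slab thicknesses: shMOLLI cT1 slices are 8 mm thick (12 mm
# gap); IDEAL PDFF slices 20 mm thick.
default_thickness <- function(modality) switch(modality, cT1 = 8, PDFF = 20)

#' Read a multislice map stored as a thin 3D NIfTI stack
#'
#' The k-th slice of the stack becomes slice k of the map; its affine is the
#' volume affine with origin advanced k steps along the third axis. The slab
#' thickness is not representable in a NIfTI header (the third pixdim is the
#' plane-to-plane spacing, gaps included) so it is taken from the modality
#' default (cT1 8 mm, PDFF 20 mm) unless given.
#'
#' @param path NIfTI path.
#' @inheritParams quant_map
#' @param thickness slab thickness in mm; default per modality.
#' @export
read_quantmap <- function(path, modality, thickness = NULL) {
  modality <- match.arg(modality, c("cT1", "PDFF"))
  if (is.null(thickness)) thickness <- default_thickness(modality)
  x <- read_nifti_3d(path, "quantitative map")
  stack_to_quantmap(x$grid, x$affine, modality, thickness)
}

stack_to_quantmap <- function(grid, affine, modality, thickness) {
  slices <- lapply(seq_len(dim(grid)[3]), function(k) {
    A <- affine
    A[1:3, 4] <- A[1:3, 4] + (k - 1) * A[1:3, 3]
    list(values = grid[, , k], affine = A, thickness = thickness)
  })
  quant_map(modality, slices)
}

#' @param map a `quant_map` whose slices share a common stack geometry.
#' @rdname read_quantmap
#' @export
write_quantmap <- function(map, path) {
  grid <- simplify2array(lapply(map$slices, `[[`, "values"))
  A <- map$slices[[1]]$affine
  if (length(map$slices) > 1)      # stack step = plane-to-plane spacing
    A[1:3, 3] <- map$slices[[2]]$affine[1:3, 4] - A[1:3, 4]
  write_nifti_3d(grid, A, path, datatype = "double")
}

#' Resample a sparse multislice map onto a label-map grid
#'
#' Slab model: a volume voxel center lying within +/- thickness/2 of a
#' slice's plane (distance along the slice normal, closed interval) receives
#' that slice's nearest in-plane pixel value; voxel centers in inter-slice
#' gaps or beyond the slice's in-plane bounds are missing (NA). Where slabs
#' overlap, the nearer slice plane wins; ties go to the earlier slice. No
#' interpolation is performed: medians of quantitative maps should not be
#' computed from invented values.
#'
#' @param map a `quant_map`.
#' @param labels a `segment_labels` object sharing the map's world frame.
#' @return array of map values on the label grid, NA where missing.
#' @export
resample_to_grid <- function(map, labels) {
  dims <- dim(labels$grid)
  n <- prod(dims)
  ijk0 <- arrayInd(seq_len(n), dims) - 1
  P <- voxel_world(ijk0, labels$affine)
  vals <- rep(NA_real_, n)
  best <- rep(Inf, n)
  for (s in map$slices) {
    c1 <- s$affine[1:3, 1]; c2 <- s$affine[1:3, 2]; o <- s$affine[1:3, 4]
    nrm <- unitize(c(c1[2] * c2[3] - c1[3] * c2[2],
                     c1[3] * c2[1] - c1[1] * c2[3],
                     c1[1] * c2[2] - c1[2] * c2[1]))
    off <- sweep(P, 2, o)
    dn <- abs(as.numeric(off %*% nrm))
    cand <- which(dn <= s$thickness / 2 & dn < best)
    if (!length(cand)) next
    # in-plane continuous pixel indices: solve [c1 c2 n] u = offset
    B <- solve(cbind(c1, c2, nrm))
    uv <- off[cand, , drop = FALSE] %*% t(B[1:2, , drop = FALSE])
    i <- as.integer(round(uv[, 1])); j <- as.integer(round(uv[, 2]))
    dsl <- dim(s$values)
    ok <- i >= 0 & i < dsl[1] & j >= 0 & j < dsl[2]
    cand <- cand[ok]
    if (!length(cand)) next
    vals[cand] <- s$values[cbind(i[ok] + 1L, j[ok] + 1L)]
    best[cand] <- dn[cand]
  }
  if (all(is.na(vals)))
    cn_warn("map and volume do not overlap: all values missing",
            "couinaud_no_overlap")
  array(vals, dim = dims)
}

#' Per-segment medians of a resampled map
#'
#' Median of the non-missing map values within each Couinaud segment and over
#' the whole liver. Segments with fewer than `min_voxels` non-missing values
#' are reported missing (NA median, `flagged = TRUE`): the sparse slice
#' coverage can clip a segment to a handful of voxels, where a median is
#' unstable. Even-count medians are the midpoint of the two central values.
#'
#' @param values array from [resample_to_grid()].
#' @param labels the `segment_labels` the values were resampled onto.
#' @param min_voxels minimum non-missing voxel count per segment; default 10.
#' @return data frame: segment, code, median, n_voxels, flagged.
#' @export
segment_medians <- function(values, labels, min_voxels = 10) {
  if (!all(dim(values) == dim(labels$grid)))
    cn_stop("values and labels have different grid shapes", "couinaud_shape_mismatch")
  one <- function(sel) {
    v <- values[sel]
    v <- v[!is.na(v)]
    n <- length(v)
    list(median = if (n >= min_voxels) stats::median(v) else NA_real_,
         n = n, flagged = n < min_voxels)
  }
  rows <- lapply(segment_codes(), function(cd) one(labels$grid == cd))
  whole <- one(labels$grid != 0L)
  data.frame(segment = c(segment_names(), "whole_liver"),
             code = c(segment_codes(), NA_integer_),
             median = c(vapply(rows, `[[`, numeric(1), "median"), whole$median),
             n_voxels = c(vapply(rows, `[[`, numeric(1), "n"), whole$n),
             flagged = c(vapply(rows, `[[`, logical(1), "flagged"), whole$flagged),
             stringsAsFactors = FALSE)
}
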