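#' Classify a single world point into a Couinaud segment
#'
#' Scalar reference decision tree, evaluated in order:
#' \enumerate{
#'   \item perpendicular distance to the IVC axis at most the caudate radius
#'     -> segment 1 (caudate);
#'   \item right of the main (Cantlie) plane: anterior of the right plane ->
#'     8 above the right portal plane else 5; posterior -> 7 above else 6;
#'   \item left: medial of the left plane -> 4a above the left portal plane
#'     else 4b; lateral -> 2 above else 3.
#' }
#' A signed distance of exactly zero counts as the positive side, so the
#' classifier is total and deterministic.
#'
#' @param point length-3 world coordinate, mm.
#' @param planes a `plane_set` from [build_planes()].
#' @return integer segment code (41/42 encode 4a/4b).
#' @export
classify_point <- function(point, planes) {
  v <- point - planes$axis_point
  t1 <- sum(v * planes$axis_direction)
  perp2 <- sum(v * v) - t1 * t1
  r <- planes$caudate_radius_mm
  if (perp2 <= r * r) return(1L)
  pd <- function(pl) sum(pl$normal * (point - pl$point))
  if (pd(planes$main_plane) >= 0) {
    if (pd(planes$right_plane) >= 0) {
      if (pd(planes$right_portal_plane) >= 0) 8L else 5L
    } else {
      if (pd(planes$right_portal_plane) >= 0) 7L else 6L
    }
  } else {
    if (pd(planes$left_plane) >= 0) {
      if (pd(planes$left_portal_plane) >= 0) 41L else 42L
    } else {
      if (pd(planes$left_portal_plane) >= 0) 2L else 3L
    }
  }
}

# Vectorized classifier over an n x 3 matrix of world points; independent
# matrix-algebra route, kept exactly sign-compatible with classify_point.
classify_points <- function(points, planes) {
  V <- sweep(points, 2, planes$axis_point)
  t1 <- as.numeric(V %*% planes$axis_direction)
  perp2 <- rowSums(V * V) - t1 * t1
  r <- planes$caudate_radius_mm
  pd <- function(pl) as.numeric(sweep(points, 2, pl$point) %*% pl$normal)
  main <- pd(planes$main_plane) >= 0
  right <- pd(planes$right_plane) >= 0
  left <- pd(planes$left_plane) >= 0
  rp <- pd(planes$right_portal_plane) >= 0
  lp <- pd(planes$left_portal_plane) >= 0
  code <- integer(nrow(points))
  code[main & right & rp] <- 8L
  code[main & right & !rp] <- 5L
  code[main & !right & rp] <- 7L
  code[main & !right & !rp] <- 6L
  code[!main & left & lp] <- 41L
  code[!main & left & !lp] <- 42L
  code[!main & !left & lp] <- 2L
  code[!main & !left & !lp] <- 3L
  code[perp2 <= r * r] <- 1L
  code
}

# World coordinates (n x 3) of the voxel centers at 0-based indices ijk0.
voxel_world <- function(ijk0, affine) {
  sweep(ijk0 %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' Label every liver voxel with its Couinaud segment
#'
#' Each foreground voxel is classified by the world coordinate of its center
#' (no partial-volume weighting); background stays 0.
#'
#' @param mask a [liver_mask()].
#' @param planes a `plane_set` in the same world frame.
#' @return a `segment_labels` object.
#' @export
assign_segments <- function(mask, planes) {
  if (!inherits(mask, "liver_mask")) cn_stop("mask must be a liver_mask",
                                             "couinaud_bad_input")
  fg <- which(mask$grid == 1L)
  if (length(fg) == 0) cn_stop("mask has no foreground voxels",
                               "couinaud_empty_mask")
  ijk0 <- arrayInd(fg, dim(mask$grid)) - 1
  codes <- classify_points(voxel_world(ijk0, mask$affine), planes)
  grid <- array(0L, dim = dim(mask$grid))
  grid[fg] <- codes
  segment_labels(grid, mask$affine)
}

#' Per-segment volumetry from a label map
#'
#' Volume of segment s = (voxel count of s) x |det(affine 3x3)| / 1000, in mL.
#' The whole-liver volume is the sum over the nine segments (identical voxel
#' counts, so the sum is exact), and fractions are segment / whole.
#'
#' @param labels a `segment_labels` object.
#' @return a `segment_report` data frame: one row per segment (display name,
#'   code, voxel count, volume in mL, fraction of whole liver) plus a final
#'   whole-liver row.
#' @export
segment_volumes <- function(labels) {
  vox_ml <- voxel_volume_mm3(labels$affine) / 1000
  codes <- segment_codes()
  counts <- vapply(codes, function(cd) sum(labels$grid == cd), integer(1))
  total <- sum(counts)
  vols <- counts * vox_ml
  # whole-liver volume as the sum of the nine segment volumes, so the
  # conservation identity holds bit-exactly
  df <- data.frame(segment = c(segment_names(), "whole_liver"),
                   code = c(codes, NA_integer_),
                   voxel_count = c(counts, total),
                   volume_ml = c(vols, sum(vols)),
                   volume_fraction = c(if (total > 0) counts / total else
                                       rep(NA_real_, length(counts)), 1),
                   stringsAsFactors = FALSE)
  class(df) <- c("segment_report", "data.frame")
  df
}

#' @export
print.segment_report <- function(x, digits = 2, ...) {
  cat("Couinaud segment report\n")
  df <- as.data.frame(x)
  df$volume_ml <- round(df$volume_ml, digits)
  df$volume_fraction <- round(df$volume_fraction, 4)
  for (nm in intersect(c("median_ct1_ms", "median_pdff_pct"), names(df)))
    df[[nm]] <- round(df[[nm]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

report_volume <- function(report, segment) {
  df <- as.data.frame(report)
  i <- match(segment, df$segment)
  if (anyNA(i)) cn_stop(sprintf("report has no row for segment %s",
                                paste(segment[is.na(i)], collapse = ", ")),
                        "couinaud_bad_report")
  df$volume_ml[i]
}
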