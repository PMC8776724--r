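#' Landmark-based Couinaud segmentation of a liver mask
#'
#' The package's central fit: takes a binary liver mask and the eight
#' anatomical landmarks, builds the intersegmental plane set, labels every
#' liver voxel with its Couinaud segment, computes per-segment volumetry and
#' (optionally) per-segment medians of cT1 and PDFF maps.
#'
#' @param mask a [liver_mask()] (or path to a NIfTI file).
#' @param landmarks a [landmark_set()] (or path to a landmark JSON file).
#' @param caudate_radius_mm caudate (segment 1) radius around the IVC axis, mm.
#' @param ct1,pdff optional [quant_map()] objects (or NIfTI paths) to
#'   summarize per segment.
#' @param min_map_voxels minimum non-missing map voxels for a segment median.
#' @return an object of class `couinaud` with components `labels`
#'   (`segment_labels`), `planes` (`plane_set`), `report` (`segment_report`,
#'   with median columns when maps are given), `landmarks` and `call`.
#'   Methods: `print`, `summary`, `plot`.
#' @examples
#' spec <- phantom_spec()
#' fit <- couinaud(make_phantom_mask(spec), place_landmarks(spec))
#' summary(fit)
#' @export
couinaud <- function(mask, landmarks, caudate_radius_mm = 30,
                     ct1 = NULL, pdff = NULL, min_map_voxels = 10) {
  cl <- match.call()
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  landmarks <- as_landmarks(landmarks)
  if (is.character(ct1)) ct1 <- read_quantmap(ct1, "cT1")
  if (is.character(pdff)) pdff <- read_quantmap(pdff, "PDFF")
  planes <- build_planes(landmarks, caudate_radius_mm)
  labels <- assign_segments(mask, planes)
  report <- segment_volumes(labels)
  add_medians <- function(report, map, col, ncol) {
    med <- segment_medians(resample_to_grid(map, labels), labels,
                           min_voxels = min_map_voxels)
    report[[col]] <- med$median[match(report$segment, med$segment)]
    report[[ncol]] <- med$n_voxels[match(report$segment, med$segment)]
    report
  }
  if (!is.null(ct1)) report <- add_medians(report, ct1, "median_ct1_ms", "n_ct1")
  if (!is.null(pdff)) report <- add_medians(report, pdff, "median_pdff_pct", "n_pdff")
  attr(report, "audit") <- c(
    list(tool = "couinaud", version = as.character(utils::packageVersion("couinaud")),
         caudate_radius_mm = caudate_radius_mm, min_map_voxels = min_map_voxels,
         orientation = list(main_plane = "positive = patient right",
                            right_plane = "positive = anterior",
                            left_plane = "positive = medial",
                            portal_planes = "positive = superior"),
         percent_loa_denominator = "pair mean"),
    plane_set_audit(planes))
  structure(list(labels = labels, planes = planes, report = report,
                 landmarks = landmarks, caudate_radius_mm = caudate_radius_mm,
                 call = cl),
            class = "couinaud")
}

#' @export
print.couinaud <- function(x, ...) {
  cat("Couinaud segmentation\n")
  cat("Call: "); print(x$call)
  df <- as.data.frame(x$report)
  whole <- df[df$segment == "whole_liver", ]
  cat(sprintf("Whole liver: %.1f mL over %d voxels; caudate radius %.1f mm\n",
              whole$volume_ml, whole$voxel_count, x$caudate_radius_mm))
  cat(sprintf("Segments present: %s\n",
              paste(df$segment[!is.na(df$code) & df$voxel_count > 0],
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.couinaud <- function(object, ...) object$report

#' Mid-axial view of the segment labels
#' @param x a `couinaud` object.
#' @param k axial slice index (default: slice with most liver).
#' @param ... passed to [graphics::image()].
#' @export
plot.couinaud <- function(x, k = NULL, ...) {
  g <- x$labels$grid
  if (is.null(k)) k <- which.max(apply(g != 0L, 3, sum))
  codes <- c(0L, segment_codes())
  pal <- c("white", grDevices::hcl.colors(9, "Spectral"))
  sl <- matrix(match(g[, , k], codes) - 1L, dim(g)[1], dim(g)[2])
  graphics::image(seq_len(dim(g)[1]), seq_len(dim(g)[2]), sl,
                  col = pal, breaks = seq(-0.5, 9.5, by = 1),
                  useRaster = TRUE, asp = dim(g)[2] / dim(g)[1],
                  xlab = "i", ylab = "j",
                  main = sprintf("Couinaud labels, axial slice k = %d", k), ...)
  invisible(x)
}
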