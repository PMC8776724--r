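#' Liver mask container
#'
#' A binary voxel grid plus a 4x4 voxel-to-world affine (RAS+ world, mm).
#' Voxel index (i, j, k) is 0-based in the affine convention, matching the
#' NIfTI header; the world position of voxel (i,j,k) is
#' `affine %*% c(i, j, k, 1)`.
#'
#' @param grid 3D array; nonzero entries are foreground.
#' @param affine 4x4 numeric matrix; the upper-left 3x3 must be invertible
#'   and its |det| is the voxel volume in mm^3.
#' @export
liver_mask <- function(grid, affine) {
  affine <- check_affine(affine)
  if (length(dim(grid)) != 3)
    cn_stop("mask grid must be 3-dimensional", "couinaud_not_3d")
  g <- array(as.integer(grid > 0), dim = dim(grid))
  if (!any(g == 1L))
    cn_stop("mask has no foreground voxels", "couinaud_empty_mask")
  structure(list(grid = g, affine = affine), class = "liver_mask")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || !all(is.finite(affine)))
    cn_stop("affine must be a finite 4x4 matrix", "couinaud_bad_affine")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    cn_stop("affine 3x3 block is singular", "couinaud_bad_affine")
  affine
}

#' Voxel volume implied by an affine, in mm^3
#' @param affine 4x4 voxel-to-world matrix.
#' @export
voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

#' @export
print.liver_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<liver_mask> %d x %d x %d voxels, %.3f mm^3/voxel, %d foreground (%.1f mL)\n",
              d[1], d[2], d[3], voxel_volume_mm3(x$affine), sum(x$grid),
              sum(x$grid) * voxel_volume_mm3(x$affine) / 1000))
  invisible(x)
}

landmark_names <- function() {
  c("ivc_superior", "ivc_inferior", "middle_hepatic_vein", "gallbladder_fossa",
    "right_hepatic_vein", "umbilical_fissure", "right_portal_vein",
    "left_portal_vein")
}

#' Named anatomical landmark set
#'
#' Exactly the eight landmarks driving plane construction, each a world-mm
#' RAS+ coordinate: the superior and inferior inferior-vena-cava points, the
#' middle and right hepatic veins, the gallbladder fossa, the umbilical
#' fissure, and the right and left portal vein branch points.
#'
#' @param points named list (or 8 x 3 matrix with rownames) of length-3
#'   numeric coordinates in mm.
#' @param space world-space tag; only "RAS" is supported.
#' @export
landmark_set <- function(points, space = "RAS") {
  if (is.matrix(points))
    points <- stats::setNames(lapply(seq_len(nrow(points)),
                                     function(i) as.numeric(points[i, ])),
                              rownames(points))
  if (!identical(toupper(space), "RAS"))
    cn_stop(sprintf("unsupported landmark space '%s' (expected RAS)", space),
            "couinaud_bad_space")
  want <- landmark_names()
  missing <- setdiff(want, names(points))
  if (length(missing))
    cn_stop(paste0("missing landmark: ", paste(missing, collapse = ", ")),
            "couinaud_missing_landmark")
  extra <- setdiff(names(points), want)
  if (length(extra))
    cn_stop(paste0("unexpected landmark: ", paste(extra, collapse = ", ")),
            "couinaud_extra_landmark")
  pts <- lapply(points[want], as.numeric)
  ok <- vapply(pts, function(p) length(p) == 3 && all(is.finite(p)), logical(1))
  if (!all(ok))
    cn_stop(paste0("landmark not a finite 3-vector: ",
                   paste(want[!ok], collapse = ", ")),
            "couinaud_bad_landmark")
  if (sqrt(sum((pts$ivc_superior - pts$ivc_inferior)^2)) < 1e-9)
    cn_stop("ivc_superior equals ivc_inferior: IVC axis undefined",
            "couinaud_degenerate_axis")
  structure(c(pts, list(space = "RAS")), class = "liver_landmarks")
}

as_landmarks <- function(x) {
  if (inherits(x, "liver_landmarks")) x else landmark_set(x)
}

#' @export
print.liver_landmarks <- function(x, ...) {
  cat("<liver_landmarks> (RAS, mm)\n")
  for (nm in landmark_names())
    cat(sprintf("  %-20s (%8.2f, %8.2f, %8.2f)\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

# ---- NIfTI ------------------------------------------------------------------

read_nifti_3d <- function(path, what = "image") {
  if (!file.exists(path))
    cn_stop(sprintf("file not found: %s", path), "couinaud_missing_file")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    cn_stop(sprintf("%s is not a 3D image (%d dimensions): %s",
                    what, length(d), path), "couinaud_not_3d")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(grid = as.array(img), affine = affine)
}

write_nifti_3d <- function(grid, affine, path, datatype = "auto") {
  img <- RNifti::asNifti(grid)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary liver mask from NIfTI
#'
#' Any voxel with value > 0 becomes foreground. The affine is taken from the
#' header (sform/qform, RAS+ convention).
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [liver_mask()].
#' @export
read_mask <- function(path) {
  x <- read_nifti_3d(path, "mask")
  liver_mask(x$grid, x$affine)
}

#' @param mask a `liver_mask`.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  write_nifti_3d(mask$grid, mask$affine, path, datatype = "uint8")
}

#' Read / write a Couinaud segment label map (integer NIfTI)
#'
#' Codes are 0 (background), 1, 2, 3, 41 (4a), 42 (4b), 5, 6, 7, 8.
#'
#' @param path NIfTI file path.
#' @return a `segment_labels` object (grid + affine).
#' @export
read_labelmap <- function(path) {
  x <- read_nifti_3d(path, "labelmap")
  segment_labels(x$grid, x$affine)
}

#' @param labels a `segment_labels` object.
#' @rdname read_labelmap
#' @export
write_labelmap <- function(labels, path) {
  write_nifti_3d(labels$grid, labels$affine, path, datatype = "uint8")
}

segment_labels <- function(grid, affine) {
  affine <- check_affine(affine)
  g <- array(as.integer(round(grid)), dim = dim(grid))
  bad <- setdiff(unique(as.vector(g)), c(0L, segment_codes()))
  if (length(bad))
    cn_stop(sprintf("labelmap contains invalid codes: %s",
                    paste(bad, collapse = ", ")), "couinaud_bad_labels")
  structure(list(grid = g, affine = affine), class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  n <- sum(x$grid != 0L)
  cat(sprintf("<segment_labels> %s voxels labelled over %s grid, %.3f mm^3/voxel\n",
              format(n, big.mark = ","), paste(dim(x$grid), collapse = " x "),
              voxel_volume_mm3(x$affine)))
  tab <- table(factor(x$grid[x$grid != 0L], levels = segment_codes(),
                      labels = segment_names()))
  print(tab)
  invisible(x)
}

# ---- landmark JSON ----------------------------------------------------------

#' Read / write landmarks as JSON
#'
#' Schema: `{"space": "RAS", "units": "mm", "landmarks": {name: [x,y,z], ...}}`
#' with exactly the eight names of [landmark_set()]. Units other than mm are
#' rejected.
#'
#' @param path JSON file path.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    cn_stop(sprintf("file not found: %s", path), "couinaud_missing_file")
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$landmarks))
    cn_stop("landmark file has no 'landmarks' field", "couinaud_bad_landmark_file")
  units <- if (is.null(x$units)) "mm" else x$units
  if (!identical(tolower(units), "mm"))
    cn_stop(sprintf("landmark units must be mm, got '%s'", units),
            "couinaud_bad_units")
  landmark_set(lapply(x$landmarks, as.numeric),
               space = if (is.null(x$space)) "RAS" else x$space)
}

#' @param landmarks a `liver_landmarks` object.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- as_landmarks(landmarks)
  out <- list(space = "RAS", units = "mm",
              landmarks = landmarks[landmark_names()])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- reports ----------------------------------------------------------------

#' Write a segment report to CSV and/or JSON
#'
#' The CSV holds one row per segment plus a whole-liver row, in a stable
#' column order. The JSON additionally carries any audit metadata attached to
#' the report (plane geometry, parameters, tool version).
#'
#' @param report a `segment_report` data frame (see [segment_volumes()]).
#' @param path output path; format chosen by extension (.csv or .json).
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    out <- list(report = as.data.frame(report),
                audit = attr(report, "audit"))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    cn_stop(sprintf("unsupported report extension '.%s' (use .csv or .json)", ext),
            "couinaud_bad_extension")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    cn_stop(sprintf("file not found: %s", path), "couinaud_missing_file")
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    as.data.frame(x$report)
  } else {
    cn_stop(sprintf("unsupported report extension '.%s'", ext),
            "couinaud_bad_extension")
  }
  df$segment <- as.character(df$segment)
  class(df) <- c("segment_report", "data.frame")
  df
}

#' Read a paired-measurement table (columns id, value_a, value_b)
#' @param path CSV path.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path))
    cn_stop(sprintf("file not found: %s", path), "couinaud_missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("value_a", "value_b")
  if (!all(need %in% names(df)))
    cn_stop("pairs CSV must have columns value_a and value_b",
            "couinaud_bad_pairs")
  df
}
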