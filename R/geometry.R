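#' Intersegmental plane geometry
#'
#' The Couinaud partition is driven by five oriented planes derived from the
#' eight anatomical landmarks. The vertical (hemiliver and sectional) planes
#' all contain the inferior vena cava (IVC) axis; the two transverse planes
#' are perpendicular to that axis through the right and left portal vein
#' landmarks. An oriented plane is a point, a unit normal and a name; the
#' signed distance of a point to the plane is positive on the oriented side.
#'
#' @name plane-geometry
NULL

unitize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) cn_stop("cannot normalize a zero vector", "couinaud_degenerate_axis")
  v / n
}

oriented_plane <- function(point, normal, name) {
  structure(list(point = as.numeric(point), normal = as.numeric(normal),
                 name = as.character(name)),
            class = "oriented_plane")
}

#' @export
print.oriented_plane <- function(x, ...) {
  cat(sprintf("<plane '%s'> point (%.2f, %.2f, %.2f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$name, x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' IVC axis from the two vena cava landmarks
#'
#' @param landmarks a `liver_landmarks` object (see [landmark_set()]).
#' @return list with `point` (the inferior IVC landmark, mm) and `direction`
#'   (unit vector toward the superior IVC landmark).
#' @export
ivc_axis_of <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  p0 <- landmarks$ivc_inferior
  v <- landmarks$ivc_superior - p0
  if (sqrt(sum(v * v)) < 1e-9)
    cn_stop("IVC landmarks coincide: axis undefined", "couinaud_degenerate_axis")
  list(point = as.numeric(p0), direction = unitize(v))
}

# Deterministic orthonormal basis of the plane orthogonal to unit vector d.
axis_basis <- function(d) {
  ref <- diag(3)[, which.min(abs(d))]
  e1 <- unitize(ref - sum(ref * d) * d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Least-squares plane through an axis
#'
#' Among all planes containing the given axis, finds the one minimizing the
#' sum of squared distances to the target points (closed form: the normal is
#' the smallest eigenvector of the 2-by-2 scatter of the target offsets
#' expressed in the axis-orthogonal basis). The normal is then flipped, if
#' needed, so that `orient_toward` lies on the requested side.
#'
#' @param axis list with `point` and unit `direction`, as from [ivc_axis_of()].
#' @param targets numeric matrix (n x 3) or length-3 vector of target points, mm.
#' @param orient_toward point (mm) that must lie on the `orient_sign` side.
#' @param orient_sign +1 or -1.
#' @param name plane name carried into the result.
#' @return an `oriented_plane` whose point is the axis point.
#' @export
fit_axis_plane <- function(axis, targets, orient_toward, orient_sign = 1, name = "plane") {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3, byrow = TRUE)
  if (nrow(targets) < 1) cn_stop("at least one target point required",
                                 "couinaud_no_targets")
  d <- unitize(axis$direction)
  b <- axis_basis(d)
  off <- sweep(targets, 2, axis$point)
  u <- cbind(off %*% b$e1, off %*% b$e2)
  if (all(sqrt(rowSums(u^2)) < 1e-6))
    cn_stop("all targets lie on the axis: plane undefined",
            "couinaud_degenerate_plane")
  S <- crossprod(u)
  ev <- eigen(S, symmetric = TRUE)
  w <- ev$vectors[, 2]                      # smallest-eigenvalue direction
  normal <- unitize(w[1] * b$e1 + w[2] * b$e2)
  pl <- oriented_plane(axis$point, normal, name)
  sd0 <- signed_distance(pl, orient_toward)
  if (abs(sd0) < 1e-6)
    cn_stop(sprintf("orientation point lies on fitted plane '%s': side ambiguous", name),
            "couinaud_ambiguous_orientation")
  if (sign(sd0) != sign(orient_sign)) pl$normal <- -pl$normal
  pl
}

#' Signed point-to-plane distance
#'
#' `normal . (point - plane$point)`, in mm; positive on the oriented side.
#' Vectorized over rows when `point` is an n x 3 matrix.
#'
#' @param plane an `oriented_plane`.
#' @param point length-3 vector or n x 3 matrix, mm.
#' @export
signed_distance <- function(plane, point) {
  if (is.null(dim(point))) return(sum(plane$normal * (point - plane$point)))
  as.numeric(sweep(point, 2, plane$point) %*% plane$normal)
}

#' Build the full intersegmental plane set
#'
#' Constructs the decision geometry from the eight landmarks:
#' \describe{
#'   \item{main plane}{(Cantlie) least-squares axis-plane through the middle
#'     hepatic vein and gallbladder fossa; positive side = patient right
#'     (oriented toward the right hepatic vein).}
#'   \item{right plane}{axis-plane through the right hepatic vein; positive =
#'     anterior (toward the gallbladder fossa).}
#'   \item{left plane}{axis-plane through the umbilical fissure; positive =
#'     medial (toward the middle hepatic vein).}
#'   \item{portal planes}{perpendicular to the IVC axis through the right and
#'     left portal vein landmarks; positive = superior.}
#' }
#'
#' @inheritParams ivc_axis_of
#' @param caudate_radius_mm radius (mm) around the IVC axis assigned to the
#'   caudate lobe (segment 1) before any plane split; default 30.
#' @return a `plane_set` object.
#' @export
build_planes <- function(landmarks, caudate_radius_mm = 30) {
  landmarks <- as_landmarks(landmarks)
  if (!is.numeric(caudate_radius_mm) || length(caudate_radius_mm) != 1 ||
      !is.finite(caudate_radius_mm) || caudate_radius_mm <= 0)
    cn_stop("caudate_radius_mm must be a positive number", "couinaud_bad_radius")
  ax <- ivc_axis_of(landmarks)
  main <- fit_axis_plane(ax, rbind(landmarks$middle_hepatic_vein,
                                   landmarks$gallbladder_fossa),
                         orient_toward = landmarks$right_hepatic_vein,
                         name = "main")
  right <- fit_axis_plane(ax, landmarks$right_hepatic_vein,
                          orient_toward = landmarks$gallbladder_fossa,
                          name = "right")
  left <- fit_axis_plane(ax, landmarks$umbilical_fissure,
                         orient_toward = landmarks$middle_hepatic_vein,
                         name = "left")
  portal <- function(point, name) {
    pl <- oriented_plane(point, ax$direction, name)
    if (signed_distance(pl, landmarks$ivc_superior) < 0) pl$normal <- -pl$normal
    pl
  }
  structure(list(axis_point = ax$point,
                 axis_direction = ax$direction,
                 main_plane = main,
                 right_plane = right,
                 left_plane = left,
                 right_portal_plane = portal(landmarks$right_portal_vein, "right_portal"),
                 left_portal_plane = portal(landmarks$left_portal_vein, "left_portal"),
                 caudate_radius_mm = caudate_radius_mm),
            class = "plane_set")
}

#' @export
print.plane_set <- function(x, ...) {
  cat("Couinaud intersegmental plane set\n")
  cat(sprintf("  IVC axis: point (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  cat(sprintf("  caudate radius: %.1f mm\n", x$caudate_radius_mm))
  for (nm in c("main_plane", "right_plane", "left_plane",
               "right_portal_plane", "left_portal_plane")) {
    cat("  "); print(x[[nm]])
  }
  invisible(x)
}

#' Serialize a plane set for audit output
#'
#' @param planes a `plane_set`.
#' @return a plain list (JSON-ready) with axis, planes and caudate radius.
#' @export
plane_set_audit <- function(planes) {
  pl <- function(p) list(point = p$point, normal = p$normal)
  list(ivc_axis = list(point = planes$axis_point, direction = planes$axis_direction),
       main_plane = pl(planes$main_plane),
       right_plane = pl(planes$right_plane),
       left_plane = pl(planes$left_plane),
       right_portal_plane = pl(planes$right_portal_plane),
       left_portal_plane = pl(planes$left_portal_plane),
       caudate_radius_mm = planes$caudate_radius_mm)
}
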