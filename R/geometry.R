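# Tolerances for degenerate geometry and frame orthonormality.
# mm-scale anatomy in double precision: collinearity is flagged when the
# triangle spanned by three landmarks has area below 1e-6 mm^2; unit length
# and orthogonality of frame vectors are enforced to 1e-9.
.gv_tol <- list(area = 1e-6, ortho = 1e-9)

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < .gv_tol$ortho) {
    rlang::abort(
      sprintf("degenerate geometry: %s has (near) zero length", what),
      class = "gv_degenerate_geometry"
    )
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Construct an oriented plane with an in-plane 2D frame
#'
#' A plane is stored as an origin point plus a right-handed orthonormal frame
#' `(u, v, normal)`. The in-plane axes `u` and `v` give every projected point
#' well-defined 2D slice coordinates in millimetres.
#'
#' @param origin Numeric length-3 point on the plane (mm).
#' @param u,v Numeric length-3 in-plane axis vectors; they are checked, not
#'   re-orthogonalised.
#' @return An object of class `gv_plane` with elements `origin`, `u`, `v`,
#'   `normal`.
#' @export
new_plane <- function(origin, u, v) {
  u <- unitize(u, "u_axis")
  v <- unitize(v, "v_axis")
  if (abs(sum(u * v)) > 1e-9) {
    rlang::abort("u_axis and v_axis are not orthogonal",
      class = "gv_degenerate_geometry"
    )
  }
  n <- cross3(u, v)
  structure(
    list(origin = as.numeric(origin), u = u, v = v, normal = n),
    class = "gv_plane"
  )
}

#' @export
print.gv_plane <- function(x, ...) {
  cat("<gv_plane>\n")
  cat("  origin:", sprintf("%.3f", x$origin), "mm\n")
  cat("  u     :", sprintf("%.6f", x$u), "\n")
  cat("  v     :", sprintf("%.6f", x$v), "\n")
  cat("  normal:", sprintf("%.6f", x$normal), "\n")
  invisible(x)
}

#' Scapular plane through three scapular landmarks
#'
#' The scapular plane is defined by the inferior tip of the scapular body,
#' the center of the glenoid surface, and the medial pole of the scapula
#' (root of the scapular spine). The returned plane has its origin at the
#' glenoid center.
#'
#' @param points Named list or 3-row matrix with rows/elements
#'   `inferior_angle`, `glenoid_center`, `medial_point` (mm).
#' @return A [new_plane()] object containing all three landmarks.
#' @export
scapular_plane <- function(points) {
  p <- lapply(c("inferior_angle", "glenoid_center", "medial_point"), function(nm) {
    pt <- if (is.matrix(points)) points[nm, ] else points[[nm]]
    if (is.null(pt) || length(pt) != 3 || !all(is.finite(pt))) {
      rlang::abort(sprintf("landmark '%s' missing or non-finite", nm),
        class = "gv_missing_landmark"
      )
    }
    as.numeric(pt)
  })
  names(p) <- c("inferior_angle", "glenoid_center", "medial_point")
  a <- p$inferior_angle - p$glenoid_center
  b <- p$medial_point - p$glenoid_center
  cr <- cross3(a, b)
  if (vnorm(cr) / 2 < .gv_tol$area) {
    rlang::abort(
      paste(
        "degenerate geometry: inferior_angle, glenoid_center and",
        "medial_point are collinear or coincident"
      ),
      class = "gv_degenerate_geometry"
    )
  }
  normal <- cr / vnorm(cr)
  u <- unitize(b, "glenoid_center - medial_point axis")
  v <- cross3(normal, u)
  new_plane(p$glenoid_center, u, v)
}

#' Three-dimensionally corrected slice
#'
#' The corrected slice is the plane containing the glenoid center and the
#' medial pole of the scapula, perpendicular to the scapular plane. Its
#' in-plane frame is anatomical: `u` points medial-to-lateral (from
#' `medial_point` toward `glenoid_center`) and `v` points
#' posterior-to-anterior, resolved from the anterior/posterior rim labels so
#' that the frame does not depend on scanner axes or side.
#'
#' @param points Named list or matrix of landmarks including
#'   `glenoid_center`, `medial_point`, `anterior_rim`, `posterior_rim`.
#' @param scap_plane The scapular plane from [scapular_plane()].
#' @return A [new_plane()] object with origin at the glenoid center.
#' @export
corrected_slice <- function(points, scap_plane) {
  get <- function(nm) {
    pt <- if (is.matrix(points)) points[nm, ] else points[[nm]]
    if (is.null(pt) || length(pt) != 3 || !all(is.finite(pt))) {
      rlang::abort(sprintf("landmark '%s' missing or non-finite", nm),
        class = "gv_missing_landmark"
      )
    }
    as.numeric(pt)
  }
  gc <- get("glenoid_center")
  mp <- get("medial_point")
  ar <- get("anterior_rim")
  pr <- get("posterior_rim")
  axis <- gc - mp
  if (vnorm(axis) < 1e-6) {
    rlang::abort(
      "degenerate geometry: glenoid_center and medial_point coincide",
      class = "gv_degenerate_geometry"
    )
  }
  u <- axis / vnorm(axis)
  # the slice contains u and is perpendicular to the scapular plane, so its
  # second in-plane axis is the scapular plane's normal
  v <- unitize(scap_plane$normal, "slice v_axis")
  if (abs(sum(u * v)) > 1e-9) {
    # guard: u must lie in the scapular plane
    v <- unitize(v - sum(u * v) * u, "slice v_axis")
  }
  # orient v anteriorly: projected anterior rim must not lie posterior to
  # the projected posterior rim
  if (sum((ar - pr) * v) < 0) v <- -v
  new_plane(gc, u, v)
}

#' Project 3D points into a plane's 2D slice coordinates
#'
#' Orthogonal projection onto the plane, expressed in the plane's `(u, v)`
#' frame. The round trip `origin + x*u + y*v` reconstructs the in-plane
#' component of the input exactly.
#'
#' @param points Numeric length-3 vector, or a matrix with 3 columns
#'   (one point per row).
#' @param plane A [new_plane()] object.
#' @return A numeric vector `c(x, y)` or a 2-column matrix of slice
#'   coordinates (mm).
#' @export
project_to_slice <- function(points, plane) {
  if (!inherits(plane, "gv_plane")) {
    rlang::abort("`plane` must be a gv_plane object")
  }
  if (is.matrix(points)) {
    rel <- sweep(points, 2, plane$origin)
    out <- cbind(x = rel %*% plane$u, y = rel %*% plane$v)
    colnames(out) <- c("x", "y")
    rownames(out) <- rownames(points)
    return(out)
  }
  rel <- as.numeric(points) - plane$origin
  c(x = sum(rel * plane$u), y = sum(rel * plane$v))
}

#' Reconstruct a 3D point from slice coordinates
#'
#' @param xy Numeric length-2 slice coordinates (mm).
#' @param plane A [new_plane()] object.
#' @return Numeric length-3 world coordinates of the in-plane point.
#' @export
slice_to_world <- function(xy, plane) {
  plane$origin + xy[[1]] * plane$u + xy[[2]] * plane$v
}

#' Signed glenoid version angle in the corrected slice
#'
#' Computes the angle between the glenoid line (posterior rim to anterior
#' rim) and the line perpendicular to a reference axis, in degrees.
#' Retroversion is positive: the sign is positive when the posterior rim
#' lies medial to the anterior rim relative to the axis direction
#' (`axis_origin` to `axis_end`, medial to lateral). The anatomical labels,
#' not the geometry, carry the sign: swapping which endpoint is called
#' anterior negates the result.
#'
#' @param glenoid_ant,glenoid_post 2D slice coordinates of the anterior and
#'   posterior glenoid rim (mm).
#' @param axis_origin,axis_end 2D slice coordinates of the reference axis
#'   (medial origin, lateral end).
#' @return Signed version angle in degrees, in (-90, 90); positive =
#'   retroversion, negative = anteversion.
#' @export
signed_version_angle <- function(glenoid_ant, glenoid_post, axis_origin, axis_end) {
  g <- as.numeric(glenoid_ant) - as.numeric(glenoid_post)
  a <- as.numeric(axis_end) - as.numeric(axis_origin)
  if (vnorm(g) < 1e-9) {
    rlang::abort("degenerate geometry: zero-length glenoid line",
      class = "gv_degenerate_geometry"
    )
  }
  if (vnorm(a) < 1e-9) {
    rlang::abort("degenerate geometry: zero-length reference axis",
      class = "gv_degenerate_geometry"
    )
  }
  g <- g / vnorm(g)
  a <- a / vnorm(a)
  p <- c(-a[2], a[1]) # perpendicular to the axis
  # acute angle between the glenoid line and the perpendicular line
  theta <- atan2(abs(g[1] * p[2] - g[2] * p[1]), abs(sum(g * p))) * 180 / pi
  s <- sign(sum(g * a)) # posterior rim medial of anterior rim => positive
  s * theta
}
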