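#' Fit the shoot coordinate frame from the segmented stem
#'
#' Builds the rigid transform placing the shoot in its own coordinate system:
#' the origin is the centroid of the stem points, the Z axis is the stem's
#' least-squares central axis (first principal direction of the stem points,
#' sign chosen so that `up` points toward +Z), and the X and Y axes are the
#' first and second principal components of all shoot points projected onto
#' the plane normal to Z. After [apply_frame()], greater `z` means higher on
#' the shoot, so organ height comparisons reduce to z-value comparisons.
#'
#' X sign is fixed so the highest shoot point has a nonnegative first
#' projected score; Y is `Z x X` so the rotation is proper (det = +1).
#'
#' @param cloud a [labeled_cloud()] (all shoot points).
#' @param stem_set integer indices of stem points (>= 3, not all coincident).
#' @param up a direction with positive dot product onto the upward stem axis,
#'   e.g. `sn - s0`; defaults to `c(0, 0, 1)`.
#' @return an object of class `shoot_frame` with fields `origin` and
#'   `rotation` (3x3, rows are the new X, Y, Z axes).
#' @export
fit_frame <- function(cloud, stem_set, up = c(0, 0, 1)) {
  stem_set <- as.integer(stem_set)
  if (length(stem_set) < 3L) stop("need at least 3 stem points")
  sp <- cloud$coords[stem_set, , drop = FALSE]
  origin <- colMeans(sp)
  sc <- sweep(sp, 2, origin)
  cv <- crossprod(sc) / nrow(sc)
  if (sum(diag(cv)) < 1e-18) stop("degenerate axis: stem points are coincident")
  z_axis <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  if (sum(z_axis * up) < 0) z_axis <- -z_axis

  q <- sweep(cloud$coords, 2, origin)
  h <- as.vector(q %*% z_axis)
  proj <- q - outer(h, z_axis)
  pcv <- crossprod(proj) / nrow(proj)
  x_axis <- eigen(pcv, symmetric = TRUE)$vectors[, 1L]
  x_axis <- .unit(x_axis - sum(x_axis * z_axis) * z_axis)
  score_top <- sum(proj[which.max(h), ] * x_axis)
  if (score_top < -1e-9) {
    x_axis <- -x_axis
  } else if (abs(score_top) <= 1e-9 && sum(as.vector(proj %*% x_axis)^3) < 0) {
    x_axis <- -x_axis
  }
  y_axis <- c(z_axis[2] * x_axis[3] - z_axis[3] * x_axis[2],
              z_axis[3] * x_axis[1] - z_axis[1] * x_axis[3],
              z_axis[1] * x_axis[2] - z_axis[2] * x_axis[1])
  rotation <- rbind(x_axis, y_axis, z_axis, deparse.level = 0)
  structure(list(origin = origin, rotation = rotation), class = "shoot_frame")
}

#' @export
print.shoot_frame <- function(x, ...) {
  cat("<shoot_frame>\n  origin:", sprintf("%.3f", x$origin), "\n")
  cat("  Z axis:", sprintf("%.4f", x$rotation[3, ]), "\n")
  invisible(x)
}

#' Transform a cloud into a shoot frame
#'
#' Applies the rigid map `p -> R (p - origin)`; labels are carried unchanged
#' and normals, when present, are rotated.
#'
#' @param cloud a [labeled_cloud()].
#' @param frame a [fit_frame()] result.
#' @return the transformed [labeled_cloud()].
#' @export
apply_frame <- function(cloud, frame) {
  stopifnot(inherits(frame, "shoot_frame"))
  R <- frame$rotation
  err <- max(abs(R %*% t(R) - diag(3)))
  if (err > 1e-8) stop("frame rotation is not orthonormal")
  cloud$coords <- sweep(cloud$coords, 2, frame$origin) %*% t(R)
  if (!is.null(cloud$normals)) cloud$normals <- cloud$normals %*% t(R)
  cloud
}

#' Serialize a shoot frame to JSON
#' @param frame a [fit_frame()] result.
#' @return JSON string.
#' @export
frame_to_json <- function(frame) {
  jsonlite::toJSON(list(origin = frame$origin,
                        rotation = frame$rotation), digits = NA)
}
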