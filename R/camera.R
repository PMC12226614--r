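#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels, inside the image.
#' @param width,height image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (width < 1 || height < 1) stop("invalid image size")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d px, fx=%.2f fy=%.2f, c=(%.2f, %.2f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

intrinsics_matrix <- function(cam) {
  matrix(c(cam$fx, 0, cam$cx,
           0, cam$fy, cam$cy,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Approximate intrinsics from image size and field of view
#'
#' When the true camera calibration is unknown (smartphone capture), the
#' intrinsic matrix is approximated by placing the principal point at the
#' image center and deriving a shared focal length from a horizontal
#' field-of-view assumption: `fx = (width/2) / tan(fov/2)`. The 53 degree
#' default matches a typical smartphone main camera.
#'
#' @param width,height image size in pixels (>= 1).
#' @param fov_deg horizontal field of view in degrees, in (1, 179).
#' @return A [camera_intrinsics()].
#' @export
approximate_intrinsics <- function(width, height, fov_deg = 53) {
  if (width < 1 || height < 1) stop("invalid image size: width/height must be >= 1")
  if (fov_deg <= 1 || fov_deg >= 179) stop("fov_deg must lie in (1, 179) degrees")
  f <- (width / 2) / tan(fov_deg * pi / 360)
  camera_intrinsics(fx = f, fy = f, cx = width / 2, cy = height / 2,
                    width = width, height = height)
}

#' Similarity pose (rotation, translation, global scale)
#'
#' The camera-frame mapping applied to world points is
#' `X_cam = R %*% (s * X_w) + T`: a single global scale `s` applied before
#' the rigid transform. Homogeneous normalization by camera depth is done
#' separately at projection time.
#'
#' @param rotation 3 x 3 rotation matrix, or a length-3 axis-angle vector.
#' @param translation length-3 translation (mm).
#' @param scale positive global scale.
#' @return An object of class `similarity_pose`.
#' @export
similarity_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  if (length(rotation) == 3L) rotation <- rotvec_to_matrix(rotation)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  dev <- max(abs(crossprod(rotation) - diag(3)))
  if (dev > 1e-4) stop("rotation is not orthonormal")
  if (dev > 1e-8) rotation <- orthonormalize_rotation(rotation)
  if (abs(det(rotation) - 1) > 1e-8) stop("rotation must have determinant +1")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "similarity_pose")
}

#' @export
print.similarity_pose <- function(x, ...) {
  rv <- matrix_to_rotvec(x$rotation)
  cat(sprintf(
    "similarity_pose: angle %.2f deg, t = (%.2f, %.2f, %.2f) mm, s = %.4f\n",
    sqrt(sum(rv^2)) * 180 / pi,
    x$translation[1], x$translation[2], x$translation[3], x$scale))
  invisible(x)
}

# Rodrigues' rotation formula and its inverse.
rotvec_to_matrix <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3) + skew(rv))   # first-order near identity
  k <- rv / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: axis from R + I
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    j <- which.max(axis)
    if (A[j, 1] < 0 && j != 1) axis[1] <- -axis[1]
    s <- sign(A[j, ]); s[s == 0] <- 1
    axis <- axis * s / s[j]
    axis <- axis / sqrt(sum(axis^2))
    return(axis * th)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w / (2 * sin(th)) * th
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

orthonormalize_rotation <- function(R) {
  s <- svd(R)
  U <- s$u; V <- s$v
  D <- diag(c(1, 1, det(U %*% t(V))))
  U %*% D %*% t(V)
}

# Camera-frame coordinates of world points under a similarity pose (N x 3).
to_camera_frame <- function(points3d, pose) {
  p <- as.matrix(points3d)
  sweep(p * pose$scale, 2, c(0, 0, 0)) %*% t(pose$rotation) +
    matrix(pose$translation, nrow(p), 3, byrow = TRUE)
}

#' 2D landmark set
#'
#' Image-space landmark coordinates with optional per-landmark predicted
#' variance and an in-bounds mask. Convention: origin at the top-left
#' corner, `u` rightward, `v` downward, 0-based, pixel centers at integer
#' coordinates.
#'
#' @param points L x 2 matrix of (u, v) pixel coordinates.
#' @param sigma2 optional length-L vector of predicted variances (px^2),
#'   strictly positive.
#' @param in_bounds optional length-L logical mask.
#' @param visible optional length-L logical occlusion mask (TRUE when the
#'   vertex is the frontmost surface at its pixel).
#' @return An object of class `landmarks2d`.
#' @export
landmarks2d <- function(points, sigma2 = NULL, in_bounds = NULL,
                        visible = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be L x 2")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  if (!is.null(sigma2)) {
    sigma2 <- as.numeric(sigma2)
    if (length(sigma2) != nrow(points)) stop("sigma2 length mismatch")
    if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  }
  structure(list(points = points, sigma2 = sigma2,
                 in_bounds = in_bounds, visible = visible),
            class = "landmarks2d")
}

#' @export
print.landmarks2d <- function(x, ...) {
  cat(sprintf("landmarks2d: %d points%s%s\n", nrow(x$points),
              if (is.null(x$sigma2)) "" else ", with sigma2",
              if (is.null(x$in_bounds)) ""
              else sprintf(", %d in bounds", sum(x$in_bounds))))
  invisible(x)
}

#' Project 3D points into the image plane
#'
#' Projects world points through a similarity pose and pinhole intrinsics:
#' the scaled, rotated and translated point `(X, Y, Z)` maps to
#' `u = fx * X/Z + cx`, `v = fy * Y/Z + cy`. All points must have positive
#' camera-frame depth.
#'
#' @param points3d N x 3 matrix of world coordinates (mm).
#' @param pose a [similarity_pose()].
#' @param cam a [camera_intrinsics()].
#' @return A [landmarks2d()] with the in-bounds mask set from the image size.
#' @export
project <- function(points3d, pose, cam) {
  pc <- to_camera_frame(points3d, pose)
  z <- pc[, 3]
  bad <- which(z <= 0)
  if (length(bad))
    stop("behind-camera: non-positive depth for point(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  u <- cam$fx * pc[, 1] / z + cam$cx
  v <- cam$fy * pc[, 2] / z + cam$cy
  inb <- u >= 0 & u <= cam$width - 1 & v >= 0 & v <= cam$height - 1
  landmarks2d(cbind(u, v), in_bounds = inb)
}

# 3 x 4 projection matrix K [sR | T]; used by the pose-jump quality metric.
projection_matrix <- function(pose, cam) {
  intrinsics_matrix(cam) %*% cbind(pose$scale * pose$rotation,
                                   pose$translation)
}
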