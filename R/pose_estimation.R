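#' Sparse 2D-3D correspondence set
#'
#' Links template vertex ids to image locations. Pose estimation needs at
#' least four correspondences.
#'
#' @param vertex_id integer vector of 1-based template vertex ids (unique).
#' @param u,v numeric image coordinates (px).
#' @return A data frame of class `correspondence_set`.
#' @export
correspondence_set <- function(vertex_id, u, v) {
  vertex_id <- as.integer(vertex_id)
  if (anyDuplicated(vertex_id)) stop("vertex ids must be unique")
  if (length(vertex_id) < 1L) stop("need at least one correspondence")
  structure(data.frame(vertex_id = vertex_id, u = as.numeric(u),
                       v = as.numeric(v)),
            class = c("correspondence_set", "data.frame"))
}

#' Read correspondences from a JSON list of \{vertex_id, u, v\}
#' @param path JSON file path.
#' @return A [correspondence_set()].
#' @export
read_correspondences <- function(path) {
  d <- jsonlite::fromJSON(path)
  correspondence_set(d$vertex_id, d$u, d$v)
}

pose_to_params <- function(pose) {
  c(matrix_to_rotvec(pose$rotation), pose$translation, log(pose$scale))
}

params_to_pose <- function(p) {
  # clamp the log-scale so finite-difference probes cannot overflow
  ls <- min(max(p[7], -30), 30)
  if (!is.finite(ls)) ls <- 0
  similarity_pose(rotation = rotvec_to_matrix(p[1:3]),
                  translation = p[4:6], scale = exp(ls))
}

default_pose_init <- function(points3d, scale = 1) {
  ctr <- colMeans(points3d)
  r <- sqrt(max(rowSums(sweep(points3d, 2, ctr)^2)))
  # centroid on the optical axis at depth 4x the bounding radius
  similarity_pose(rotation = diag(3),
                  translation = c(0, 0, 4 * max(r, 1)) - scale * ctr,
                  scale = scale)
}

# Reprojection residual vector (u then v, stacked per point) with a soft
# barrier against non-positive depth so LM always sees finite values.
reproj_residuals <- function(p, X, uv, cam, w = NULL) {
  pose <- params_to_pose(p)
  pc <- to_camera_frame(X, pose)
  z <- pc[, 3]
  zs <- pmax(z, 1e-6)
  u <- cam$fx * pc[, 1] / zs + cam$cx
  v <- cam$fy * pc[, 2] / zs + cam$cy
  r <- c(u - uv[, 1], v - uv[, 2])
  pen <- pmax(0, 1e-3 - z) * 1e6
  r <- r + c(pen, pen)
  if (!is.null(w)) r <- r * sqrt(rep(w, 2L))
  r
}

#' Estimate a similarity pose from sparse 2D-3D correspondences
#'
#' Iteratively refines rotation (axis-angle), translation and global scale
#' to minimize the sum of squared reprojection errors between the 2D
#' landmarks and the projected 3D template points, using damped
#' (Levenberg-Marquardt) nonlinear least squares. At least four
#' correspondences are required; the recovered pose is defined up to the
#' scale/depth ambiguity inherent in a fixed, approximate intrinsic matrix
#' (the reprojection, not the raw pose parameters, is the reliable output).
#'
#' @param corr a [correspondence_set()], or anything coercible with columns
#'   `vertex_id`, `u`, `v`.
#' @param template_points V x 3 matrix of template vertex coordinates (mm).
#' @param cam a [camera_intrinsics()].
#' @param init optional [similarity_pose()] starting point; by default the
#'   template centroid is placed on the optical axis at four bounding radii.
#' @param weights optional per-correspondence nonnegative weights.
#' @param max_iter maximum LM iterations.
#' @return A [similarity_pose()] with attributes `rms_px` (achieved RMS
#'   reprojection error), `cost_trace` (residual sum of squares per
#'   iteration) and `n_iter`.
#' @export
estimate_pose <- function(corr, template_points, cam, init = NULL,
                          weights = NULL, max_iter = 200L) {
  if (nrow(corr) < 4L)
    stop("insufficient-correspondences: pose estimation needs at least 4, got ",
         nrow(corr))
  ids <- corr$vertex_id
  if (min(ids) < 1L || max(ids) > nrow(template_points))
    stop("correspondence vertex ids out of range")
  X <- template_points[ids, , drop = FALSE]
  uv <- cbind(corr$u, corr$v)
  # With no warm start the problem is prone to local minima far from the
  # true orientation; run LM from a small set of canonical initial
  # rotations and keep the best solution.
  starts <- if (is.null(init)) {
    base <- default_pose_init(template_points)
    lapply(list(c(0, 0, 0), c(pi, 0, 0), c(pi / 2, 0, 0), c(-pi / 2, 0, 0),
                c(0, pi, 0), c(0, pi / 2, 0), c(0, -pi / 2, 0),
                c(pi, 0, pi / 2), c(pi, 0, -pi / 2)),
           function(rv) {
             ctr <- colMeans(template_points)
             R <- rotvec_to_matrix(rv)
             similarity_pose(R, base$translation + ctr - as.numeric(R %*% ctr),
                             base$scale)
           })
  } else list(init)
  fit <- NULL
  for (st in starts) {
    f <- minpack.lm::nls.lm(
      par = pose_to_params(st), fn = reproj_residuals, X = X, uv = uv,
      cam = cam, w = weights,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-14, ptol = 1e-12))
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
    if (fit$deviance < 1e-12) break
  }
  if (!all(is.finite(fit$par)) || !is.finite(fit$deviance))
    stop("convergence-failure: pose optimization produced non-finite values")
  pose <- params_to_pose(fit$par)
  res <- reproj_residuals(fit$par, X, uv, cam, w = weights)
  attr(pose, "rms_px") <- sqrt(mean(res^2))
  attr(pose, "cost_trace") <- fit$rsstrace
  attr(pose, "n_iter") <- fit$niter
  pose
}
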