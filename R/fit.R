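#' Control parameters for flip-flop fitting
#'
#' @param pose_tol,shape_tol relative parameter-step convergence
#'   tolerances of the pose and shape sub-problems.
#' @param max_outer_iters maximum number of outer alternations.
#' @param point_weights optional per-landmark nonnegative weights (at
#'   least 4 must be strictly positive); used to emphasize regions such
#'   as the plate-contact ridges.
#' @param use_sigma_weighting additionally weight landmarks by
#'   `1/sigma2` when the landmark set carries predicted variances.
#' @param shape_prior_lambda Tikhonov weight on `sum(w_i^2 / variance_i)`
#'   guarding against out-of-distribution extrapolation (0 disables).
#' @param init_pose optional [similarity_pose()] starting pose.
#' @param init_coef optional starting shape coefficients.
#' @param n_restarts maximum number of perturbed-pose restarts taken when
#'   the alternation settles with a residual above `restart_rmse`.
#' @param restart_rmse reprojection RMSE (px) under which a solution is
#'   accepted without restarts.
#' @return An object of class `flipflop_control`.
#' @export
flipflop_control <- function(pose_tol = 1e-6, shape_tol = 1e-6,
                             max_outer_iters = 200L, point_weights = NULL,
                             use_sigma_weighting = FALSE,
                             shape_prior_lambda = 1e-3,
                             init_pose = NULL, init_coef = NULL,
                             n_restarts = 2L, restart_rmse = 1e-3) {
  if (pose_tol <= 0 || shape_tol <= 0) stop("tolerances must be positive")
  if (!is.null(point_weights)) {
    if (any(point_weights < 0)) stop("point weights must be >= 0")
    if (sum(point_weights > 0) < 4L)
      stop("at least 4 landmarks must have positive weight")
  }
  structure(list(pose_tol = pose_tol, shape_tol = shape_tol,
                 max_outer_iters = as.integer(max_outer_iters),
                 point_weights = point_weights,
                 use_sigma_weighting = use_sigma_weighting,
                 shape_prior_lambda = shape_prior_lambda,
                 init_pose = init_pose, init_coef = init_coef,
                 n_restarts = as.integer(n_restarts),
                 restart_rmse = restart_rmse),
            class = "flipflop_control")
}

# Component rows restricted to the landmark subset, as a (3*nsub) x k
# matrix in x1,y1,z1,... order, plus the subset mean.
subset_basis <- function(model, sub) {
  idx3 <- as.integer(rbind(3L * (sub - 1L) + 1L,
                           3L * (sub - 1L) + 2L,
                           3L * (sub - 1L) + 3L))
  list(mean = model$mean_shape[idx3],
       B = if (n_modes(model) > 0)
         t(model$components[, idx3, drop = FALSE]) else
           matrix(0, length(idx3), 0L),
       idx3 = idx3)
}

subset_vertices <- function(sb, w) {
  x <- sb$mean
  if (length(w)) x <- x + as.numeric(sb$B %*% w)
  unflatten_vertices(x)
}

# Weighted squared reprojection cost plus the shape prior; infinite when
# any landmark falls behind the camera (rejects such trial steps).
flipflop_cost <- function(pts3, pose, cam, obs, wts, w, lambda, variances) {
  pc <- to_camera_frame(pts3, pose)
  if (any(pc[, 3] <= 0)) return(Inf)
  pr <- project(pts3, pose, cam)
  r2 <- rowSums((pr$points - obs)^2)
  cost <- sum(wts * r2)
  if (lambda > 0 && length(w))
    cost <- cost + lambda * sum(w^2 / variances)
  cost
}

#' Fit the shape model to 2D landmarks by flip-flop alternation
#'
#' Alternates between (a) a pose step - damped nonlinear least squares
#' over rotation, translation and global scale against the currently
#' reconstructed shape ([estimate_pose()]) - and (b) a shape step -
#' damped Gauss-Newton over the eigenmode weights, solved jointly with
#' the global scale (which is linear in the camera frame at fixed
#' rotation and translation, and would otherwise stall the alternation
#' through its coupling to the model's size mode), plus an optional
#' Tikhonov prior.
#' Each sub-step is safeguarded by a step-halving line search so the
#' joint cost never increases. Fitting terminates when both
#' sub-problems' parameter updates fall below tolerance in the same
#' outer iteration, or when the joint cost stalls.
#'
#' @param landmarks a [landmarks2d()] over the model's landmark subset
#'   (one observation per subset vertex, in subset order).
#' @param model a [shape_model()] carrying a topology with a
#'   `landmark_subset`.
#' @param cam a [camera_intrinsics()].
#' @param control a [flipflop_control()].
#' @return An object of class `flipflop_fit`: `pose`, `coef`,
#'   `residual_rmse` (px), `per_landmark_residuals` (px), `outer_iters`,
#'   `converged`, `cost_trace`.
#' @export
fit_flipflop <- function(landmarks, model, cam,
                         control = flipflop_control()) {
  sub <- model$topology$landmark_subset
  if (is.null(sub) || !length(sub))
    stop("model topology lacks a landmark subset")
  obs <- landmarks$points
  if (nrow(obs) != length(sub))
    stop("topology error: expected ", length(sub), " landmarks, got ",
         nrow(obs))
  wts <- if (is.null(control$point_weights)) rep(1, nrow(obs))
  else as.numeric(control$point_weights)
  if (control$use_sigma_weighting && !is.null(landmarks$sigma2))
    wts <- wts / landmarks$sigma2
  usable <- sum(wts > 0)
  if (usable < 4L)
    stop("fewer than 4 usable landmarks (", usable, ")")

  sb <- subset_basis(model, sub)
  k <- n_modes(model)
  w <- if (!is.null(control$init_coef)) {
    if (length(control$init_coef) != k) stop("init_coef length mismatch")
    as.numeric(control$init_coef)
  } else numeric(k)
  lambda <- control$shape_prior_lambda
  vr <- model$variances

  corr <- correspondence_set(seq_len(length(sub)), obs[, 1], obs[, 2])

  run_alternation <- function(init_pose, w) {
  pts3 <- subset_vertices(sb, w)
  pose <- estimate_pose(corr, pts3, cam, init = init_pose, weights = wts)
  cost <- flipflop_cost(pts3, pose, cam, obs, wts, w, lambda, vr)
  if (!is.finite(cost)) {   # degenerate start: fall back to multi-start
    pose <- estimate_pose(corr, pts3, cam, weights = wts)
    cost <- flipflop_cost(pts3, pose, cam, obs, wts, w, lambda, vr)
  }
  trace <- cost
  converged <- FALSE
  stopped_on <- "max-iters"
  it <- 0L
  if (is.finite(cost)) for (it in seq_len(control$max_outer_iters)) {
    # (a) pose step at fixed shape; rejected if it raises the true cost
    # (its internal objective adds a depth barrier, so this can differ)
    p_old <- pose_to_params(pose)
    pose_try <- estimate_pose(corr, pts3, cam, init = pose, weights = wts)
    c_pose <- flipflop_cost(pts3, pose_try, cam, obs, wts, w, lambda, vr)
    if (is.finite(c_pose) && c_pose <= cost + 1e-12) {
      pose <- pose_try
      cost <- c_pose
    }
    p_new <- pose_to_params(pose)
    pose_step <- sqrt(sum((p_new - p_old)^2)) /
      (sqrt(sum(p_old^2)) + 1e-12)

    # (b) shape step at fixed rotation/translation: the camera-frame
    # landmark s*R*(mean + B w) + T is LINEAR in (alpha, nu) = (s, s*w)
    # before projection, so the weights are re-solved by damped
    # Gauss-Newton jointly with the scale, which otherwise couples to
    # the size mode of the model and stalls the alternation; the full
    # projective quotient-rule Jacobian is used (the depth derivative
    # matters most for the scale column); iterated until the inner
    # update stalls
    shape_step <- 0
    if (k > 0) {
      R <- pose$rotation
      n <- nrow(obs)
      Bx <- sb$B[seq(1, 3 * n, 3), , drop = FALSE]
      By <- sb$B[seq(2, 3 * n, 3), , drop = FALSE]
      Bz <- sb$B[seq(3, 3 * n, 3), , drop = FALSE]
      M <- unflatten_vertices(sb$mean)
      wv <- rep(wts, 2L)
      theta0_norm <- sqrt(pose$scale^2 * (1 + sum(w^2)))
      total_step <- 0
      for (inner in 1:25) {
        alpha <- pose$scale
        pc <- to_camera_frame(subset_vertices(sb, w), pose)
        z <- pc[, 3]
        # camera-frame derivatives wrt theta = (alpha, nu), with the full
        # projective quotient rule (the depth derivative matters most for
        # the scale column)
        RM <- M %*% t(R)                      # n x 3: R %*% mean_j
        RB <- lapply(1:3, function(d)
          R[d, 1] * Bx + R[d, 2] * By + R[d, 3] * Bz)
        Jx <- cbind(RM[, 1], RB[[1]])
        Jy <- cbind(RM[, 2], RB[[2]])
        Jz <- cbind(RM[, 3], RB[[3]])
        Au <- (Jx - (pc[, 1] / z) * Jz) * (cam$fx / z)
        Av <- (Jy - (pc[, 2] / z) * Jz) * (cam$fy / z)
        A <- rbind(Au, Av)
        pr0 <- cbind(cam$fx * pc[, 1] / z + cam$cx,
                     cam$fy * pc[, 2] / z + cam$cy)
        r <- c(obs[, 1] - pr0[, 1], obs[, 2] - pr0[, 2])
        theta <- c(alpha, alpha * w)
        AtWA <- crossprod(A, A * wv)
        rhs <- crossprod(A, r * wv)
        if (lambda > 0) {
          # prior on w = nu/alpha, linearized at the current alpha
          D <- c(0, lambda / (alpha^2 * vr))
          AtWA <- AtWA + diag(D, k + 1L)
          rhs <- rhs - D * theta
        }
        # minimum-norm Gauss-Newton step: the similarity-ambiguous
        # direction (scale vs depth) makes the normal matrix
        # rank-deficient, so invert through a truncated SVD
        sv <- svd(AtWA)
        keep <- sv$d > 1e-12 * sv$d[1L]
        dth <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                            ((crossprod(sv$u[, keep, drop = FALSE], rhs)) /
                               sv$d[keep]))
        # step-halving safeguard on the true (non-linearized) cost
        step <- 1
        moved <- FALSE
        while (step >= 1e-8) {
          th_try <- theta + step * dth
          if (th_try[1] > 1e-8) {
            w_try <- th_try[-1L] / th_try[1L]
            pose_try <- similarity_pose(pose$rotation, pose$translation,
                                        th_try[1L])
            pts_try <- subset_vertices(sb, w_try)
            c_try <- flipflop_cost(pts_try, pose_try, cam, obs, wts, w_try,
                                   lambda, vr)
            if (is.finite(c_try) && c_try <= cost + 1e-12) {
              w <- w_try
              pose <- pose_try
              pts3 <- pts_try
              cost <- c_try
              total_step <- total_step + sqrt(sum((step * dth)^2))
              moved <- TRUE
              break
            }
          }
          step <- step / 2
        }
        if (!moved || sqrt(sum((step * dth)^2)) <
              1e-3 * control$shape_tol * (theta0_norm + 1e-12)) break
      }
      shape_step <- total_step / (theta0_norm + 1e-12)
    } else {
      pts3 <- subset_vertices(sb, w)
      cost <- flipflop_cost(pts3, pose, cam, obs, wts, w, lambda, vr)
    }
    trace <- c(trace, cost)
    if (!is.finite(cost))
      stop("convergence-failure: non-finite flip-flop cost at iteration ", it)
    if (pose_step < control$pose_tol && shape_step < control$shape_tol) {
      converged <- TRUE
      stopped_on <- "parameter-step"
      break
    }
    # residual stall: both sub-problems have stopped improving the joint
    # cost; remaining parameter motion is reparameterization along the
    # scale/depth-ambiguous direction
    nprev <- length(trace)
    if (nprev >= 3L &&
          trace[nprev - 2L] - cost < 1e-10 * max(cost, 1)) {
      converged <- TRUE
      stopped_on <- "cost-stall"
      break
    }
  }
  list(pose = pose, w = w, pts3 = pts3, cost = cost, trace = trace,
       converged = converged, stopped_on = stopped_on, it = it)
  }

  # First attempt from the configured initialization; if the alternation
  # settles in a local minimum with a non-trivial residual, retry from
  # seeded small-rotation perturbations of the best pose found and keep
  # the lowest-cost solution.
  best <- run_alternation(control$init_pose, w)
  rms_of <- function(a) {
    if (!is.finite(a$cost)) return(Inf)
    pr <- project(a$pts3, a$pose, cam)
    sqrt(mean(rowSums((pr$points - obs)^2)))
  }
  if (control$n_restarts > 0L && rms_of(best) > control$restart_rmse) {
    for (rr in seq_len(control$n_restarts)) {
      rv <- local_rng(1000L + rr)(stats::rnorm(3, 0, 3 * pi / 180))
      pinit <- similarity_pose(rotvec_to_matrix(rv) %*% best$pose$rotation,
                               best$pose$translation, best$pose$scale)
      alt <- tryCatch(run_alternation(pinit, best$w),
                      error = function(e) NULL)
      if (!is.null(alt) && is.finite(alt$cost) && alt$cost < best$cost)
        best <- alt
      if (rms_of(best) <= control$restart_rmse) break
    }
  }
  if (!is.finite(best$cost))
    stop("convergence-failure: non-finite flip-flop cost")
  pose <- best$pose; w <- best$w; pts3 <- best$pts3
  trace <- best$trace; converged <- best$converged
  stopped_on <- best$stopped_on; it <- best$it

  pr <- project(pts3, pose, cam)
  res <- sqrt(rowSums((pr$points - obs)^2))
  structure(list(pose = pose, coef = w,
                 residual_rmse = sqrt(mean(res^2)),
                 per_landmark_residuals = res,
                 outer_iters = it, converged = converged,
                 stopped_on = stopped_on,
                 cost_trace = trace, model = model, cam = cam,
                 weights = wts, landmarks = landmarks),
            class = "flipflop_fit")
}

#' @export
print.flipflop_fit <- function(x, ...) {
  cat(sprintf(
    "flipflop_fit: %d modes, %d outer iterations (%sconverged)\n",
    length(x$coef), x$outer_iters, if (x$converged) "" else "NOT "))
  cat(sprintf("  reprojection RMSE: %.4f px over %d landmarks\n",
              x$residual_rmse, length(x$per_landmark_residuals)))
  print(x$pose)
  invisible(x)
}

#' @export
summary.flipflop_fit <- function(object, ...) {
  r <- object$per_landmark_residuals
  out <- list(residual_rmse = object$residual_rmse,
              residual_quantiles = stats::quantile(r, c(0, .25, .5, .75, 1)),
              outer_iters = object$outer_iters,
              converged = object$converged,
              coef = object$coef,
              cost_trace = object$cost_trace)
  class(out) <- "summary.flipflop_fit"
  out
}

#' @export
print.summary.flipflop_fit <- function(x, ...) {
  cat(sprintf("flip-flop fit: RMSE %.4f px in %d iterations (%sconverged)\n",
              x$residual_rmse, x$outer_iters, if (x$converged) "" else "NOT "))
  cat("  residual quantiles (px):\n")
  print(round(x$residual_quantiles, 4))
  cat(sprintf("  |coef|: %s\n",
              paste(sprintf("%.2f", utils::head(abs(x$coef), 8)),
                    collapse = " ")))
  invisible(x)
}

#' @export
coef.flipflop_fit <- function(object, ...) object$coef

#' @export
residuals.flipflop_fit <- function(object, ...) object$per_landmark_residuals

#' @export
fitted.flipflop_fit <- function(object, ...) {
  sub <- object$model$topology$landmark_subset
  sb <- subset_basis(object$model, sub)
  project(subset_vertices(sb, object$coef), object$pose, object$cam)
}

#' Reconstructed surface of a flip-flop fit
#' @param object a [fit_flipflop()] result.
#' @param ... unused.
#' @return The full reconstructed [tri_mesh()].
#' @export
predict.flipflop_fit <- function(object, ...) {
  predict(object$model, object$coef)
}

#' Single-image 3D reconstruction pipeline
#'
#' Runs the full pipeline on one image: predict 2D landmarks with their
#' uncertainties, fit the shape model by flip-flop alternation, and
#' reconstruct the 3D surface.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param predictor a trained [train_predictor()] model.
#' @param model a [shape_model()] whose landmark subset matches the
#'   predictor's landmark count.
#' @param cam a [camera_intrinsics()].
#' @param control a [flipflop_control()].
#' @return list with `mesh` (the reconstructed [tri_mesh()]) and `fit`
#'   (the [fit_flipflop()] result).
#' @export
reconstruct_from_image <- function(image, predictor, model, cam,
                                   control = flipflop_control()) {
  lm <- predict(predictor, image)
  if (nrow(lm$points) != length(model$topology$landmark_subset))
    stop("topology error: predictor landmark count (", nrow(lm$points),
         ") does not match the model's landmark subset (",
         length(model$topology$landmark_subset), ")")
  fit <- fit_flipflop(lm, model, cam, control)
  list(mesh = predict(fit), fit = fit)
}
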