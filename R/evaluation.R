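#' Correspondence-based surface error between two meshes
#'
#' Per-vertex Euclidean distances between two meshes in the same template
#' topology (not closest-point distances), summarized over an optional
#' vertex subset such as the plate contact region. Symmetric in its two
#' arguments.
#'
#' @param fitted,reference [tri_mesh()] objects with equal vertex counts.
#' @param region optional integer vertex subset.
#' @return list with `mean`, `max` (mm) and `per_vertex` distances.
#' @export
surface_error <- function(fitted, reference, region = NULL) {
  if (n_vertices(fitted) != n_vertices(reference))
    stop("topology error: vertex counts differ")
  d <- sqrt(rowSums((fitted$vertices - reference$vertices)^2))
  if (!is.null(region)) {
    if (!length(region)) stop("invalid-parameter: empty region")
    d <- d[region]
  }
  list(mean = mean(d), max = max(d), per_vertex = d)
}

new_scaling_curve <- function(df, metric) {
  stopifnot(all(c("size", "replicate", "error") %in% names(df)))
  structure(df, metric = metric, class = c("scaling_curve", "data.frame"))
}

#' Median error per size of a scaling curve
#' @param curve a `scaling_curve`.
#' @return data frame with `size` and `error` (median over replicates).
#' @export
curve_median <- function(curve) {
  agg <- stats::aggregate(error ~ size, data = as.data.frame(curve),
                          FUN = stats::median)
  agg[order(agg$size), ]
}

#' @export
plot.scaling_curve <- function(x, fit = NULL, ...) {
  d <- as.data.frame(x)
  graphics::plot(d$size, d$error, pch = 16, col = "grey50",
                 xlab = "training set size", ylab = attr(x, "metric"), ...)
  m <- curve_median(x)
  graphics::lines(m$size, m$error, lwd = 2)
  if (!is.null(fit)) {
    xs <- seq(min(d$size), max(d$size), length.out = 200)
    graphics::lines(xs, fit$a * exp(-fit$b * xs) + fit$c,
                    col = "firebrick", lty = 2)
    graphics::abline(h = fit$c, col = "firebrick", lty = 3)
  }
  invisible(x)
}

#' Model-size scaling experiment
#'
#' The shape-model analogue of a learning curve: for each training-set
#' size, build a PCA model (with the variance-truncation rule) on a
#' seeded subset of the mesh family and measure the mean reconstruction
#' error on held-out meshes, replicated over seeds. Retained variance
#' fractions per size are recorded in the `retained_variance` attribute.
#'
#' @param meshes list of [tri_mesh()] in template correspondence.
#' @param sizes increasing training-set sizes.
#' @param variance_threshold PCA truncation threshold (default 99.9%).
#' @param heldout_fraction fraction of the family held out per replicate.
#' @param n_replicates number of seeded replicates.
#' @param region optional vertex subset for the error.
#' @param seed global seed.
#' @param heldout evaluate on held-out meshes (default) or on the
#'   training meshes themselves.
#' @return A `scaling_curve` data frame (size, replicate, error in mm).
#' @export
model_size_experiment <- function(meshes, sizes,
                                  variance_threshold = 0.999,
                                  heldout_fraction = 0.2,
                                  n_replicates = 5L, region = NULL,
                                  seed = 1L, heldout = TRUE) {
  n <- length(meshes)
  n_held <- max(1L, round(heldout_fraction * n))
  if (max(sizes) > n - n_held)
    stop("insufficient meshes: largest size plus held-out set exceeds family")
  rows <- list()
  retained <- list()
  for (r in seq_len(n_replicates)) {
    ord <- local_rng(stage_seed(seed, paste0("modelsize/", r)))(sample.int(n))
    held <- ord[seq_len(n_held)]
    pool <- ord[-seq_len(n_held)]
    eval_ids <- if (heldout) held else NULL
    for (s in sizes) {
      mdl <- shape_model(meshes[pool[seq_len(s)]],
                         variance_threshold = variance_threshold)
      ids <- if (heldout) eval_ids else pool[seq_len(s)]
      err <- mean(vapply(ids, function(i)
        reconstruction_error(mdl, meshes[[i]], region = region)$mean, 0))
      rows[[length(rows) + 1L]] <-
        data.frame(size = s, replicate = r, error = err)
      retained[[length(retained) + 1L]] <-
        data.frame(size = s, replicate = r,
                   retained = sum(mdl$variances) / mdl$total_variance,
                   n_modes = length(mdl$variances))
    }
  }
  out <- new_scaling_curve(do.call(rbind, rows),
                           metric = "mean reconstruction error (mm)")
  attr(out, "retained_variance") <- do.call(rbind, retained)
  out
}

#' Exponential learning-curve fit and convergence point
#'
#' Fits `y = a * exp(-b * n) + c` with `a, b > 0` by multi-start
#' Levenberg-Marquardt least squares; the asymptote `c` is the estimated
#' convergence point of the curve - the error one would approach with
#' unlimited training data. When `a > 0` the asymptote is a lower bound
#' of the fitted curve.
#'
#' @param curve a `scaling_curve`, or a data frame with `size` and
#'   `error` columns.
#' @return An object of class `exponential_fit`: `a`, `b`, `c`,
#'   `residual_sse`, `fitted` (at the data sizes), `misfit` flag set when
#'   `b` pins at its bound (the curve is not exponential-decay shaped).
#' @export
fit_exponential <- function(curve) {
  d <- as.data.frame(curve)
  if (!all(c("size", "error") %in% names(d)))
    stop("curve needs `size` and `error` columns")
  if (length(unique(d$size)) < 4L)
    stop("need at least 4 distinct sizes to fit the exponential")
  n <- d$size; y <- d$error
  span <- max(diff(range(n)), 1)
  if (diff(range(y)) < 1e-10 * max(1, abs(mean(y)))) {
    # degenerate flat curve: the asymptote is the constant itself
    return(structure(list(a = 0, b = 1 / span, c = mean(y),
                          residual_sse = sum((y - mean(y))^2),
                          fitted = rep(mean(y), length(n)), sizes = n,
                          misfit = FALSE),
                     class = "exponential_fit"))
  }
  c0 <- min(y)
  a0 <- max(max(y) - c0, 1e-6)
  best <- NULL
  for (b0 in c(0.2, 0.5, 1, 2, 5, 10, 30) / span) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * n) + c,
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(a = 1e-12, b = 1e-9, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("exponential fit failed to converge from all starts")
  p <- stats::coef(best$fit)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 residual_sse = best$sse,
                 fitted = unname(p["a"] * exp(-p["b"] * n) + p["c"]),
                 sizes = n,
                 misfit = unname(p["b"]) < 1e-8 | unname(p["b"]) > 1e6),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "exponential_fit: y = %.4g * exp(-%.4g n) + %.4g  (SSE %.3g)%s\n",
    x$a, x$b, x$c, x$residual_sse,
    if (x$misfit) "  [model misfit: decay rate at bound]" else ""))
  cat(sprintf("  convergence point (asymptote): %.4g\n", x$c))
  invisible(x)
}

#' Dataset-size scaling experiment
#'
#' The desk-scale analogue of evaluating landmark prediction against the
#' number of training identities: for each identity count, render a
#' training set, train the landmark regressor, and measure landmark RMSE
#' on held-out renders of held-out identities; optionally also fit the
#' shape model to the predicted landmarks and measure the contact-region
#' surface error. Replicated over seeds.
#'
#' @param meshes list of [tri_mesh()] identities (training pool followed
#'   by test identities).
#' @param topology the matching [palate_template()].
#' @param identity_counts increasing counts of training identities.
#' @param n_test_identities identities reserved for testing (taken from
#'   the end of `meshes`).
#' @param images_per_mesh renders per identity.
#' @param n_test_images test renders per test identity.
#' @param image_size render/training resolution.
#' @param cfg_args list of [predictor_config()] overrides.
#' @param seeds integer vector of replicate seeds.
#' @param shape_mdl optional [shape_model()] used for surface errors; when
#'   NULL the surface curve is skipped.
#' @param fit_images number of test images per count used for surface
#'   errors.
#' @param dir scratch directory for the rendered datasets.
#' @return list with `landmark_curve` (normalized-unit RMSE) and
#'   `surface_curve` (mm, or NULL).
#' @export
dataset_size_experiment <- function(meshes, topology,
                                    identity_counts = c(1, 2, 4, 8),
                                    n_test_identities = 2L,
                                    images_per_mesh = 12L,
                                    n_test_images = 4L,
                                    image_size = 48L,
                                    cfg_args = list(),
                                    seeds = 1:3,
                                    shape_mdl = NULL,
                                    fit_images = 4L,
                                    dir = tempfile("dsexp")) {
  n_pool <- length(meshes) - n_test_identities
  if (max(identity_counts) > n_pool)
    stop("not enough training identities for the largest count")
  test_meshes <- meshes[(n_pool + 1L):length(meshes)]
  lm_rows <- list(); sf_rows <- list()
  for (sd in seeds) {
    test_dir <- file.path(dir, sprintf("s%d_test", sd))
    make_dataset(test_meshes, topology, test_dir,
                 images_per_mesh = n_test_images, image_size = image_size,
                 seed = stage_seed(sd, "test-set"))
    test_man <- read_manifest(test_dir)
    ord <- local_rng(stage_seed(sd, "pool-order"))(sample.int(n_pool))
    for (cnt in identity_counts) {
      tr_dir <- file.path(dir, sprintf("s%d_n%d", sd, cnt))
      make_dataset(meshes[ord[seq_len(cnt)]], topology, tr_dir,
                   images_per_mesh = images_per_mesh,
                   image_size = image_size,
                   seed = stage_seed(sd, paste0("train-set/", cnt)))
      cfg <- do.call(predictor_config,
                     c(list(image_size = image_size,
                            n_landmarks = length(topology$landmark_subset),
                            seed = stage_seed(sd, paste0("train/", cnt))),
                       cfg_args))
      pred <- train_predictor(tr_dir, cfg)
      ev <- evaluate_predictor(pred, test_man)
      lm_rows[[length(lm_rows) + 1L]] <-
        data.frame(size = cnt, replicate = sd, error = ev$rmse_norm)
      if (!is.null(shape_mdl)) {
        errs <- c()
        cam <- approximate_intrinsics(image_size, image_size)
        take <- utils::head(seq_len(nrow(test_man$samples)), fit_images)
        for (i in take) {
          img <- png::readPNG(file.path(test_dir, test_man$samples$image[i]))
          rec <- reconstruct_from_image(img[, , 1:3], pred, shape_mdl, cam)
          truth <- test_meshes[[test_man$samples$mesh_id[i]]]
          errs <- c(errs, aligned_surface_error(
            rec$mesh, truth, region = topology$contact_region))
        }
        sf_rows[[length(sf_rows) + 1L]] <-
          data.frame(size = cnt, replicate = sd, error = mean(errs))
      }
    }
  }
  list(landmark_curve = new_scaling_curve(
    do.call(rbind, lm_rows), metric = "landmark RMSE (normalized units)"),
    surface_curve = if (length(sf_rows)) new_scaling_curve(
      do.call(rbind, sf_rows), metric = "contact-region error (mm)")
    else NULL)
}

# Mean per-vertex distance after rigid alignment; used when comparing a
# reconstruction in model coordinates against a mesh in generator
# coordinates.
aligned_surface_error <- function(fitted, reference, region = NULL) {
  A <- procrustes_fit(fitted$vertices, reference$vertices, scale = FALSE)
  d <- sqrt(rowSums((A - reference$vertices)^2))
  if (!is.null(region)) d <- d[region]
  mean(d)
}

#' Landmark RMSE of a predictor over a rendered dataset
#'
#' @param predictor a trained [train_predictor()] model.
#' @param manifest dataset directory or manifest.
#' @return list with `rmse_norm` (RMSE in normalized `[-1, 1]` units,
#'   the scale-free loss convention) and `rmse_px` at the dataset's
#'   resolution.
#' @export
evaluate_predictor <- function(predictor, manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  sz <- manifest$image_size
  se <- 0; cnt <- 0L
  for (i in seq_len(nrow(manifest$samples))) {
    img <- png::readPNG(file.path(manifest$dir, manifest$samples$image[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    lm <- read_landmarks(file.path(manifest$dir,
                                   manifest$samples$landmarks[i]))
    pr <- predict(predictor, img[, , 1:3, drop = FALSE])
    e <- normalize_coords(pr$points, sz, sz) -
      normalize_coords(lm$points, sz, sz)
    se <- se + sum(e^2); cnt <- cnt + length(e)
  }
  rmse <- sqrt(se / cnt)
  list(rmse_norm = rmse, rmse_px = rmse * sz / 2)
}
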