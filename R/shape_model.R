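#' PCA statistical shape model over template-corresponded meshes
#'
#' Builds a point-distribution model: meshes sharing the template topology
#' are rigidly pre-aligned by generalized Procrustes analysis, the
#' vertex-wise mean is removed, and the principal directions of the
#' stacked 3V-dimensional coordinate vectors are extracted by thin
#' singular value decomposition. The number of retained eigenmodes is the
#' smallest count whose cumulative variance fraction reaches
#' `variance_threshold` (default 99.9%).
#'
#' @param meshes list of [tri_mesh()] objects in template correspondence
#'   (>= 2, equal vertex counts).
#' @param variance_threshold fraction of total variance to retain, in
#'   (0, 1].
#' @param topology optional [palate_template()] carried along for
#'   contact-region and landmark-subset bookkeeping.
#' @param align apply generalized Procrustes alignment before PCA
#'   (default TRUE).
#' @param scale_align also normalize scale during alignment (default
#'   FALSE: rigid-only).
#' @return An object of class `shape_model` with elements `mean_shape`
#'   (3V), `components` (k x 3V, orthonormal rows), `variances` (k,
#'   descending, mm^2), `total_variance`, `n_training`, `faces`,
#'   `topology`.
#' @seealso [predict.shape_model()], [simulate.shape_model()],
#'   [shape_coef()], [reconstruction_error()]
#' @export
shape_model <- function(meshes, variance_threshold = 0.999, topology = NULL,
                        align = TRUE, scale_align = FALSE) {
  if (length(meshes) < 2L)
    stop("insufficient-data: need at least 2 meshes to build a shape model")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  V <- n_vertices(meshes[[1L]])
  if (!all(vapply(meshes, n_vertices, 0L) == V))
    stop("topology error: meshes have mismatched vertex counts")
  configs <- lapply(meshes, function(m) m$vertices)
  if (align) configs <- gpa_align(configs, scale = scale_align)
  X <- do.call(rbind, lapply(configs, flatten_vertices))
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(Xc)))
  d <- sv$d[seq_len(ncol(sv$v))]
  variances <- d^2 / (n - 1)
  total <- sum(variances)
  cumfrac <- cumsum(variances) / total
  k <- which(cumfrac >= variance_threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(variances)
  structure(list(mean_shape = mu,
                 components = t(sv$v[, seq_len(k), drop = FALSE]),
                 variances = variances[seq_len(k)],
                 all_variances = variances,
                 total_variance = total,
                 variance_threshold = variance_threshold,
                 n_training = n,
                 faces = meshes[[1L]]$faces,
                 topology = topology),
            class = "shape_model")
}

n_modes <- function(model) length(model$variances)

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: %d training meshes, %d vertices, %d retained modes\n",
    x$n_training, length(x$mean_shape) / 3, n_modes(x)))
  cat(sprintf("  retained variance: %.4f%% of %.2f mm^2 total\n",
              100 * sum(x$variances) / x$total_variance, x$total_variance))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  v <- object$all_variances
  out <- list(n_training = object$n_training,
              n_vertices = length(object$mean_shape) / 3,
              n_modes = n_modes(object),
              variances = object$variances,
              cumulative_fraction = cumsum(v) / sum(v),
              retained_fraction = sum(object$variances) / object$total_variance)
  class(out) <- "summary.shape_model"
  out
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("PCA shape model: %d meshes, %d vertices, %d modes (%.3f%% variance)\n",
              x$n_training, x$n_vertices, x$n_modes, 100 * x$retained_fraction))
  k <- min(10L, x$n_modes)
  cat("  leading mode standard deviations (mm):\n  ")
  cat(sprintf("%.3f", sqrt(x$variances[seq_len(k)])), sep = "  ")
  cat("\n")
  invisible(x)
}

#' Reconstruct a mesh from shape coefficients
#'
#' `vertices = mean_shape + t(components) %*% weights`, reshaped to V x 3
#' with the template faces attached. `coef = NULL` (or a zero vector)
#' returns the mean shape.
#'
#' @param object a [shape_model()].
#' @param coef numeric vector of mode weights, length equal to the
#'   retained mode count.
#' @param ... unused.
#' @return A [tri_mesh()].
#' @export
predict.shape_model <- function(object, coef = NULL, ...) {
  k <- n_modes(object)
  if (is.null(coef)) coef <- numeric(k)
  if (length(coef) != k)
    stop("dimension error: expected ", k, " coefficients, got ", length(coef))
  x <- object$mean_shape + as.numeric(crossprod(object$components, coef))
  tri_mesh(unflatten_vertices(x), object$faces)
}

#' Encode a mesh as shape coefficients
#'
#' Orthogonal projection onto the model subspace:
#' `weights = components %*% (x - mean_shape)` - the least-squares-closest
#' point of the subspace.
#'
#' @param model a [shape_model()].
#' @param mesh a [tri_mesh()] in template correspondence.
#' @return numeric vector of length `k`.
#' @export
shape_coef <- function(model, mesh) {
  x <- flatten_vertices(mesh$vertices)
  if (length(x) != length(model$mean_shape))
    stop("topology error: mesh vertex count does not match the model")
  as.numeric(model$components %*% (x - model$mean_shape))
}

#' Sample in-distribution shape coefficients
#'
#' Draws mode weights independently as zero-mean Gaussians with the
#' model's per-mode variances.
#'
#' @param object a [shape_model()].
#' @param nsim number of draws.
#' @param seed optional integer seed (draws are reproducible given it).
#' @param ... unused.
#' @return `nsim` x `k` matrix of coefficients.
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL, ...) {
  k <- n_modes(object)
  draw <- function() matrix(stats::rnorm(nsim * k), nsim, k) %*%
    diag(sqrt(object$variances), k)
  if (is.null(seed)) draw() else local_rng(seed)(draw())
}

#' Reconstruction error of a mesh under the model
#'
#' Encodes the mesh ([shape_coef()]), reconstructs it, and reports
#' per-vertex Euclidean distances, optionally restricted to a vertex
#' subset such as the plate contact region.
#'
#' @param model a [shape_model()].
#' @param mesh a [tri_mesh()] in template correspondence.
#' @param region optional integer vertex subset.
#' @return list with `mean`, `max` (mm) and `per_vertex` distances.
#' @export
reconstruction_error <- function(model, mesh, region = NULL) {
  if (!is.null(region) && length(region) == 0L)
    stop("invalid-parameter: empty region")
  rec <- predict(model, shape_coef(model, mesh))
  d <- sqrt(rowSums((mesh$vertices - rec$vertices)^2))
  if (!is.null(region)) d <- d[region]
  list(mean = mean(d), max = max(d), per_vertex = d)
}

# Generalized Procrustes alignment: iteratively superimpose every
# configuration onto the evolving mean by Kabsch rotation (+ optional
# scale), until the mean stabilizes.
gpa_align <- function(configs, scale = FALSE, max_iter = 20L, tol = 1e-9) {
  ref <- configs[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(configs, procrustes_fit, B = ref, scale = scale)
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    configs <- aligned
    if (delta < tol && it > 1L) break
  }
  configs
}

# Rigid (optionally scaled) superimposition of A onto B.
procrustes_fit <- function(A, B, scale = FALSE) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Ac, Bc))
  D <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  R <- s$u %*% D %*% t(s$v)
  g <- if (scale) sum(s$d * diag(D)) / sum(Ac^2) else 1
  g * Ac %*% R + matrix(cb, nrow(A), 3, byrow = TRUE)
}

#' Serialize a shape model to a versioned binary container
#'
#' Writes a single file: a one-line JSON header describing array shapes
#' followed by little-endian doubles (mean, components, variances,
#' canonical template vertices) and 32-bit integers (faces and vertex
#' subsets). [read_shape_model()] restores it.
#'
#' @param model a [shape_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path) {
  topo <- model$topology
  hdr <- list(format = "cleftrecon-shape-model", version = 1L,
              n_vertices = length(model$mean_shape) / 3,
              k = n_modes(model),
              n_all_variances = length(model$all_variances),
              n_training = model$n_training,
              total_variance = model$total_variance,
              variance_threshold = model$variance_threshold,
              n_faces = nrow(model$faces),
              has_topology = !is.null(topo))
  if (!is.null(topo))
    hdr <- c(hdr, list(nu = topo$nu, nv = topo$nv,
                       n_contact = length(topo$contact_region),
                       n_landmarks = length(topo$landmark_subset)))
  con <- file(path, "wb")
  on.exit(close(con))
  hjson <- jsonlite::toJSON(hdr, auto_unbox = TRUE)
  writeBin(charToRaw(paste0(hjson, "\n")), con)
  wd <- function(x) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wd(model$mean_shape); wd(t(model$components)); wd(model$variances)
  wd(model$all_variances)
  wi(model$faces)
  if (!is.null(topo)) {
    wi(topo$contact_region); wi(topo$landmark_subset)
    wd(topo$canonical_vertices)
  }
  invisible(path)
}

#' Read a serialized shape model
#' @param path file written by [write_shape_model()].
#' @return A [shape_model()].
#' @export
read_shape_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readBinLine(con))
  if (!identical(hdr$format, "cleftrecon-shape-model"))
    stop("not a cleftrecon shape-model file")
  rd <- function(n) readBin(con, "double", n, size = 8L, endian = "little")
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  V3 <- hdr$n_vertices * 3
  mean_shape <- rd(V3)
  components <- t(matrix(rd(V3 * hdr$k), V3, hdr$k))
  variances <- rd(hdr$k)
  all_var <- rd(hdr$n_all_variances)
  faces <- matrix(ri(hdr$n_faces * 3), hdr$n_faces, 3)
  topo <- NULL
  if (isTRUE(hdr$has_topology)) {
    contact <- ri(hdr$n_contact)
    lms <- ri(hdr$n_landmarks)
    canon <- matrix(rd(hdr$nu * hdr$nv * 3), hdr$nu * hdr$nv, 3)
    topo <- structure(list(faces = faces, n_vertices = hdr$nu * hdr$nv,
                           nu = hdr$nu, nv = hdr$nv,
                           grid_u = rep(seq(0, 1, length.out = hdr$nu), times = hdr$nv),
                           grid_v = rep(seq(0, 1, length.out = hdr$nv), each = hdr$nu),
                           contact_region = contact, landmark_subset = lms,
                           canonical_vertices = canon),
                      class = "template_topology")
  }
  structure(list(mean_shape = mean_shape, components = components,
                 variances = variances, all_variances = all_var,
                 total_variance = hdr$total_variance,
                 variance_threshold = hdr$variance_threshold,
                 n_training = hdr$n_training, faces = faces,
                 topology = topo),
            class = "shape_model")
}
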