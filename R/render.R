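#' Canonical "mirror view" pose of a palate mesh
#'
#' Orients the palate dome toward the camera (a 180 degree rotation about
#' the image x-axis) and places its centroid on the optical axis at
#' `depth_factor` times the bounding radius.
#'
#' @param mesh a [tri_mesh()].
#' @param depth_factor distance in bounding radii (default 4).
#' @return A [similarity_pose()].
#' @export
canonical_pose <- function(mesh, depth_factor = 4) {
  ctr <- colMeans(mesh$vertices)
  r <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  R0 <- rotvec_to_matrix(c(pi, 0, 0))
  similarity_pose(rotation = R0,
                  translation = c(0, 0, depth_factor * max(r, 1)) -
                    as.numeric(R0 %*% ctr),
                  scale = 1)
}

#' Randomized camera pose around the canonical mirror view
#'
#' Perturbs the canonical view by independent per-axis rotations (default
#' +/- 20 degrees), a distance jitter (default +/- 15%), and a small
#' in-plane offset.
#'
#' @param mesh a [tri_mesh()].
#' @param seed integer seed.
#' @param angle_range per-axis rotation range in degrees.
#' @param dist_jitter relative depth jitter.
#' @return A [similarity_pose()].
#' @export
random_view_pose <- function(mesh, seed = 1L, angle_range = 20,
                             dist_jitter = 0.15) {
  local_rng(seed)({
    ctr <- colMeans(mesh$vertices)
    r <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
    ang <- stats::runif(3, -angle_range, angle_range) * pi / 180
    R <- rotvec_to_matrix(c(ang[1], 0, 0)) %*%
      rotvec_to_matrix(c(0, ang[2], 0)) %*%
      rotvec_to_matrix(c(0, 0, ang[3])) %*%
      rotvec_to_matrix(c(pi, 0, 0))
    d <- 4 * max(r, 1) * (1 + stats::runif(1, -dist_jitter, dist_jitter))
    off <- c(stats::runif(2, -0.15, 0.15) * r, 0)
    similarity_pose(rotation = R,
                    translation = c(off[1], off[2], d) - as.numeric(R %*% ctr),
                    scale = 1)
  })
}

noise_background <- function(width, height, seed = 1L) {
  local_rng(seed)({
    base <- stats::runif(1, 0.05, 0.25)
    arr <- array(base + stats::rnorm(height * width * 3, 0, 0.03),
                 dim = c(height, width, 3))
    pmin(pmax(arr, 0), 1)
  })
}

linear_motion_blur <- function(img, blur_px, angle) {
  n <- max(1L, as.integer(round(blur_px)))
  if (n <= 1L) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  offs <- seq(-(n - 1) / 2, (n - 1) / 2, length.out = n)
  dx <- round(offs * cos(angle)); dy <- round(offs * sin(angle))
  out <- array(0, dim(img))
  for (i in seq_len(n)) {
    sx <- pmin(pmax(seq_len(W) + dx[i], 1L), W)
    sy <- pmin(pmax(seq_len(H) + dy[i], 1L), H)
    out <- out + img[sy, sx, , drop = FALSE]
  }
  out / n
}

#' Render a palate mesh into an annotated synthetic sample
#'
#' Software z-buffer rasterization with flat Lambertian shading modulated
#' by the mesh's per-vertex albedo, over a textured-noise background, with
#' optional linear motion blur. The sample's landmarks are the exact
#' projections of the template's landmark-subset vertices - including
#' occluded ones, which are flagged (not dropped) via a z-buffer
#' visibility bit.
#'
#' @param mesh a [tri_mesh()] (vertex colors used as albedo when present).
#' @param pose a [similarity_pose()].
#' @param cam a [camera_intrinsics()].
#' @param topology a [palate_template()] supplying the landmark subset.
#' @param light_dir light direction in camera coordinates.
#' @param blur_px linear motion-blur extent in pixels (0 disables).
#' @param seed integer seed (background texture and blur direction).
#' @param ambient ambient light fraction added to the Lambertian term.
#' @return An object of class `synthetic_sample`: `image` (H x W x 3 in
#'   `[0,1]`), `landmarks` ([landmarks2d()] with visibility flags), `pose`,
#'   `cam`, `seed`.
#' @export
render <- function(mesh, pose, cam, topology, light_dir = c(0, 0, 1),
                   blur_px = 0, seed = 1L, ambient = 0) {
  pc <- to_camera_frame(mesh$vertices, pose)
  if (any(pc[, 3] <= 0)) stop("behind-camera: mesh not fully in front of camera")
  uv_all <- project(mesh$vertices, pose, cam)
  f <- mesh$faces
  e1 <- pc[f[, 2], , drop = FALSE] - pc[f[, 1], , drop = FALSE]
  e2 <- pc[f[, 3], , drop = FALSE] - pc[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2); nn[nn == 0] <- 1
  l <- light_dir / sqrt(sum(light_dir^2))
  lambert <- abs(nx * l[1] + ny * l[2] + nz * l[3]) / nn
  shade <- pmin(1, ambient + (1 - ambient) * lambert)
  albedo <- if (is.null(mesh$vertex_colors)) matrix(1, nrow(mesh$vertices), 3)
  else mesh$vertex_colors
  fcol <- (albedo[f[, 1], , drop = FALSE] + albedo[f[, 2], , drop = FALSE] +
             albedo[f[, 3], , drop = FALSE]) / 3 * shade
  bg <- noise_background(cam$width, cam$height, seed = seed)
  ras <- .rasterize_cpp(uv_all$points, pc[, 3], f, fcol, as.numeric(bg),
                        as.integer(cam$width), as.integer(cam$height))
  img <- array(ras$image, dim = c(cam$height, cam$width, 3))
  zbuf <- matrix(ras$zbuffer, cam$height, cam$width)
  if (blur_px > 0) {
    ang <- local_rng(seed + 1L)(stats::runif(1, 0, pi))
    img <- linear_motion_blur(img, blur_px, ang)
  }
  sub <- topology$landmark_subset
  lm_pts <- uv_all$points[sub, , drop = FALSE]
  px <- pmin(pmax(round(lm_pts[, 1]), 0), cam$width - 1) + 1L
  py <- pmin(pmax(round(lm_pts[, 2]), 0), cam$height - 1) + 1L
  zb <- zbuf[cbind(py, px)]
  visible <- uv_all$in_bounds[sub] &
    pc[sub, 3] <= zb * (1 + 1e-3) + 1e-6
  lm <- landmarks2d(lm_pts, in_bounds = uv_all$in_bounds[sub],
                    visible = visible)
  structure(list(image = img, landmarks = lm, pose = pose, cam = cam,
                 seed = seed),
            class = "synthetic_sample")
}

#' Write/read landmark files (JSON or CSV)
#'
#' JSON files carry `points` (L x 2), optional `sigma2`, `visible`, and
#' image metadata; CSV files have columns `id,u,v[,sigma2]`.
#'
#' @param lm a [landmarks2d()].
#' @param path output path (`.json` or `.csv`).
#' @param image optional image path recorded in JSON metadata.
#' @param width,height optional image size recorded in JSON metadata.
#' @return `path` invisibly.
#' @export
write_landmarks <- function(lm, path, image = NULL, width = NULL,
                            height = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- data.frame(id = seq_len(nrow(lm$points)),
                    u = lm$points[, 1], v = lm$points[, 2])
    if (!is.null(lm$sigma2)) d$sigma2 <- lm$sigma2
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    obj <- list(points = unname(lm$points))
    if (!is.null(lm$sigma2)) obj$sigma2 <- lm$sigma2
    if (!is.null(lm$visible)) obj$visible <- lm$visible
    if (!is.null(image)) obj$image <- image
    if (!is.null(width)) { obj$width <- width; obj$height <- height }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path)
    landmarks2d(cbind(d$u, d$v),
                sigma2 = if ("sigma2" %in% names(d)) d$sigma2 else NULL)
  } else {
    obj <- jsonlite::fromJSON(path)
    landmarks2d(obj$points, sigma2 = obj$sigma2,
                visible = obj$visible)
  }
}

#' Generate an annotated synthetic dataset
#'
#' Renders `images_per_mesh` views of every mesh (the study default is
#' 100 per mesh) under randomized camera position and angles, lighting and
#' motion blur, and writes `images/*.png`, `landmarks/*.json` and a
#' `manifest.json` listing every sample with its seed. Regeneration with
#' the same seed is byte-identical.
#'
#' @param meshes list of [tri_mesh()] in template correspondence.
#' @param topology the matching [palate_template()].
#' @param out_dir output directory (created if missing).
#' @param images_per_mesh renders per mesh (default 100).
#' @param image_size square image size in pixels.
#' @param seed global integer seed.
#' @param angle_range,dist_jitter camera randomization ranges (degrees,
#'   relative depth).
#' @param blur_range motion-blur range in pixels.
#' @param fov_deg assumed horizontal field of view.
#' @return The manifest as a data frame, invisibly.
#' @export
make_dataset <- function(meshes, topology, out_dir, images_per_mesh = 100L,
                         image_size = 256L, seed = 1L, angle_range = 20,
                         dist_jitter = 0.15, blur_range = c(0, 3),
                         fov_deg = 53) {
  if (length(meshes) < 1L) stop("need at least one mesh")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "landmarks"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  cam <- approximate_intrinsics(image_size, image_size, fov_deg = fov_deg)
  rows <- list()
  for (mi in seq_along(meshes)) {
    for (ii in seq_len(images_per_mesh)) {
      sseed <- stage_seed(seed, sprintf("render/%d/%d", mi, ii))
      pose <- random_view_pose(meshes[[mi]], seed = sseed,
                               angle_range = angle_range,
                               dist_jitter = dist_jitter)
      extras <- local_rng(sseed + 7L)(list(
        light = c(stats::runif(2, -0.4, 0.4), 1),
        blur = stats::runif(1, blur_range[1], blur_range[2])))
      smp <- render(meshes[[mi]], pose, cam, topology,
                    light_dir = extras$light, blur_px = extras$blur,
                    seed = sseed)
      stem <- sprintf("m%03d_i%03d", mi, ii)
      ipath <- file.path("images", paste0(stem, ".png"))
      lpath <- file.path("landmarks", paste0(stem, ".json"))
      png::writePNG(smp$image, file.path(out_dir, ipath))
      write_landmarks(smp$landmarks, file.path(out_dir, lpath),
                      image = ipath, width = cam$width, height = cam$height)
      rows[[length(rows) + 1L]] <-
        data.frame(image = ipath, landmarks = lpath, mesh_id = mi,
                   seed = sseed)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(list(format = "cleftrecon-dataset", version = 1L,
                            image_size = image_size, fov_deg = fov_deg,
                            n_landmarks = length(topology$landmark_subset),
                            samples = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

read_manifest <- function(dir) {
  m <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  m$dir <- dir
  m
}
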