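#' Training-time image/landmark augmentation
#'
#' Applies a seeded random in-plane rotation about the image center, an
#' optional horizontal flip, per-channel color shifts and additive
#' Gaussian pixel noise. Landmark coordinates undergo exactly the same
#' geometric transform as the pixels; when a left/right symmetry map is
#' supplied, flips also permute landmark ids accordingly. With all ranges
#' zero (and flips disabled) the input is returned bit-exact.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param landmarks a [landmarks2d()] in the image's pixel coordinates.
#' @param seed integer seed.
#' @param max_rot_deg rotation range (+/- degrees).
#' @param flip_prob probability of a horizontal flip.
#' @param color_shift per-channel additive shift range.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param symmetry_map optional integer permutation mapping each landmark
#'   id to its mirror-symmetric counterpart, applied on flips.
#' @return list with elements `image` and `landmarks`.
#' @export
augment <- function(image, landmarks, seed = 1L, max_rot_deg = 30,
                    flip_prob = 0.5, color_shift = 0.1, noise_sd = 0.02,
                    symmetry_map = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  local_rng(seed)({
    ang <- if (max_rot_deg > 0) stats::runif(1, -max_rot_deg, max_rot_deg) *
      pi / 180 else 0
    do_flip <- flip_prob > 0 && stats::runif(1) < flip_prob
    pts <- landmarks$points
    img <- image
    if (ang != 0) {
      img <- rotate_image(img, ang)
      pts <- rotate_points(pts, ang, W, H)
    }
    if (do_flip) {
      img <- img[, W:1, , drop = FALSE]
      pts[, 1] <- (W - 1) - pts[, 1]
      if (!is.null(symmetry_map)) pts <- pts[symmetry_map, , drop = FALSE]
    }
    if (color_shift > 0) {
      sh <- stats::runif(3, -color_shift, color_shift)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + sh[ch]
    }
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    if (color_shift > 0 || noise_sd > 0) img <- pmin(pmax(img, 0), 1)
    list(image = img, landmarks = landmarks2d(pts, sigma2 = landmarks$sigma2,
                                              visible = landmarks$visible))
  })
}

# Rotate landmark coordinates about the image center (pixel convention:
# centers at integers, center of a WxH image at ((W-1)/2, (H-1)/2)).
# Positive angle rotates the IMAGE CCW in standard orientation, which in
# the v-down pixel frame maps points by the matrix [cos, sin; -sin, cos].
rotate_points <- function(pts, ang, W, H) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  du <- pts[, 1] - cx; dv <- pts[, 2] - cy
  cbind(cx + cos(ang) * du + sin(ang) * dv,
        cy - sin(ang) * du + cos(ang) * dv)
}

# Inverse-mapped bilinear rotation of the pixel grid; matches
# rotate_points so image content and landmarks transform together.
rotate_image <- function(img, ang) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  u <- rep(0:(W - 1), each = H) - cx
  v <- rep(0:(H - 1), times = W) - cy
  # inverse transform (rotate by -ang)
  su <- cx + cos(ang) * u - sin(ang) * v
  sv <- cy + sin(ang) * u + cos(ang) * v
  u0 <- floor(su); v0 <- floor(sv)
  fu <- su - u0; fv <- sv - v0
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  idx <- function(uu, vv) cbind(cl(vv, 0, H - 1) + 1, cl(uu, 0, W - 1) + 1)
  inside <- su >= -0.5 & su <= W - 0.5 & sv >= -0.5 & sv <= H - 0.5
  out <- array(0, dim(img))
  for (ch in 1:3) {
    p <- img[, , ch]
    val <- (1 - fu) * (1 - fv) * p[idx(u0, v0)] +
      fu * (1 - fv) * p[idx(u0 + 1, v0)] +
      (1 - fu) * fv * p[idx(u0, v0 + 1)] +
      fu * fv * p[idx(u0 + 1, v0 + 1)]
    val[!inside] <- 0
    out[, , ch] <- matrix(val, H, W)
  }
  out
}
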