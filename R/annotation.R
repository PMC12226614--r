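#' Ordered video frames
#'
#' @param frames list of H x W x 3 arrays sharing dimensions (>= 1).
#' @param frame_ids optional identifiers (default 1..n).
#' @return An object of class `video_frames`.
#' @export
video_frames <- function(frames, frame_ids = seq_along(frames)) {
  if (length(frames) < 1L) stop("need at least one frame")
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must share dimensions")
  structure(list(frames = frames, frame_ids = frame_ids,
                 width = d[2], height = d[1]),
            class = "video_frames")
}

#' Read a directory of numbered PNG frames as a video
#' @param dir directory containing `*.png` frames in lexical order.
#' @return A [video_frames()].
#' @export
read_video_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(paths)) stop("no PNG frames in ", dir)
  frames <- lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  video_frames(frames, frame_ids = basename(paths))
}

to_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

# Normalized cross-correlation search of one template patch around a
# previous position. Returns c(u, v, score) or NA coordinates when lost.
ncc_search <- function(tpl, gray, p, radius) {
  H <- nrow(gray); W <- ncol(gray)
  ph <- (nrow(tpl) - 1L) %/% 2L
  cx <- round(p[1]); cy <- round(p[2])
  x0 <- cx - radius - ph; x1 <- cx + radius + ph
  y0 <- cy - radius - ph; y1 <- cy + radius + ph
  if (x0 < 0 || y0 < 0 || x1 > W - 1 || y1 > H - 1)
    return(c(NA_real_, NA_real_, -Inf))
  region <- gray[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  np <- 2L * ph + 1L
  ns <- 2L * radius + 1L
  M <- matrix(0, ns * ns, np * np)
  t <- 0L
  for (j in seq_len(np)) for (i in seq_len(np)) {
    t <- t + 1L
    M[, t] <- as.numeric(region[i:(i + ns - 1L), j:(j + ns - 1L)])
  }
  tv <- as.numeric(tpl) - mean(tpl)
  tn <- sqrt(sum(tv^2))
  Mc <- M - rowMeans(M)
  denom <- sqrt(rowSums(Mc^2)) * tn
  score <- as.numeric(Mc %*% tv) / pmax(denom, 1e-12)
  score[denom < 1e-10] <- -Inf
  S <- matrix(score, ns, ns)
  best <- arrayInd(which.max(S), dim(S))
  by <- best[1]; bx <- best[2]
  du <- bx - 1L - radius; dv <- by - 1L - radius
  # exact match at zero offset (e.g. a static scene): keep the position
  if (du == 0L && dv == 0L && max(S) > 1 - 1e-9)
    return(c(p[1], p[2], max(S)))
  # quadratic sub-pixel refinement along each axis
  sub <- c(0, 0)
  if (bx > 1 && bx < ns) {
    a <- S[by, bx - 1]; b <- S[by, bx]; cc <- S[by, bx + 1]
    den <- a - 2 * b + cc
    if (is.finite(den) && den < 0) sub[1] <- 0.5 * (a - cc) / den
  }
  if (by > 1 && by < ns) {
    a <- S[by - 1, bx]; b <- S[by, bx]; cc <- S[by + 1, bx]
    den <- a - 2 * b + cc
    if (is.finite(den) && den < 0) sub[2] <- 0.5 * (a - cc) / den
  }
  c(cx + du + sub[1], cy + dv + sub[2], max(S))
}

extract_patch <- function(gray, p, ph) {
  cx <- round(p[1]); cy <- round(p[2])
  H <- nrow(gray); W <- ncol(gray)
  if (cx - ph < 0 || cy - ph < 0 || cx + ph > W - 1 || cy + ph > H - 1)
    return(NULL)
  gray[(cy - ph + 1):(cy + ph + 1), (cx - ph + 1):(cx + ph + 1)]
}

#' Propagate sparse 2D landmarks through a video by patch tracking
#'
#' The baseline tracker is frame-to-frame normalized cross-correlation of
#' grayscale patches with quadratic sub-pixel refinement, run forward and
#' backward from the annotated frame. A landmark whose best correlation
#' falls below the threshold (or that leaves the trackable area) is
#' flagged lost, never fabricated. A different tracker can be plugged in
#' via `tracker`, a function `(prev_gray, cur_gray, points, lost)` that
#' returns `list(points, lost)`.
#'
#' @param video a [video_frames()].
#' @param init a [landmarks2d()] on frame `frame_k` (inside the image).
#' @param frame_k index of the annotated frame.
#' @param vertex_ids optional template vertex ids carried along.
#' @param patch_size odd NCC patch size in px.
#' @param search_radius search radius in px.
#' @param corr_threshold minimum acceptable correlation.
#' @param tracker optional replacement tracking function.
#' @return An object of class `landmark_tracks`: per-frame list with
#'   `points` (L x 2) and `lost` (logical L), plus `vertex_ids`.
#' @export
track_landmarks <- function(video, init, frame_k = 1L, vertex_ids = NULL,
                            patch_size = 21L, search_radius = 20L,
                            corr_threshold = 0.6, tracker = NULL) {
  n <- length(video$frames)
  L <- nrow(init$points)
  if (any(init$points[, 1] < 0 | init$points[, 1] > video$width - 1 |
            init$points[, 2] < 0 | init$points[, 2] > video$height - 1))
    stop("init landmarks must lie inside frame ", frame_k)
  ph <- (as.integer(patch_size) - 1L) %/% 2L
  grays <- lapply(video$frames, to_gray)
  default_step <- function(prev_g, cur_g, pts, lost) {
    out <- pts
    for (j in seq_len(L)) {
      if (lost[j]) next
      tpl <- extract_patch(prev_g, pts[j, ], ph)
      if (is.null(tpl) || stats::sd(tpl) < 1e-6) { lost[j] <- TRUE; next }
      hit <- ncc_search(tpl, cur_g, pts[j, ], search_radius)
      if (!is.finite(hit[3]) || hit[3] < corr_threshold) lost[j] <- TRUE
      else out[j, ] <- hit[1:2]
    }
    list(points = out, lost = lost)
  }
  step <- if (is.null(tracker)) default_step else tracker
  res <- vector("list", n)
  res[[frame_k]] <- list(points = init$points, lost = rep(FALSE, L))
  if (frame_k < n) for (f in (frame_k + 1L):n) {
    prev <- res[[f - 1L]]
    res[[f]] <- step(grays[[f - 1L]], grays[[f]], prev$points, prev$lost)
  }
  if (frame_k > 1L) for (f in (frame_k - 1L):1L) {
    prev <- res[[f + 1L]]
    res[[f]] <- step(grays[[f + 1L]], grays[[f]], prev$points, prev$lost)
  }
  structure(list(frames = res, vertex_ids = vertex_ids,
                 frame_ids = video$frame_ids),
            class = "landmark_tracks")
}

#' Transfer annotated 3D points onto template vertices
#'
#' Maps each annotated point on the original surface to the nearest
#' vertex of the registered template (Euclidean distance; exact ties go
#' to the lower index). Duplicate assignments are resolved by moving the
#' later point to its next-nearest free vertex.
#'
#' @param annotated_points n x 3 matrix of points on the original mesh.
#' @param registered_template a [tri_mesh()] with template topology,
#'   registered to the original surface.
#' @return Integer vector of template vertex ids.
#' @export
transfer_landmarks <- function(annotated_points, registered_template) {
  P <- as.matrix(annotated_points)
  V <- registered_template$vertices
  taken <- rep(FALSE, nrow(V))
  ids <- integer(nrow(P))
  for (i in seq_len(nrow(P))) {
    d2 <- rowSums(sweep(V, 2, P[i, ])^2)
    ord <- order(d2)                    # stable: ties resolved by index
    j <- ord[which(!taken[ord])[1L]]
    ids[i] <- j
    taken[j] <- TRUE
  }
  ids
}

#' Densify tracked sparse landmarks into per-frame dense annotations
#'
#' For every frame with at least four surviving sparse tracks, estimates
#' the similarity pose from the tracked 2D-3D correspondences (warm
#' started from the previous frame's pose) and projects ALL template
#' vertices, yielding one dense annotation per template vertex. Frames
#' with fewer than four tracks are skipped and reported.
#'
#' @param tracks a [track_landmarks()] result whose `vertex_ids` are set.
#' @param template a [tri_mesh()] in template topology.
#' @param cam a [camera_intrinsics()].
#' @param init_pose optional pose for the first processed frame.
#' @return An object of class `dense_annotation`: per-frame list with
#'   `landmarks` ([landmarks2d()] over all vertices or NULL), `pose`,
#'   `reproj_rmse` (px over the sparse tracks), plus `skipped` frame
#'   indices.
#' @export
densify <- function(tracks, template, cam, init_pose = NULL) {
  if (is.null(tracks$vertex_ids))
    stop("tracks must carry template vertex_ids")
  n <- length(tracks$frames)
  out <- vector("list", n)
  skipped <- integer(0)
  prev_pose <- init_pose
  for (f in seq_len(n)) {
    tr <- tracks$frames[[f]]
    ok <- which(!tr$lost)
    if (length(ok) < 4L) {
      skipped <- c(skipped, f)
      out[[f]] <- list(landmarks = NULL, pose = NULL, reproj_rmse = NA_real_)
      next
    }
    corr <- correspondence_set(tracks$vertex_ids[ok],
                               tr$points[ok, 1], tr$points[ok, 2])
    pose <- tryCatch(
      estimate_pose(corr, template$vertices, cam, init = prev_pose),
      error = function(e) NULL)
    if (is.null(pose)) {
      skipped <- c(skipped, f)
      out[[f]] <- list(landmarks = NULL, pose = NULL, reproj_rmse = NA_real_)
      next
    }
    prev_pose <- pose
    dense <- project(template$vertices, pose, cam)
    out[[f]] <- list(landmarks = dense, pose = pose,
                     reproj_rmse = attr(pose, "rms_px"))
  }
  structure(list(frames = out, skipped = skipped, cam = cam,
                 frame_ids = tracks$frame_ids),
            class = "dense_annotation")
}

#' Quality-filter densely annotated frames
#'
#' A frame is accepted iff (1) at least `min_in_bounds` of its projected
#' points fall inside the image, (2) the sparse reprojection RMSE is at
#' most `max_rmse` px, and (3) the pose jump - the Frobenius norm of the
#' difference between the frame's 3x4 projection matrix and that of the
#' last accepted frame, normalized by the focal length - is at most
#' `max_jump` (defined as 0 for the first annotated frame). Measuring
#' against the last accepted frame means a single teleported pose
#' rejects only itself. Skipped/unannotated frames are rejected
#' outright.
#'
#' @param dense a [densify()] result.
#' @param min_in_bounds minimum in-bounds fraction (0-1) or absolute
#'   count (> 1).
#' @param max_rmse maximum sparse reprojection RMSE (px).
#' @param max_jump maximum normalized pose change.
#' @return A data frame of class `quality_report` with columns
#'   `frame_id`, `n_in_bounds`, `reproj_rmse`, `pose_change`, `accepted`.
#' @export
quality_filter <- function(dense, min_in_bounds = 0.9, max_rmse = 3,
                           max_jump = 0.1) {
  n <- length(dense$frames)
  cam <- dense$cam
  rows <- vector("list", n)
  prev_P <- NULL
  for (f in seq_len(n)) {
    fr <- dense$frames[[f]]
    if (is.null(fr$landmarks)) {
      rows[[f]] <- data.frame(frame_id = f, n_in_bounds = 0L,
                              reproj_rmse = NA_real_,
                              pose_change = NA_real_, accepted = FALSE)
      next
    }
    nin <- sum(fr$landmarks$in_bounds)
    total <- nrow(fr$landmarks$points)
    need <- if (min_in_bounds <= 1) ceiling(min_in_bounds * total)
    else min_in_bounds
    # pose jump is measured against the last ACCEPTED frame, so a single
    # teleported pose rejects only itself, not its successor as well
    P <- projection_matrix(fr$pose, cam)
    jump <- if (is.null(prev_P)) 0
    else sqrt(sum((P - prev_P)^2)) / cam$fx
    acc <- nin >= need & fr$reproj_rmse <= max_rmse & jump <= max_jump
    if (acc) prev_P <- P
    rows[[f]] <- data.frame(
      frame_id = f, n_in_bounds = nin, reproj_rmse = fr$reproj_rmse,
      pose_change = jump, accepted = acc)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("quality_report", "data.frame")
  rep
}

#' Write a quality report as CSV
#' @param report a [quality_filter()] result.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_quality_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
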