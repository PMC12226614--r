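make_static_video <- function(n = 5, seed = 1) {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = seed), topo)
  cam <- toy_cam(128)
  pose <- canonical_pose(mesh)
  smp <- render(mesh, pose, cam, topo, seed = seed)
  video_frames(rep(list(smp$image), n))
}

test_that("tracking a static video returns the init exactly", {
  video <- make_static_video(5)
  init <- landmarks2d(cbind(c(40, 60, 80, 64), c(40, 60, 50, 70)))
  tr <- track_landmarks(video, init, frame_k = 2L)
  for (f in seq_along(tr$frames)) {
    expect_false(any(tr$frames[[f]]$lost))
    expect_equal(tr$frames[[f]]$points, init$points, tolerance = 1e-9)
  }
})

test_that("featureless points are flagged lost, not fabricated", {
  flat <- array(0.5, c(64, 64, 3))
  video <- video_frames(rep(list(flat), 3))
  init <- landmarks2d(cbind(32, 32))
  tr <- track_landmarks(video, init, frame_k = 1L)
  expect_true(tr$frames[[2]]$lost[1])
  expect_true(tr$frames[[3]]$lost[1])
})

test_that("out-of-frame init is rejected", {
  video <- make_static_video(2)
  expect_error(track_landmarks(video, landmarks2d(cbind(500, 10))),
               "inside")
})

test_that("tracking follows rendered motion within 2 px RMS", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 13), topo)
  cam <- toy_cam(256)
  n <- 8
  poses <- lapply(seq_len(n), function(f) {
    a <- 0.003 * (f - 1)                 # slow smooth rotation + drift
    similarity_pose(
      cleftrecon:::rotvec_to_matrix(c(a, -a / 2, 0)) %*%
        canonical_pose(mesh)$rotation,
      canonical_pose(mesh)$translation +
        c(0.5 * (f - 1), 0.3 * (f - 1), -0.5 * (f - 1)),
      1)
  })
  frames <- lapply(seq_len(n), function(f)
    render(mesh, poses[[f]], cam, topo, seed = 99 + f)$image)
  video <- video_frames(frames)
  nu <- topo$nu                          # interior palate vertices
  ids <- c(8 + 7 * nu, 13 + 7 * nu, 10 + 10 * nu, 7 + 13 * nu,
           14 + 12 * nu, 10 + 15 * nu)
  truth <- lapply(poses, function(p)
    project(mesh$vertices[ids, ], p, cam)$points)
  tr <- track_landmarks(video, landmarks2d(truth[[1]]), frame_k = 1L,
                        vertex_ids = ids)
  errs <- vapply(seq_len(n), function(f) {
    ok <- !tr$frames[[f]]$lost
    sqrt(mean((tr$frames[[f]]$points[ok, ] - truth[[f]][ok, ])^2))
  }, 0)
  expect_true(all(vapply(tr$frames, function(x) sum(!x$lost), 0L) >= 4L))
  expect_lt(max(errs), 2)
})

test_that("landmark transfer picks nearest vertices with documented ties", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 3), topo)
  # a point exactly at a vertex returns that vertex
  expect_identical(transfer_landmarks(mesh$vertices[57, , drop = FALSE],
                                      mesh)[1], 57L)
  # equidistant point between vertices 1 and 2: lower index wins
  tri <- tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0)),
                  matrix(c(1L, 2L, 3L), 1))
  expect_identical(transfer_landmarks(rbind(c(1, 0, 0)), tri)[1], 1L)
  # duplicates resolved by next-nearest
  two <- transfer_landmarks(rbind(c(0.1, 0, 0), c(0.2, 0, 0)), tri)
  expect_identical(two, c(1L, 2L))
  # brute-force nearest-vertex oracle on random surface points
  set.seed(8)
  pick <- sample(nrow(mesh$vertices), 10)
  pts <- mesh$vertices[pick, ] +
    matrix(rnorm(30, 0, 0.05), 10, 3)
  got <- transfer_landmarks(pts, mesh)
  for (i in seq_len(10)) {
    d <- sqrt(sum((mesh$vertices[got[i], ] - pts[i, ])^2))
    oracle <- min(sqrt(rowSums(sweep(mesh$vertices, 2, pts[i, ])^2)))
    expect_lt(d - oracle, 0.5)            # within an edge length
  }
})

test_that("densification reproduces renderer ground truth", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 17), topo)
  cam <- toy_cam(128)
  n <- 5
  poses <- lapply(seq_len(n), function(f) {
    base <- canonical_pose(mesh)
    similarity_pose(base$rotation,
                    base$translation + c(0.3 * f, -0.2 * f, 0), 1)
  })
  ids <- topo$landmark_subset[c(3, 10, 18, 25, 33, 40)]
  tracks <- structure(list(
    frames = lapply(poses, function(p)
      list(points = project(mesh$vertices[ids, ], p, cam)$points,
           lost = rep(FALSE, length(ids)))),
    vertex_ids = ids, frame_ids = seq_len(n)),
    class = "landmark_tracks")
  dn <- densify(tracks, mesh, cam)
  expect_length(dn$skipped, 0L)
  for (f in seq_len(n)) {
    truth <- project(mesh$vertices, poses[[f]], cam)$points
    got <- dn$frames[[f]]$landmarks$points
    expect_identical(nrow(got), nrow(mesh$vertices))
    expect_lt(sqrt(mean((got - truth)^2)), 0.5)
  }
  # fixed point: re-estimating the pose from its own dense output
  # reproduces the same projections
  f1 <- dn$frames[[1]]
  sub <- seq(1, nrow(mesh$vertices), by = 40)
  corr <- correspondence_set(sub, f1$landmarks$points[sub, 1],
                             f1$landmarks$points[sub, 2])
  pose2 <- estimate_pose(corr, mesh$vertices, cam, init = f1$pose)
  expect_lt(max(abs(project(mesh$vertices, pose2, cam)$points -
                      f1$landmarks$points)), 1e-6)
})

test_that("frames with fewer than four tracks are skipped and reported", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 17), topo)
  cam <- toy_cam(128)
  pose <- canonical_pose(mesh)
  ids <- topo$landmark_subset[c(3, 10, 18, 25)]
  pts <- project(mesh$vertices[ids, ], pose, cam)$points
  tracks <- structure(list(
    frames = list(list(points = pts, lost = rep(FALSE, 4)),
                  list(points = pts, lost = c(FALSE, TRUE, FALSE, FALSE))),
    vertex_ids = ids, frame_ids = 1:2),
    class = "landmark_tracks")
  dn <- densify(tracks, mesh, cam)
  expect_identical(dn$skipped, 2L)
  expect_null(dn$frames[[2]]$landmarks)
})

toy_dense <- function(jump_frame = NULL, rmse = c(0, 0, 0, 0)) {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 19), topo)
  cam <- toy_cam(128)
  frames <- lapply(seq_len(4), function(f) {
    base <- canonical_pose(mesh)
    tr <- if (!is.null(jump_frame) && f == jump_frame)
      base$translation + c(150, 0, 200) else base$translation
    pose <- similarity_pose(base$rotation, tr, 1)
    list(landmarks = project(mesh$vertices, pose, cam),
         pose = pose, reproj_rmse = rmse[f])
  })
  structure(list(frames = frames, skipped = integer(0), cam = cam,
                 frame_ids = 1:4), class = "dense_annotation")
}

test_that("clean static sequences pass the quality filter entirely", {
  rep <- quality_filter(toy_dense())
  expect_true(all(rep$accepted))
  expect_equal(rep$pose_change[1], 0)
})

test_that("a teleported pose rejects exactly that frame", {
  rep <- quality_filter(toy_dense(jump_frame = 3))
  expect_identical(which(!rep$accepted), 3L)
})

test_that("a zero RMSE threshold keeps only noise-free frames", {
  rep <- quality_filter(toy_dense(rmse = c(0, 0.4, 0, 0.2)), max_rmse = 0)
  expect_identical(rep$accepted, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("survivor counts are monotone as thresholds tighten", {
  dense <- toy_dense(jump_frame = 4, rmse = c(0, 1, 2, 3))
  for (th in list(c(3, 0.1), c(1.5, 0.1), c(0.5, 0.05), c(0, 0.01))) {
    a <- sum(quality_filter(dense, max_rmse = th[1], max_jump = th[2])$accepted)
    b <- sum(quality_filter(dense, max_rmse = th[1] + 1,
                            max_jump = th[2] * 2)$accepted)
    expect_lte(a, b)
  }
})

test_that("quality reports serialize as the documented CSV", {
  rep <- quality_filter(toy_dense())
  path <- tempfile(fileext = ".csv")
  write_quality_report(rep, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("frame_id", "n_in_bounds", "reproj_rmse",
                     "pose_change", "accepted"))
  expect_identical(nrow(back), 4L)
})
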