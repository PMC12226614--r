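test_that("a zero-mode model reduces to pure pose recovery", {
  topo <- toy_topology()
  mdl <- toy_model()
  mdl0 <- mdl
  mdl0$components <- mdl$components[0, , drop = FALSE]
  mdl0$variances <- numeric(0)
  mean_mesh <- predict(mdl0)
  pose <- random_view_pose(mean_mesh, seed = 21)
  cam <- toy_cam(256)
  lm <- project(mean_mesh$vertices[topo$landmark_subset, ], pose, cam)
  fit <- fit_flipflop(lm, mdl0, cam)
  expect_length(coef(fit), 0L)
  expect_lt(fit$residual_rmse, 1e-3)
  expect_true(fit$converged)
})

test_that("exact in-distribution landmarks are recovered to sub-0.5 mm", {
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam(256)
  for (s in c(5, 23)) {
    truth <- predict(mdl, as.numeric(simulate(mdl, 1, seed = s)))
    pose <- random_view_pose(truth, seed = s + 1)
    lm <- project(truth$vertices[topo$landmark_subset, ], pose, cam)
    fit <- fit_flipflop(lm, mdl, cam)
    expect_lt(fit$residual_rmse, 0.1)
    err <- surface_error(predict(fit), truth,
                         region = topo$contact_region)
    expect_lt(err$mean, 0.5)
  }
})

test_that("the joint cost never increases across outer iterations", {
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam(256)
  truth <- predict(mdl, as.numeric(simulate(mdl, 1, seed = 31)))
  pose <- random_view_pose(truth, seed = 32)
  lm <- project(truth$vertices[topo$landmark_subset, ], pose, cam)
  fit <- fit_flipflop(lm, mdl, cam)
  expect_true(all(diff(fit$cost_trace) <= 1e-9))
})

test_that("region emphasis shrinks residuals inside the weighted patch", {
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam(256)
  # conflicting landmarks: patch observations from shape A, the rest
  # from shape B
  wA <- as.numeric(simulate(mdl, 1, seed = 41))
  wB <- as.numeric(simulate(mdl, 1, seed = 42))
  shapeA <- predict(mdl, wA); shapeB <- predict(mdl, wB)
  pose <- random_view_pose(shapeA, seed = 43)
  sub <- topo$landmark_subset
  patch <- which(sub %in% topo$contact_region)[1:10]
  ptsA <- project(shapeA$vertices[sub, ], pose, cam)$points
  ptsB <- project(shapeB$vertices[sub, ], pose, cam)$points
  mixed <- ptsB; mixed[patch, ] <- ptsA[patch, ]
  lm <- landmarks2d(mixed)
  wts <- rep(0, length(sub)); wts[patch] <- 1
  fit_patch <- fit_flipflop(lm, mdl, cam,
                            flipflop_control(point_weights = wts))
  fit_unif <- fit_flipflop(lm, mdl, cam)
  expect_lt(mean(residuals(fit_patch)[patch]),
            mean(residuals(fit_unif)[patch]))
})

test_that("inflating sigma2 on a subset favors the complementary subset", {
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam(256)
  truth <- predict(mdl, as.numeric(simulate(mdl, 1, seed = 51)))
  pose <- random_view_pose(truth, seed = 52)
  sub <- topo$landmark_subset
  pts <- project(truth$vertices[sub, ], pose, cam)$points
  set.seed(53)
  noisy <- pts + matrix(rnorm(length(pts), 0, 2), ncol = 2)
  half <- seq_len(length(sub) %/% 2)
  s2 <- rep(1, length(sub)); s2[half] <- 100
  fit_w <- fit_flipflop(landmarks2d(noisy, sigma2 = s2), mdl, cam,
                        flipflop_control(use_sigma_weighting = TRUE))
  fit_u <- fit_flipflop(landmarks2d(noisy), mdl, cam)
  comp <- setdiff(seq_along(sub), half)
  expect_lte(mean(residuals(fit_w)[comp]),
             mean(residuals(fit_u)[comp]) + 1e-6)
})

test_that("degenerate landmark inputs are rejected", {
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam()
  expect_error(fit_flipflop(landmarks2d(cbind(1:5, 1:5)), mdl, cam),
               "topology error")
  wts <- rep(0, length(topo$landmark_subset)); wts[1:3] <- 1
  expect_error(flipflop_control(point_weights = wts), "at least 4")
})

test_that("the full image pipeline composes its stages", {
  tp <- tiny_predictor()
  topo <- toy_topology()
  mdl <- toy_model()
  cam <- toy_cam(32)
  img <- png::readPNG(list.files(file.path(tp$dir, "images"),
                                 full.names = TRUE)[1])[, , 1:3]
  rec <- reconstruct_from_image(img, tp$predictor, mdl, cam,
                                flipflop_control(max_outer_iters = 10))
  expect_s3_class(rec$mesh, "tri_mesh")
  expect_s3_class(rec$fit, "flipflop_fit")
  # ground-truth landmarks short-circuit to fit_flipflop itself
  lm <- predict(tp$predictor, img)
  direct <- fit_flipflop(lm, mdl, cam,
                         flipflop_control(max_outer_iters = 10))
  expect_equal(rec$fit$coef, direct$coef)
  expect_equal(rec$mesh$vertices, predict(direct)$vertices)
  # mismatched landmark counts raise a topology error
  mdl_small <- mdl
  mdl_small$topology$landmark_subset <-
    mdl$topology$landmark_subset[1:10]
  expect_error(reconstruct_from_image(img, tp$predictor, mdl_small, cam),
               "topology error")
})
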