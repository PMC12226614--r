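test_that("the NLL loss matches its closed form", {
  expect_equal(gaussian_nll(1, 1, 1), 0)
  expect_equal(gaussian_nll(2, 1, 1), 0.5)
  # variance floored at machine epsilon stays finite
  expect_equal(gaussian_nll(3, 3, 0), 0.5 * log(.Machine$double.eps))
  expect_error(gaussian_nll(NA, 1, 1), "finite")
  expect_error(gaussian_nll(1, 1, 1, eps = 0), "eps")
})

test_that("loss reductions satisfy sum = mean * count", {
  set.seed(1)
  y <- rnorm(40); mu <- rnorm(40); s2 <- runif(40, 0.1, 3)
  expect_equal(gaussian_nll(y, mu, s2, reduction = "sum"),
               gaussian_nll(y, mu, s2, reduction = "mean") * 40)
  expect_length(gaussian_nll(y, mu, s2, reduction = "none"), 40L)
})

test_that("for a fixed error the loss is minimized at sigma2 = error^2", {
  for (err in c(0.5, 1, 2.5)) {
    grid <- seq(err^2 / 10, err^2 * 10, length.out = 20000)
    vals <- gaussian_nll(rep(err, length(grid)), 0, grid,
                         reduction = "none")
    expect_equal(grid[which.min(vals)], err^2, tolerance = 1e-2)
    # and the analytic minimizer beats both floor and inflation
    expect_lt(gaussian_nll(err, 0, err^2), gaussian_nll(err, 0, err^2 / 4))
    expect_lt(gaussian_nll(err, 0, err^2), gaussian_nll(err, 0, err^2 * 4))
  }
})

test_that("identity augmentation returns its input bit-exact", {
  set.seed(2)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lm <- landmarks2d(cbind(runif(5, 2, 29), runif(5, 2, 29)))
  out <- augment(img, lm, seed = 1, max_rot_deg = 0, flip_prob = 0,
                 color_shift = 0, noise_sd = 0)
  expect_identical(out$image, img)
  expect_identical(out$landmarks$points, lm$points)
})

test_that("landmark coordinates follow the analytic rotation", {
  pts <- cbind(c(10, 25, 3), c(5, 28, 17))
  W <- 32; H <- 32
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  for (ang_deg in c(90, -90, 37)) {
    ang <- ang_deg * pi / 180
    got <- cleftrecon:::rotate_points(pts, ang, W, H)
    exp_u <- cx + cos(ang) * (pts[, 1] - cx) + sin(ang) * (pts[, 2] - cy)
    exp_v <- cy - sin(ang) * (pts[, 1] - cx) + cos(ang) * (pts[, 2] - cy)
    expect_equal(got, cbind(exp_u, exp_v), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("image content and landmarks rotate together", {
  # a bright dot at a known pixel must follow its landmark
  img <- array(0, c(33, 33, 3))
  img[9, 25, ] <- 1                       # (u = 24, v = 8)
  lm <- landmarks2d(cbind(24, 8))
  out <- augment(img, lm, seed = 1, max_rot_deg = 0, flip_prob = 0,
                 color_shift = 0, noise_sd = 0)
  rot <- cleftrecon:::rotate_image(img, pi / 2)
  pts <- cleftrecon:::rotate_points(lm$points, pi / 2, 33, 33)
  expect_equal(rot[round(pts[1, 2]) + 1, round(pts[1, 1]) + 1, 1], 1,
               tolerance = 1e-6)
})

test_that("a double horizontal flip restores the original", {
  set.seed(3)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  lm <- landmarks2d(cbind(runif(4, 1, 14), runif(4, 1, 14)))
  once <- augment(img, lm, seed = 5, max_rot_deg = 0, flip_prob = 1,
                  color_shift = 0, noise_sd = 0)
  twice <- augment(once$image, once$landmarks, seed = 6, max_rot_deg = 0,
                   flip_prob = 1, color_shift = 0, noise_sd = 0)
  expect_identical(twice$image, img)
  expect_equal(twice$landmarks$points, lm$points)
})
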