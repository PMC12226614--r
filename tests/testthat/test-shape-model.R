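test_that("two meshes give exactly one mode capturing all variance", {
  fam <- toy_family()
  mdl <- shape_model(fam[1:2], topology = toy_topology())
  expect_identical(length(mdl$variances), 1L)
  expect_equal(sum(mdl$variances) / mdl$total_variance, 1)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  # oracle: eigen() of the Gram matrix of the centered, aligned data
  fam <- toy_family()[1:20]
  mdl <- shape_model(fam, variance_threshold = 1, align = FALSE)
  X <- do.call(rbind, lapply(fam, function(m) as.numeric(t(m$vertices))))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(Xc %*% t(Xc) / (nrow(X) - 1), symmetric = TRUE)
  k <- length(mdl$variances)
  expect_equal(mdl$variances, ev$values[seq_len(k)], tolerance = 1e-6)
  # eigenvectors agree up to sign
  V <- crossprod(Xc, ev$vectors[, seq_len(k)])
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  dots <- abs(colSums(t(mdl$components) * V))
  expect_equal(dots, rep(1, k), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("threshold 1 retains the full rank n - 1", {
  fam <- toy_family()[1:8]
  mdl <- shape_model(fam, variance_threshold = 1)
  expect_identical(length(mdl$variances), 7L)
})

test_that("component rows are orthonormal and variances descend", {
  mdl <- toy_model()
  G <- tcrossprod(mdl$components)
  expect_equal(max(abs(G - diag(nrow(G)))), 0, tolerance = 1e-8)
  expect_true(all(diff(mdl$variances) <= 1e-12))
  expect_true(all(mdl$variances >= 0))
  expect_gte(sum(mdl$variances) / mdl$total_variance, 0.999)
})

test_that("reconstruction is the linear model mean + t(B) w", {
  mdl <- toy_model()
  expect_equal(predict(mdl)$vertices,
               matrix(mdl$mean_shape, ncol = 3, byrow = TRUE),
               ignore_attr = TRUE)
  w <- numeric(length(mdl$variances)); w[1] <- 1
  rec <- predict(mdl, w)
  expect_equal(as.numeric(t(rec$vertices)),
               mdl$mean_shape + mdl$components[1, ])
  expect_error(predict(mdl, numeric(2)), "dimension")
})

test_that("encode/decode is the identity on training meshes (full rank)", {
  fam <- toy_family()[1:10]
  mdl <- shape_model(fam, variance_threshold = 1, align = FALSE)
  for (m in fam[c(1, 5, 10)]) {
    rec <- predict(mdl, shape_coef(mdl, m))
    expect_lt(sqrt(mean((rec$vertices - m$vertices)^2)), 1e-6)
  }
})

test_that("projection onto the model leaves an orthogonal residual", {
  mdl <- toy_model()
  expect_equal(shape_coef(mdl, predict(mdl)),
               numeric(length(mdl$variances)), tolerance = 1e-8)
  # mean + 2 * mode_3 encodes to the unit vector scaled by 2
  w <- numeric(length(mdl$variances)); w[3] <- 2
  expect_equal(shape_coef(mdl, predict(mdl, w)), w, tolerance = 1e-8)
  # random out-of-subspace mesh: residual orthogonal to every component
  set.seed(42)
  m <- toy_family()[[25]]
  rec <- predict(mdl, shape_coef(mdl, m))
  resid <- as.numeric(t(m$vertices)) - as.numeric(t(rec$vertices))
  expect_lt(max(abs(mdl$components %*% resid)), 1e-6)
})

test_that("simulated coefficients are reproducible and match variances", {
  mdl <- toy_model()
  a <- simulate(mdl, 5, seed = 77)
  b <- simulate(mdl, 5, seed = 77)
  expect_identical(a, b)
  draws <- simulate(mdl, 10000, seed = 78)
  sv <- apply(draws, 2, stats::var)
  lead <- which(mdl$variances > 1e-8)[1:5]
  expect_equal(sv[lead] / mdl$variances[lead], rep(1, 5),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("zero-variance modes always draw zero weights", {
  fam <- toy_family()
  dup <- list(fam[[1]], fam[[1]])
  mdl <- shape_model(dup, align = FALSE)
  expect_equal(max(abs(simulate(mdl, 100, seed = 1))), 0)
})

test_that("reconstruction_error reports per-vertex distances and regions", {
  fam <- toy_family()[1:10]
  topo <- toy_topology()
  mdl <- shape_model(fam, variance_threshold = 1, align = FALSE,
                     topology = topo)
  expect_lt(reconstruction_error(mdl, fam[[2]])$mean, 1e-6)
  # a discarded direction: error equals that component's magnitude
  mdl_trunc <- mdl
  drop_row <- mdl$components[length(mdl$variances), ]
  mdl_trunc$components <- mdl$components[-length(mdl$variances), ,
                                         drop = FALSE]
  mdl_trunc$variances <- mdl$variances[-length(mdl$variances)]
  m <- predict(mdl, c(numeric(length(mdl_trunc$variances)), 3))
  err <- reconstruction_error(mdl_trunc, m)
  disp <- 3 * sqrt(rowSums(matrix(drop_row, ncol = 3, byrow = TRUE)^2))
  expect_equal(err$per_vertex, disp, tolerance = 1e-8)
  # single-vertex region
  err1 <- reconstruction_error(mdl_trunc, m, region = 7L)
  expect_equal(err1$mean, disp[7], tolerance = 1e-8)
  expect_error(reconstruction_error(mdl, fam[[1]], region = integer(0)),
               "empty region")
})

test_that("Procrustes pre-alignment makes the model rigid-invariant", {
  fam <- toy_family()[1:12]
  R <- cleftrecon:::rotvec_to_matrix(c(0.4, -0.7, 0.25))
  rot <- lapply(fam, function(m)
    tri_mesh(m$vertices %*% t(R) + 5, m$faces))
  m1 <- shape_model(fam)
  m2 <- shape_model(rot)
  expect_equal(m1$variances, m2$variances, tolerance = 1e-6)
})

test_that("model build rejects degenerate input", {
  fam <- toy_family()
  expect_error(shape_model(fam[1]), "insufficient-data")
  small <- tri_mesh(diag(3) * 10, matrix(c(1L, 2L, 3L), 1))
  expect_error(shape_model(list(fam[[1]], small)), "topology")
})

test_that("shape models survive a serialization round-trip", {
  mdl <- toy_model()
  path <- tempfile(fileext = ".bin")
  write_shape_model(mdl, path)
  back <- read_shape_model(path)
  expect_equal(back$mean_shape, mdl$mean_shape)
  expect_equal(back$components, mdl$components, ignore_attr = TRUE)
  expect_equal(back$variances, mdl$variances)
  expect_identical(back$topology$landmark_subset,
                   mdl$topology$landmark_subset)
  expect_identical(back$topology$contact_region,
                   mdl$topology$contact_region)
  expect_identical(back$faces, mdl$faces, ignore_attr = TRUE)
})
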