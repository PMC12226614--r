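test_that("palate generation is deterministic and parameter-validated", {
  topo <- toy_topology()
  a <- generate_palate(palate_params(seed = 4), topo)
  b <- generate_palate(palate_params(seed = 4), topo)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$vertex_colors, b$vertex_colors)
  expect_error(palate_params(dome_width = -1), "positive")
  expect_error(palate_params(cleft_width = -2), "cleft_width")
  expect_error(palate_params(noise_amplitude = -0.1), "noise_amplitude")
})

test_that("zero cleft width yields a bilaterally symmetric surface", {
  topo <- toy_topology()
  p <- palate_params(cleft_width = 0, noise_amplitude = 0,
                     cleft_laterality = 3)
  m <- generate_palate(p, topo)
  nu <- topo$nu
  mirror <- as.integer(outer(nu:1, (seq_len(topo$nv) - 1L) * nu, `+`))
  v <- m$vertices
  vm <- v[mirror, ]
  vm[, 1] <- -vm[, 1]
  expect_equal(v, vm, tolerance = 1e-9)
  # flipping laterality is irrelevant without a cleft
  p2 <- palate_params(cleft_width = 0, noise_amplitude = 0,
                      cleft_laterality = -3)
  expect_equal(generate_palate(p2, topo)$vertices, v)
})

test_that("the anterior gap grows monotonically with cleft width", {
  topo <- toy_topology()
  gaps <- vapply(c(0, 2, 4, 8, 12), function(cw)
    cleft_gap(generate_palate(palate_params(cleft_width = cw, seed = 2),
                              topo), topo), 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("rendered samples satisfy the exact projection identity", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 6), topo)
  cam <- toy_cam(96)
  pose <- random_view_pose(mesh, seed = 3)
  smp <- render(mesh, pose, cam, topo, blur_px = 1.5)
  pr <- project(mesh$vertices[topo$landmark_subset, ], pose, cam)
  expect_equal(smp$landmarks$points, pr$points, tolerance = 1e-9)
  expect_true(all(smp$image >= 0 & smp$image <= 1))
  # determinism: identical seed, identical image
  smp2 <- render(mesh, pose, cam, topo, blur_px = 1.5)
  expect_identical(smp$image, smp2$image)
})

test_that("flat shading is proportional to the normal/light cosine", {
  # single tilted triangle with white albedo: every covered pixel must
  # equal |cos(normal, light)| exactly
  v <- rbind(c(-30, -30, 100), c(30, -30, 100), c(0, 40, 130))
  mesh <- tri_mesh(v, matrix(c(1L, 2L, 3L), 1),
                   vertex_colors = matrix(1, 3, 3))
  cam <- camera_intrinsics(200, 200, 64, 64, 128, 128)
  topo_stub <- structure(list(landmark_subset = 1L), class = "template_topology")
  smp <- render(mesh, similarity_pose(), cam, topo_stub,
                light_dir = c(0, 0, 1))
  e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  expected <- abs(n[3]) / sqrt(sum(n^2))
  center_px <- smp$image[64, 64, 1]     # interior pixel of the triangle
  expect_equal(center_px, expected, tolerance = 1e-10)
})

test_that("rendering is resolution-covariant", {
  topo <- toy_topology()
  mesh <- generate_palate(palate_params(seed = 7), topo)
  pose <- random_view_pose(mesh, seed = 5)
  lo <- render(mesh, pose, toy_cam(64), topo)
  hi <- render(mesh, pose, toy_cam(128), topo)
  expect_equal(hi$landmarks$points, lo$landmarks$points * 2,
               tolerance = 1e-9)
})

test_that("datasets have the documented layout and are reproducible", {
  topo <- toy_topology()
  meshes <- toy_family()[1:3]
  d1 <- tempfile("ds1"); d2 <- tempfile("ds2")
  man <- make_dataset(meshes, topo, d1, images_per_mesh = 5L,
                      image_size = 48L, seed = 9)
  expect_identical(nrow(man), 15L)
  expect_true(all(file.exists(file.path(d1, man$image))))
  expect_true(all(file.exists(file.path(d1, man$landmarks))))
  # default volume matches the study design: 100 renders per mesh
  expect_identical(eval(formals(make_dataset)$images_per_mesh), 100L)
  make_dataset(meshes, topo, d2, images_per_mesh = 5L,
               image_size = 48L, seed = 9)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  lmf <- man$landmarks[7]
  expect_identical(readLines(file.path(d1, lmf)),
                   readLines(file.path(d2, lmf)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("leading PCA modes explain the generative cleft width", {
  topo <- toy_topology()
  fam_par <- sample_palate_params(50, seed = 31)
  meshes <- lapply(fam_par, generate_palate, topology = topo)
  mdl <- shape_model(meshes, topology = topo)
  W <- t(vapply(meshes, function(m) shape_coef(mdl, m),
                numeric(length(mdl$variances))))
  cw <- vapply(fam_par, `[[`, 0, "cleft_width")
  r2 <- summary(stats::lm(cw ~ W))$r.squared
  expect_gt(r2, 0.9)
})
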