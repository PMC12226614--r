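# Shared fixtures, built once per test run. Everything is generated in
# code from seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

toy_topology <- function() {
  fixture("toy_topology", function()
    palate_template(nu = 20L, nv = 20L, n_landmarks = 40L))
}

toy_family <- function() {
  fixture("toy_family", function() {
    topo <- toy_topology()
    lapply(sample_palate_params(25, seed = 101),
           generate_palate, topology = topo)
  })
}

toy_model <- function() {
  fixture("toy_model", function()
    shape_model(toy_family()[1:20], topology = toy_topology()))
}

toy_cam <- function(size = 128L) approximate_intrinsics(size, size)

# A tiny trained predictor shared across predictor/fit tests.
tiny_predictor <- function() {
  fixture("tiny_predictor", function() {
    topo <- toy_topology()
    mesh <- generate_palate(palate_params(seed = 3), topo)
    dir <- tempfile("tinypred")
    make_dataset(list(mesh), topo, dir, images_per_mesh = 10L,
                 image_size = 32L, seed = 5)
    cfg <- predictor_config(image_size = 32L, n_landmarks = 40L,
                            channels = c(4L, 8L), fc_hidden = 32L,
                            epochs = 3L, batch_size = 5L, seed = 2)
    list(predictor = train_predictor(dir, cfg), dir = dir, mesh = mesh)
  })
}
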