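#' Parameters of the synthetic palate generator
#'
#' The generator emulates neonatal cleft palate geometry as a parametric
#' height field over a fixed grid: a smooth dome, two lateral alveolar
#' ridge bulges, and an anterior cleft modelled as a lateral separation of
#' the two segments plus a groove, at a configurable lateral offset.
#' Defaults are sized for a neonatal maxilla (mm).
#'
#' @param dome_width,dome_length,dome_height overall palate extent (mm).
#' @param ridge_height,ridge_width alveolar ridge bulge size (mm).
#' @param cleft_width lateral separation of the anterior segments (mm, >= 0;
#'   0 means no cleft).
#' @param cleft_laterality signed lateral offset of the cleft line (mm;
#'   sign encodes the side).
#' @param noise_amplitude RMS amplitude of the smooth per-identity shape
#'   perturbation (mm).
#' @param seed integer seed for the perturbation and coloring.
#' @return An object of class `palate_params`.
#' @export
palate_params <- function(dome_width = 34, dome_length = 38, dome_height = 11,
                          ridge_height = 3, ridge_width = 4.5,
                          cleft_width = 8, cleft_laterality = 2,
                          noise_amplitude = 0.4, seed = 1L) {
  sizes <- c(dome_width, dome_length, dome_height, ridge_height, ridge_width)
  if (any(sizes <= 0)) stop("size parameters must be positive")
  if (cleft_width < 0) stop("cleft_width must be >= 0")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  structure(list(dome_width = dome_width, dome_length = dome_length,
                 dome_height = dome_height, ridge_height = ridge_height,
                 ridge_width = ridge_width, cleft_width = cleft_width,
                 cleft_laterality = cleft_laterality,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed)),
            class = "palate_params")
}

# Lateral positions (in normalized u) of the two ridge crests.
RIDGE_U <- c(0.20, 0.80)

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Height-field geometry shared by generate_palate() and the canonical
# template surface. u: lateral in [0,1]; v: posterior (0) to anterior (1).
palate_surface <- function(params, nu, nv) {
  p <- params
  u <- rep(seq(0, 1, length.out = nu), times = nv)
  v <- rep(seq(0, 1, length.out = nv), each = nu)
  x <- (u - 0.5) * p$dome_width
  y <- (v - 0.5) * p$dome_length
  z <- p$dome_height * sin(pi * u) * sin(pi * v)

  su <- p$ridge_width / p$dome_width      # ridge gaussian width in u units
  ridge <- exp(-0.5 * ((u - RIDGE_U[1]) / su)^2) +
    exp(-0.5 * ((u - RIDGE_U[2]) / su)^2)
  z <- z + p$ridge_height * ridge * sqrt(pmax(sin(pi * v), 0))

  if (p$cleft_width > 0) {
    xc <- p$cleft_laterality
    h <- smoothstep((v - 0.5) / 0.45)^2   # anterior taper
    d <- x - xc
    # lateral separation of the two segments, saturating away from the line
    sep <- sign(d) * (p$cleft_width / 2) * (1 - exp(-abs(d) / 2)) * h
    x <- x + sep
    groove <- exp(-0.5 * (d / (0.35 * p$cleft_width + 0.8))^2) * h
    z <- z - (0.6 * p$dome_height + p$ridge_height) *
      min(1, p$cleft_width / 2) * groove
  }
  cbind(x, y, z)
}

smooth_noise_field <- function(nu, nv, amplitude, rng_n = 6L) {
  u <- rep(seq(0, 1, length.out = nu), times = nv)
  v <- rep(seq(0, 1, length.out = nv), each = nu)
  field <- numeric(nu * nv)
  for (j in seq_len(rng_n)) {
    f <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    field <- field + a * cos(2 * pi * (f[1] * u + f[2] * v) + ph)
  }
  s <- stats::sd(field)
  if (s > 0) field <- field / s
  field * amplitude
}

#' Fixed template topology of the palate grid
#'
#' All synthetic palates share this topology, giving template
#' correspondence by construction: vertex `i` is the same grid location on
#' every generated mesh. The default 100 x 100 grid yields 10,000 vertices.
#' The contact region collects the vertices on the two alveolar ridge
#' bands (the area a presurgical orthopedic plate touches), and the
#' landmark subset is a weighted farthest-point subsample with higher
#' density on those bands (see [subsample_landmarks()]).
#'
#' @param nu,nv grid resolution (lateral x anteroposterior).
#' @param n_landmarks size of the landmark subset (default one tenth of
#'   the vertex count).
#' @param ridge_weight sampling-density multiplier on the contact region.
#' @param seed seed for the deterministic landmark subsample.
#' @return An object of class `template_topology` with fields `faces`,
#'   `n_vertices`, `contact_region`, `landmark_subset`.
#' @export
palate_template <- function(nu = 100L, nv = 100L,
                            n_landmarks = round(nu * nv / 10),
                            ridge_weight = 4, seed = 1L) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  if (nu < 4L || nv < 4L) stop("grid must be at least 4 x 4")
  idx <- function(iu, iv) (iv - 1L) * nu + iu
  iu <- rep(seq_len(nu - 1L), times = nv - 1L)
  iv <- rep(seq_len(nv - 1L), each = nu - 1L)
  a <- idx(iu, iv); b <- idx(iu + 1L, iv)
  cc <- idx(iu, iv + 1L); d <- idx(iu + 1L, iv + 1L)
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))

  u <- rep(seq(0, 1, length.out = nu), times = nv)
  v <- rep(seq(0, 1, length.out = nv), each = nu)
  band <- 0.05
  contact <- which((abs(u - RIDGE_U[1]) <= band | abs(u - RIDGE_U[2]) <= band) &
                     v >= 0.15 & v <= 0.95)

  topo <- structure(list(faces = faces, n_vertices = nu * nv,
                         nu = nu, nv = nv, grid_u = u, grid_v = v,
                         contact_region = contact,
                         landmark_subset = integer(0)),
                    class = "template_topology")
  topo$canonical_vertices <-
    palate_surface(palate_params(cleft_width = 0, noise_amplitude = 0), nu, nv)
  topo$landmark_subset <- subsample_landmarks(topo, n = n_landmarks,
                                              ridge_weight = ridge_weight,
                                              seed = seed)
  topo
}

#' @export
print.template_topology <- function(x, ...) {
  cat(sprintf(
    "template_topology: %d vertices (%d x %d grid), %d faces\n",
    x$n_vertices, x$nu, x$nv, nrow(x$faces)))
  cat(sprintf("  contact region: %d vertices; landmark subset: %d vertices\n",
              length(x$contact_region), length(x$landmark_subset)))
  invisible(x)
}

#' Generate a synthetic palate mesh in template correspondence
#'
#' Evaluates the parametric palate height field on the template grid and
#' adds a seeded smooth random displacement, so every call with the same
#' parameters and seed is identical and all meshes share the template
#' topology. Per-vertex colors mimic mucosal tissue with a seeded mottled
#' pattern (useful as tracking texture and for rendering).
#'
#' @param params a [palate_params()].
#' @param topology a [palate_template()]; its grid resolution determines
#'   the vertex count.
#' @return A [tri_mesh()] with vertex colors.
#' @export
generate_palate <- function(params, topology = palate_template()) {
  stopifnot(inherits(params, "palate_params"),
            inherits(topology, "template_topology"))
  nu <- topology$nu; nv <- topology$nv
  vert <- palate_surface(params, nu, nv)
  fields <- local_rng(params$seed)(list(
    noise = smooth_noise_field(nu, nv, params$noise_amplitude),
    mottle = smooth_noise_field(nu, nv, 0.06, rng_n = 10L)))
  if (params$noise_amplitude > 0)
    vert[, 3] <- vert[, 3] + fields$noise
  base <- c(0.85, 0.52, 0.48)
  mottle <- fields$mottle
  shade <- 0.5 + 0.5 * (vert[, 3] - min(vert[, 3])) / max(diff(range(vert[, 3])), 1e-9)
  cols <- cbind(base[1] * shade + mottle,
                base[2] * shade + 0.6 * mottle,
                base[3] * shade + 0.6 * mottle)
  tri_mesh(vert, topology$faces, vertex_colors = pmin(pmax(cols, 0), 1))
}

# Run expr-like function under a local, seeded RNG without disturbing the
# caller's RNG state.
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
  }
}

#' Draw a family of palate identities
#'
#' Samples generator parameters from declared neonatal ranges: width
#' 28-38 mm, length 32-42 mm, dome height 8-14 mm, ridge height 2-4 mm,
#' ridge width 3-6 mm, cleft width 0-12 mm, laterality -4 to 4 mm.
#'
#' @param n number of identities.
#' @param seed integer seed.
#' @param cleft_range range of cleft widths (mm).
#' @return A list of [palate_params()].
#' @export
sample_palate_params <- function(n, seed = 1L, cleft_range = c(0, 12)) {
  rng <- local_rng(seed)
  rng({
    lapply(seq_len(n), function(i) {
      palate_params(
        dome_width = stats::runif(1, 28, 38),
        dome_length = stats::runif(1, 32, 42),
        dome_height = stats::runif(1, 8, 14),
        ridge_height = stats::runif(1, 2, 4),
        ridge_width = stats::runif(1, 3, 6),
        cleft_width = stats::runif(1, cleft_range[1], cleft_range[2]),
        cleft_laterality = stats::runif(1, -4, 4),
        noise_amplitude = 0.4,
        seed = sample.int(1e6, 1))
    })
  })
}

#' Measure the anterior inter-segment gap of a generated palate
#'
#' Mean distance between paired left/right ridge-crest vertices on the
#' anterior rows; increases with the generator's `cleft_width`.
#'
#' @param mesh a generated palate [tri_mesh()].
#' @param topology the matching [palate_template()].
#' @return gap in mm.
#' @export
cleft_gap <- function(mesh, topology) {
  nu <- topology$nu; nv <- topology$nv
  iul <- which.min(abs(seq(0, 1, length.out = nu) - RIDGE_U[1]))
  iur <- which.min(abs(seq(0, 1, length.out = nu) - RIDGE_U[2]))
  rows <- which(seq(0, 1, length.out = nv) > 0.75)
  li <- (rows - 1L) * nu + iul
  ri <- (rows - 1L) * nu + iur
  mean(sqrt(rowSums((mesh$vertices[li, ] - mesh$vertices[ri, ])^2)))
}
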