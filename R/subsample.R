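#' Sub-sample template vertices as landmarks
#'
#' Deterministic (seeded) weighted farthest-point sampling over the
#' template's canonical geometry. Vertices in the contact region carry a
#' `ridge_weight`-fold selection density, so the plate-contact ridge bands
#' are sampled more densely than the rest of the palate; with
#' `ridge_weight = 1` this reduces to plain farthest-point sampling. The
#' default template configuration selects 1,000 of 10,000 vertices.
#'
#' @param topology a [palate_template()] (or any `template_topology` with
#'   `canonical_vertices` and `contact_region`).
#' @param n subset size (<= number of vertices).
#' @param ridge_weight density multiplier (>= 1) for contact-region
#'   vertices.
#' @param seed seed choosing the starting vertex.
#' @return Sorted integer vector of `n` unique vertex indices.
#' @export
subsample_landmarks <- function(topology, n, ridge_weight = 1, seed = 1L) {
  V <- topology$n_vertices
  if (n > V) stop("invalid-parameter: n exceeds the template vertex count")
  if (n < 1L) stop("invalid-parameter: n must be >= 1")
  if (ridge_weight < 1) stop("invalid-parameter: ridge_weight must be >= 1")
  X <- topology$canonical_vertices
  w <- rep(1, V)
  w[topology$contact_region] <- ridge_weight
  sel <- integer(n)
  sel[1L] <- local_rng(seed)(sample.int(V, 1L, prob = w))
  d2 <- rowSums(sweep(X, 2, X[sel[1L], ])^2)
  if (n > 1L) for (i in 2:n) {
    sel[i] <- which.max(w * d2)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[sel[i], ])^2))
  }
  sort(sel)
}
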