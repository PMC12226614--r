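#' Gaussian negative log-likelihood landmark loss
#'
#' Per-coordinate loss for a landmark regressor that predicts both a
#' position `mu` and a variance `sigma2`:
#' `L = 1/2 * ( log(max(sigma2, eps)) + (y - mu)^2 / max(sigma2, eps) )`.
#' The variance is floored at machine epsilon, so a zero predicted
#' variance stays finite. The loss penalizes uncertainty as well as a
#' wrong prediction made with high certainty; for a fixed error it is
#' minimized at `sigma2 = (y - mu)^2`.
#'
#' @param y reference coordinate(s).
#' @param mu predicted coordinate(s).
#' @param sigma2 predicted variance(s) (recycled against `y`).
#' @param eps variance floor (default machine epsilon).
#' @param reduction `"mean"`, `"sum"` or `"none"`.
#' @return The reduced loss, or the elementwise vector for
#'   `reduction = "none"`.
#' @export
gaussian_nll <- function(y, mu, sigma2, eps = .Machine$double.eps,
                         reduction = c("mean", "sum", "none")) {
  reduction <- match.arg(reduction)
  if (eps <= 0) stop("eps must be > 0")
  if (!all(is.finite(y), is.finite(mu), is.finite(sigma2)))
    stop("gaussian_nll: inputs must be finite")
  s2 <- pmax(sigma2, eps)
  l <- 0.5 * (log(s2) + (y - mu)^2 / s2)
  switch(reduction, mean = mean(l), sum = sum(l), none = l)
}
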