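#' Infinitesimal variance of the lethal-genotype chain
#'
#' The variance coefficient of the diffusion approximation,
#' \deqn{V(x) = \frac{[x + F(x)]\,[1 - (2x + 2F(x))]}{2N},}
#' which equals the exact one-step variance of the modified Wright-Fisher
#' chain (`Var[Bin(N, p)] / (2N)^2` with `p = 2x + 2F(x)`) identically, not
#' just asymptotically.
#'
#' @param x Frequency (or vector) in `[0, 1/2]`.
#' @param model A [lethal_model()] with finite `N`.
#' @return `V(x)`, same length as `x`.
#' @examples
#' infinitesimal_variance(1e-3, lethal_model(u = 1e-8, h = 0, N = 1000))
#' @export
infinitesimal_variance <- function(x, model) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  assert_frequency(x)
  f <- force_fn(x, model$h, model$u)
  (x + f) * (1 - (2 * x + 2 * f)) / (2 * model$N)
}

#' Small-frequency diffusion coefficients
#'
#' Leading-order forms of the drift and variance coefficients for
#' `x << 1` (neglecting terms of order `x^2`, `x u`, `u^2`), assuming the
#' allele is not fully dominant (`h != 1`):
#' \deqn{F(x) \approx u(1-h) - hx, \qquad V(x) \approx \frac{(1-h)(x+u)}{2N}.}
#' The variance form shows that at low frequency the chain fluctuates like
#' a neutral population of effective size `N / (1 - h)`, and that the
#' fluctuations persist even at `x = 0` (mutational input), unlike the
#' weak-selection chain.
#'
#' @param x Frequency (or vector); intended for `x << 1` (no hard cutoff).
#' @param model A [lethal_model()] with finite `N` and `h != 1`.
#' @return List with numeric vectors `drift` and `variance`.
#' @examples
#' small_x_coefficients(0, lethal_model(u = 1e-8, h = 0, N = 500))$drift
#' @export
small_x_coefficients <- function(x, model) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  if (model$h == 1)
    stop("small-x forms assume the allele is not fully dominant (h != 1)",
         call. = FALSE)
  assert_frequency(x)
  h <- model$h; u <- model$u
  list(drift = u * (1 - h) - h * x,
       variance = (1 - h) * (x + u) / (2 * model$N))
}

#' Tabulate diffusion coefficients over a frequency grid
#'
#' Convenience dump of the exact drift `F(x)` and variance `V(x)` together
#' with their small-`x` approximations, for plotting or export via
#' [write_table()].
#'
#' @param model A [lethal_model()] with finite `N`.
#' @param x Frequency grid (default 201 points over `[0, 1/2]`).
#' @return Data frame with columns `x`, `drift`, `variance`,
#'   `drift_small_x`, `variance_small_x`.
#' @export
diffusion_grid <- function(model, x = seq(0, 0.5, length.out = 201)) {
  approx <- small_x_coefficients(x, model)
  data.frame(x = x,
             drift = selection_force(x, model),
             variance = infinitesimal_variance(x, model),
             drift_small_x = approx$drift,
             variance_small_x = approx$variance)
}
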