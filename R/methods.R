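#' Expected frequency trajectory of a lethal-allele model
#'
#' For an infinite population this is the deterministic recursion; for a
#' finite population, the mean of the propagated state distribution
#' (starting from a point mass on the grid state nearest `x0`, or from the
#' stationary distribution when `x0 = "stationary"`).
#'
#' @param object A [lethal_model()].
#' @param x0 Initial frequency, `"equilibrium"` (infinite `N`), or
#'   `"stationary"` (finite `N`).
#' @param t_max Number of generations.
#' @param schedule Optional [dominance_schedule()]; defaults to constant
#'   `object$h`.
#' @param ... Unused.
#' @return Data frame with columns `t` and `x` (expected frequency).
#' @examples
#' m <- lethal_model(u = 1e-5, h = -0.01)
#' tail(predict(m, x0 = "equilibrium", t_max = 10), 1)
#' @export
predict.lethal_model <- function(object, x0 = "equilibrium", t_max = 100,
                                 schedule = NULL, ...) {
  if (is.null(schedule)) schedule <- object$h
  schedule <- as_dominance_schedule(schedule)
  if (!is.finite(object$N)) {
    if (identical(x0, "stationary")) x0 <- "equilibrium"
    tr <- trajectory_infinite(x0, schedule, object$u, t_max)
    return(data.frame(t = tr$t, x = tr$x))
  }
  N <- object$N
  if (identical(x0, "stationary") || identical(x0, "equilibrium")) {
    d0 <- stationary_distribution(
      lethal_model(u = object$u, h = dominance_at(schedule, 0), N = N))$pi
  } else {
    assert_frequency(x0, "x0")
    n0 <- as.integer(round(x0 * 2 * N))
    d0 <- numeric(N + 1L); d0[n0 + 1L] <- 1
  }
  pr <- propagate_distribution(d0, schedule, object, t_max)
  data.frame(t = pr$summary$t, x = pr$summary$mean_x)
}

#' Simulate stochastic trajectories of a finite lethal-allele population
#'
#' Draws `nsim` independent trajectories of the lethal-genotype
#' Wright-Fisher chain.
#'
#' @param object A [lethal_model()] with finite `N`.
#' @param nsim Number of trajectories.
#' @param seed Optional integer seed (recorded as an attribute).
#' @param x0 Initial frequency on the state grid (default 0).
#' @param t_max Number of generations (default 100).
#' @param schedule Optional [dominance_schedule()].
#' @param ... Unused.
#' @return A `(t_max + 1) x nsim` matrix of frequencies with attribute
#'   `"seed"`; row `t + 1` holds generation `t`.
#' @examples
#' m <- lethal_model(u = 0.01, h = 0, N = 50)
#' x <- simulate(m, nsim = 3, seed = 1, t_max = 20)
#' dim(x)
#' @export
simulate.lethal_model <- function(object, nsim = 1, seed = NULL, x0 = 0,
                                  t_max = 100, schedule = NULL, ...) {
  stopifnot(is.finite(object$N))
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(nsim), function(i)
    sample_trajectory(object, x0 = x0, t_max = t_max,
                      schedule = schedule, seed = NULL)$x,
    numeric(t_max + 1L))
  out <- matrix(out, nrow = t_max + 1L,
                dimnames = list(t = 0:t_max, sim = seq_len(nsim)))
  attr(out, "seed") <- seed
  out
}

#' Residual evolutionary force along a trajectory
#'
#' Returns `F(x_t)` for each frequency of a trajectory data frame; at
#' equilibrium the residual force vanishes.
#'
#' @param object A [lethal_model()].
#' @param trajectory Data frame with a column `x` (e.g. from
#'   [predict.lethal_model()]).
#' @param ... Unused.
#' @return Numeric vector of per-generation forces.
#' @export
residuals.lethal_model <- function(object, trajectory, ...) {
  selection_force(trajectory$x, object)
}
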