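## ------------------------------------------------------------------
## Modified Wright-Fisher chain for a lethal genotype.
##
## With one genotype lethal, selection must be applied at the level of
## genotypes; the offspring generation is built from N adults, of which
## the aA heterozygotes are binomially sampled. The adult allele-count
## state is n = 0..N (frequency x_n = n / (2N), never above 1/2) and the
## one-generation update is
##     n' ~ Binomial(N, p(x)),   p(x) = 2x + 2F(x),
## so that X' = n'/(2N) <= 1/2 structurally. This differs from the
## weak-selection chain X' = Bin(2N, x + F(x)) / (2N) in the placement of
## the factors of 2; both share the one-step mean x + F(x).
## ------------------------------------------------------------------

## success probabilities p_n for all source states; p is a probability
## analytically, so excursions beyond 1e-12 raise (bug, not roundoff).
chain_p <- function(model, tol = 1e-12) {
  N <- model$N
  x <- (0:N) / (2 * N)
  p <- 2 * x + 2 * force_fn(x, model$h, model$u)
  bad <- p < -tol | p > 1 + tol
  if (any(bad))
    stop("model inconsistency: sampling probability 2x + 2F(x) = ",
         p[which(bad)[1]], " outside [0, 1] beyond tolerance", call. = FALSE)
  pmin(pmax(p, 0), 1)
}

#' One-generation transition probability of the lethal-genotype chain
#'
#' Probability that a population with `n_from` copies of the lethal allele
#' among its `N` adults (frequency `n_from / (2N)`) has `n_to` copies in the
#' next adult generation: the `Binomial(N, 2x + 2F(x))` mass at `n_to`.
#'
#' @param n_from,n_to State indices in `0..N`.
#' @param model A [lethal_model()] with finite `N`.
#' @return Transition probability.
#' @examples
#' m <- lethal_model(u = 0, h = 0, N = 1)
#' transition_probability(1, 1, m)  # 2/3
#' @export
transition_probability <- function(n_from, n_to, model) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  N <- model$N
  stopifnot(all(n_from >= 0), all(n_from <= N),
            all(n_to >= 0), all(n_to <= N))
  p <- chain_p(model)
  stats::dbinom(n_to, N, p[n_from + 1L])
}

#' Transition matrix of the lethal-genotype Wright-Fisher chain
#'
#' Builds the full `(N+1) x (N+1)` column-stochastic kernel `W`, with
#' `W[m + 1, n + 1]` the probability of moving from `n` lethal-allele
#' copies to `m` in one generation. Binomial masses come from
#' [stats::dbinom()], which evaluates in log space and is accurate for
#' large `N` with extreme `p`.
#'
#' @param model A [lethal_model()] with finite `N`.
#' @param cap Largest admissible `N` (guards against accidental huge dense
#'   allocations); default 10000.
#' @return Dense numeric matrix with columns summing to 1.
#' @examples
#' transition_matrix(lethal_model(u = 0, h = 0, N = 1))
#' @export
transition_matrix <- function(model, cap = 10000) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  N <- model$N
  if (N > cap)
    stop("N = ", N, " exceeds the dense-kernel cap (", cap, "); raise 'cap' ",
         "explicitly if you really want an (N+1)^2 dense matrix",
         call. = FALSE)
  p <- chain_p(model)
  W <- vapply(p, function(pp) stats::dbinom(0:N, N, pp), numeric(N + 1L))
  dimnames(W) <- list(to = 0:N, from = 0:N)
  W
}

#' Standard weak-selection Wright-Fisher kernel (comparison only)
#'
#' The textbook chain `X' = Bin(2N, x + F(x)) / (2N)` over states
#' `n = 0..2N`. It is provided for comparison studies only: unlike the
#' lethal-genotype chain it does not respect the structural bound
#' `X <= 1/2`.
#'
#' @inheritParams transition_matrix
#' @return Dense `(2N+1) x (2N+1)` column-stochastic matrix.
#' @export
transition_matrix_standard <- function(model, cap = 10000) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  N <- model$N
  if (2 * N > cap)
    stop("2N = ", 2 * N, " exceeds the dense-kernel cap (", cap, ")",
         call. = FALSE)
  x <- (0:(2 * N)) / (2 * N)
  p <- x + force_fn(x, model$h, model$u)
  p <- pmin(pmax(p, 0), 1)
  W <- vapply(p, function(pp) stats::dbinom(0:(2 * N), 2 * N, pp),
              numeric(2 * N + 1L))
  dimnames(W) <- list(to = 0:(2 * N), from = 0:(2 * N))
  W
}

#' Stationary distribution of the lethal-genotype chain
#'
#' Solves `W pi = pi` with `pi >= 0`, `sum(pi) = 1`. For `N + 1 <= 2001`
#' states the linear system `(W - I) pi = 0` plus the normalization row is
#' solved densely (exact to roundoff); larger chains fall back to power
#' iteration (tolerance `1e-14`, up to `1e6` sweeps). With `u = 0` the
#' chain is absorbing at state 0 and the degenerate distribution is
#' returned with a warning (uniqueness of the stationary solution requires
#' `u > 0`).
#'
#' @param model A [lethal_model()] with finite `N`.
#' @param W Optional precomputed [transition_matrix()] (avoids rebuilding).
#' @param dense_max Largest state count solved densely; default 2001.
#' @return Object of class `"stationary_dist"`: list with `pi` (length
#'   `N + 1`), `n = 0:N`, `x = n/(2N)`, `residual` (`max |W pi - pi|`) and
#'   `solver`.
#' @examples
#' sd <- stationary_distribution(lethal_model(u = 0.1, h = 0, N = 1))
#' sum(sd$pi)
#' @export
stationary_distribution <- function(model, W = NULL, dense_max = 2001) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N))
  N <- model$N
  if (model$u == 0) {
    warning("u = 0: chain is absorbing at n = 0; returning the degenerate ",
            "stationary distribution", call. = FALSE)
    pi <- c(1, numeric(N))
    return(structure(list(pi = pi, n = 0:N, x = (0:N) / (2 * N),
                          residual = 0, solver = "degenerate"),
                     class = "stationary_dist"))
  }
  if (is.null(W)) W <- transition_matrix(model)
  n_states <- N + 1L
  if (n_states <= dense_max) {
    A <- W - diag(n_states)
    A[n_states, ] <- 1
    b <- c(numeric(n_states - 1L), 1)
    pi <- solve(A, b)
    solver <- "dense"
  } else {
    pi <- rep(1 / n_states, n_states)
    for (it in seq_len(1e6)) {
      pin <- as.numeric(W %*% pi)
      pin <- pin / sum(pin)
      if (max(abs(pin - pi)) < 1e-14) { pi <- pin; break }
      pi <- pin
    }
    solver <- "power"
  }
  pi <- unname(pmax(pi, 0))
  pi <- pi / sum(pi)
  residual <- max(abs(W %*% pi - pi))
  structure(list(pi = pi, n = 0:N, x = (0:N) / (2 * N),
                 residual = residual, solver = solver),
            class = "stationary_dist")
}

#' @export
print.stationary_dist <- function(x, ...) {
  N <- length(x$pi) - 1L
  m <- sum(x$pi * x$x)
  cat(sprintf("Stationary distribution over %d states (N = %d), solver = %s\n",
              N + 1L, N, x$solver))
  cat(sprintf("  mean frequency = %.6g, residual = %.3g\n", m, x$residual))
  invisible(x)
}

#' Stationary mean frequency of the lethal-genotype chain
#'
#' The mean of the stationary distribution is the finite-population analog
#' of the deterministic equilibrium frequency. Also reports `log10` of the
#' mean and its ratio to the mutation rate, the quantities used in
#' stationary-frequency tables.
#'
#' @inheritParams stationary_distribution
#' @param dist Optional precomputed [stationary_distribution()].
#' @return List with `mean_x`, `log10_mean`, `ratio_u`.
#' @examples
#' stationary_mean(lethal_model(u = 1e-8, h = 0, N = 500))$log10_mean  # ~-6.248
#' @export
stationary_mean <- function(model, dist = NULL, W = NULL) {
  if (is.null(dist)) dist <- stationary_distribution(model, W = W)
  m <- sum(dist$pi * dist$x)
  list(mean_x = m,
       log10_mean = if (m > 0) log10(m) else -Inf,
       ratio_u = if (model$u > 0) m / model$u else 0)
}

#' Propagate a frequency distribution through the chain
#'
#' Deterministic matrix-vector evolution of a probability distribution over
#' allele-count states, generation by generation, under a (possibly
#' time-varying) dominance schedule. Kernels are built once per distinct
#' epoch.
#'
#' @param dist0 Numeric probability vector over states `0..N` (sums to 1),
#'   or a `"stationary_dist"` object.
#' @param schedule A [dominance_schedule()] or single numeric `h`.
#' @param model A [lethal_model()] with finite `N` (its `h` is ignored in
#'   favour of the schedule).
#' @param t_max Number of generations to propagate.
#' @param keep_dist Generations (subset of `0:t_max`) at which to retain the
#'   full distribution; default none.
#' @return List of class `"chain_summary"`: `summary` is a data frame with
#'   columns `t`, `mean_x`, `var_x`, `h`; `dist` a named list of retained
#'   distributions.
#' @export
propagate_distribution <- function(dist0, schedule, model, t_max,
                                   keep_dist = integer(0)) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N),
            t_max >= 0, t_max == round(t_max))
  N <- model$N
  if (inherits(dist0, "stationary_dist")) dist0 <- dist0$pi
  if (!is.numeric(dist0) || length(dist0) != N + 1L ||
      any(dist0 < -1e-12) || abs(sum(dist0) - 1) > 1e-10)
    stop("'dist0' must be a probability vector over the states 0..N ",
         "(length N + 1, non-negative, summing to 1)", call. = FALSE)
  schedule <- as_dominance_schedule(schedule)
  hs <- dominance_at(schedule, 0:max(t_max, 1) )[seq_len(max(t_max, 1))]
  x_states <- (0:N) / (2 * N)
  kernels <- new.env(parent = emptyenv())
  get_kernel <- function(h) {
    key <- format(h, digits = 17)
    if (is.null(kernels[[key]]))
      kernels[[key]] <- transition_matrix(
        lethal_model(u = model$u, h = h, N = N))
    kernels[[key]]
  }
  v <- dist0
  mean_x <- var_x <- numeric(t_max + 1L)
  mean_x[1L] <- sum(v * x_states)
  var_x[1L] <- sum(v * x_states^2) - mean_x[1L]^2
  dists <- list()
  if (0 %in% keep_dist) dists[["0"]] <- v
  if (t_max > 0) {
    for (t in seq_len(t_max)) {
      v <- as.numeric(get_kernel(hs[t]) %*% v)
      mean_x[t + 1L] <- sum(v * x_states)
      var_x[t + 1L] <- sum(v * x_states^2) - mean_x[t + 1L]^2
      if (t %in% keep_dist) dists[[as.character(t)]] <- v
    }
  }
  h_col <- dominance_at(schedule, 0:t_max)
  structure(list(summary = data.frame(t = 0:t_max, mean_x = mean_x,
                                      var_x = var_x, h = h_col),
                 dist = dists, model = model),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Chain propagation over %d generations (N = %d)\n",
              nrow(s) - 1L, x$model$N))
  cat(sprintf("  mean frequency: %.6g (t = 0) -> %.6g (t = %d)\n",
              s$mean_x[1], s$mean_x[nrow(s)], s$t[nrow(s)]))
  invisible(x)
}

#' Sample a stochastic trajectory of the lethal-genotype chain
#'
#' Draws `n_{t+1} ~ Binomial(N, 2 x_t + 2 F(x_t))` generation by
#' generation. Sampled frequencies can never exceed one half.
#'
#' @param model A [lethal_model()] with finite `N`.
#' @param x0 Initial frequency; must lie on the state grid `n / (2N)` with
#'   integer `n <= N`.
#' @param t_max Number of generations to simulate.
#' @param schedule Optional [dominance_schedule()] (default: constant
#'   `model$h`).
#' @param seed Optional integer seed; if supplied the R generator is seeded
#'   for reproducibility and the seed is recorded on the result.
#' @return Data frame with columns `t`, `n`, `x`; attribute `"seed"`.
#' @examples
#' sample_trajectory(lethal_model(u = 0.01, h = 0, N = 50), x0 = 0,
#'                   t_max = 10, seed = 1)
#' @export
sample_trajectory <- function(model, x0, t_max, schedule = NULL, seed = NULL) {
  stopifnot(inherits(model, "lethal_model"), is.finite(model$N),
            t_max >= 0, t_max == round(t_max))
  N <- model$N
  n0 <- x0 * 2 * N
  if (abs(n0 - round(n0)) > 1e-9 || round(n0) > N || n0 < 0)
    stop("'x0' must equal n/(2N) for an integer n in 0..N", call. = FALSE)
  n0 <- as.integer(round(n0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- model$h
  schedule <- as_dominance_schedule(schedule)
  hs <- dominance_at(schedule, 0:max(t_max, 1))[seq_len(max(t_max, 1))]
  ## per-epoch success probabilities, precomputed per distinct h
  p_by_h <- new.env(parent = emptyenv())
  get_p <- function(h) {
    key <- format(h, digits = 17)
    if (is.null(p_by_h[[key]]))
      p_by_h[[key]] <- chain_p(lethal_model(u = model$u, h = h, N = N))
    p_by_h[[key]]
  }
  n <- integer(t_max + 1L)
  n[1L] <- n0
  if (t_max > 0) {
    ## constant-h fast path
    if (length(unique(hs)) == 1L) {
      p <- get_p(hs[1L])
      for (t in seq_len(t_max))
        n[t + 1L] <- stats::rbinom(1L, N, p[n[t] + 1L])
    } else {
      for (t in seq_len(t_max))
        n[t + 1L] <- stats::rbinom(1L, N, get_p(hs[t])[n[t] + 1L])
    }
  }
  out <- data.frame(t = 0:t_max, n = n, x = n / (2 * N))
  attr(out, "seed") <- seed
  out
}

#' Half-time to stationarity after a change in dominance (finite population)
#'
#' The population is assumed to sit in the stationary distribution of the
#' pre-change chain; the dominance coefficient then changes and the
#' distribution is propagated under the post-change kernel. The half-time
#' is located on the mean-frequency trajectory, as the first census at
#' which the mean has covered half the distance between the two stationary
#' means. Censuses are labelled 1-based from the final pre-change
#' generation, i.e. a crossing after `k` post-change transitions is
#' reported as `T = k + 1` (the convention used for tabulated
#' finite-population half-times).
#'
#' @param model_pre,model_post [lethal_model()]s sharing `u` and finite `N`.
#' @param t_cap Safety cap on propagated generations (default `1e5`).
#' @return Object of class `"half_time"` (see [half_time_infinite()]), with
#'   `x_start`/`x_final` the stationary means.
#' @examples
#' \donttest{
#' half_time_finite(lethal_model(1e-8, 0, N = 500),
#'                  lethal_model(1e-8, -0.01, N = 500))$t_half  # 37
#' }
#' @export
half_time_finite <- function(model_pre, model_post, t_cap = 1e5) {
  stopifnot(inherits(model_pre, "lethal_model"),
            inherits(model_post, "lethal_model"),
            is.finite(model_pre$N), model_pre$N == model_post$N)
  if (model_pre$u != model_post$u)
    stop("pre- and post-change models must share the mutation rate u",
         call. = FALSE)
  if (model_pre$u == 0)
    stop("u > 0 is required (stationary distributions are degenerate at ",
         "u = 0)", call. = FALSE)
  N <- model_pre$N
  x_states <- (0:N) / (2 * N)
  W_post <- transition_matrix(model_post)
  d_pre <- stationary_distribution(model_pre)
  d_post <- stationary_distribution(model_post, W = W_post)
  x_start <- sum(d_pre$pi * x_states)
  x_final <- sum(d_post$pi * x_states)
  if (x_start == x_final)
    stop("degenerate input: stationary means coincide", call. = FALSE)
  x_mid <- (x_start + x_final) / 2
  rising <- x_final > x_start
  v <- d_pre$pi
  prev <- x_start
  for (k in seq_len(t_cap)) {
    v <- as.numeric(W_post %*% v)
    m <- sum(v * x_states)
    if ((rising && m >= x_mid) || (!rising && m <= x_mid)) {
      frac <- if (m == prev) 0 else (x_mid - prev) / (m - prev)
      return(structure(list(t_half = k + 1L,
                            t_cross = k + frac,
                            x_start = x_start, x_final = x_final,
                            x_mid = x_mid,
                            direction = if (rising) "rise" else "fall"),
                       class = "half_time"))
    }
    prev <- m
  }
  stop("midpoint not reached within ", t_cap, " generations", call. = FALSE)
}
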