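#' Transient after a temporary episode of overdominance
#'
#' Runs the two-jump experiment: the population sits at its recessive
#' (`h = 0`) equilibrium or stationary state; at `t = 0` the dominance
#' coefficient jumps to `h_star` (typically negative, i.e. the heterozygote
#' becomes advantageous); at `t = t_f` it reverts to 0. For an infinite
#' population the deterministic recursion is iterated from the exact
#' `h = 0` equilibrium; for finite `N` the exact `h = 0` stationary
#' distribution is propagated through the lethal-genotype kernel.
#'
#' @param u Mutation rate.
#' @param N Adult census size (positive integer) or `Inf`.
#' @param h_star Dominance coefficient during the episode (any `h <= 1`;
#'   negative for overdominance).
#' @param t_f Generation at which the episode ends (`0 < t_f <= t_max`).
#' @param t_max Total number of generations.
#' @return Data frame of class `"scenario_result"` with columns `t`,
#'   `mean_x`, `log10_mean_x`, `h`, and `var_x` for finite `N`; attributes
#'   `model` and `schedule`.
#' @examples
#' sc <- run_jump_scenario(u = 1e-5, N = Inf, h_star = -0.01,
#'                         t_f = 200, t_max = 400)
#' sc[sc$t %in% c(0, 200, 400), ]
#' @export
run_jump_scenario <- function(u, N = Inf, h_star, t_f, t_max) {
  stopifnot(t_f > 0, t_f <= t_max)
  schedule <- dominance_schedule(t_start = c(0L, as.integer(t_f)),
                                 h = c(h_star, 0))
  if (is.finite(N)) {
    model0 <- lethal_model(u = u, h = 0, N = N)
    d0 <- stationary_distribution(model0)
    pr <- propagate_distribution(d0, schedule, model0, t_max)
    out <- pr$summary
    out$log10_mean_x <- ifelse(out$mean_x > 0, log10(out$mean_x), -Inf)
    out <- out[, c("t", "mean_x", "log10_mean_x", "var_x", "h")]
    model <- model0
  } else {
    x0 <- eq_hat(0, u)
    tr <- trajectory_infinite(x0, schedule, u, t_max)
    out <- data.frame(t = tr$t, mean_x = tr$x,
                      log10_mean_x = ifelse(tr$x > 0, log10(tr$x), -Inf),
                      h = tr$h)
    model <- lethal_model(u = u, h = 0, N = Inf)
  }
  attr(out, "model") <- model
  attr(out, "schedule") <- schedule
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Stationary / equilibrium frequency table over a parameter grid
#'
#' One row per `(u, N, h)` combination: finite `N` rows use the stationary
#' mean of the lethal-genotype chain, infinite rows the exact deterministic
#' equilibrium. Layout follows the conventional stationary-frequency
#' table: `N x h` product, `log10` mean, and mean-to-mutation-rate ratio.
#'
#' @param u_list,h_list Numeric vectors of mutation rates and dominance
#'   coefficients.
#' @param N_list Vector of census sizes; use `Inf` for the deterministic
#'   rows.
#' @param digits Decimal places for the rounded `log10` column in formatted
#'   output (raw values are kept alongside); default 3.
#' @return Data frame with columns `u`, `N`, `h`, `Nh`, `log10_mean`,
#'   `ratio_u` and rounded `log10_mean_rounded`.
#' @examples
#' stationary_table(1e-5, Inf, c(0, 0.01))
#' @export
stationary_table <- function(u_list, N_list, h_list, digits = 3) {
  grid <- expand.grid(h = h_list, N = N_list, u = u_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("u", "N", "h")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    u <- grid$u[i]; N <- grid$N[i]; h <- grid$h[i]
    if (is.finite(N)) {
      m <- stationary_mean(lethal_model(u = u, h = h, N = N))
      mean_x <- m$mean_x
    } else {
      mean_x <- eq_hat(h, u)
    }
    data.frame(u = u, N = N, h = h,
               Nh = if (is.finite(N)) N * h else NA_real_,
               mean_x = mean_x,
               log10_mean = if (mean_x > 0) log10(mean_x) else -Inf,
               ratio_u = if (u > 0) mean_x / u else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$log10_mean_rounded <- round(out$log10_mean, digits)
  out
}

#' Half-time table over a parameter grid
#'
#' One row per `(u, N, jump)` combination, where each jump is a pair
#' `(h_pre, h_post)`. Infinite-`N` rows use the deterministic half-time
#' ([half_time_infinite()]); finite rows use the mean-trajectory half-time
#' of the chain ([half_time_finite()]).
#'
#' @param u_list Numeric vector of mutation rates.
#' @param N_list Vector of census sizes (`Inf` allowed).
#' @param jumps List of length-2 numeric vectors `c(h_pre, h_post)`.
#' @return Data frame with columns `u`, `N`, `h_pre`, `h_post`, `t_half`.
#' @examples
#' half_time_table(1e-8, Inf, list(c(0, -0.01)))
#' @export
half_time_table <- function(u_list, N_list, jumps) {
  stopifnot(is.list(jumps), all(vapply(jumps, length, 1L) == 2L))
  rows <- list()
  for (u in u_list) for (jump in jumps) for (N in N_list) {
    pre <- lethal_model(u = u, h = jump[1], N = N)
    post <- lethal_model(u = u, h = jump[2], N = N)
    ht <- if (is.finite(N)) half_time_finite(pre, post)
          else half_time_infinite(pre, post)
    rows[[length(rows) + 1L]] <-
      data.frame(u = u, N = N, h_pre = jump[1], h_post = jump[2],
                 t_half = ht$t_half)
  }
  do.call(rbind, rows)
}

#' @export
print.scenario_result <- function(x, ...) {
  model <- attr(x, "model")
  cat(sprintf("Jump scenario (%s population, u = %g), %d generations\n",
              if (is.finite(model$N)) paste0("N = ", model$N) else "infinite",
              model$u, max(x$t)))
  print(attr(x, "schedule"))
  utils::str(as.data.frame(x)[, setdiff(names(x), NULL)], give.attr = FALSE)
  invisible(x)
}

#' Plot a scenario or trajectory result
#'
#' Quick-look base-graphics plot of `log10` mean frequency against time.
#'
#' @param x A `"scenario_result"` from [run_jump_scenario()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scenario_result <- function(x, ...) {
  graphics::plot(x$t, x$log10_mean_x, type = "l",
                 xlab = "generation t",
                 ylab = expression(log[10] ~ "mean frequency"), ...)
  sch <- attr(x, "schedule")
  if (!is.null(sch) && length(sch$t_start) > 1L)
    graphics::abline(v = sch$t_start[-1L], lty = 3)
  invisible(x)
}
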