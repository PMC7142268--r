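#' Deterministic evolutionary force on a lethal allele
#'
#' Expected per-generation change of the frequency `x` of a lethal allele in
#' an effectively infinite population:
#' \deqn{F(x) = \frac{(1-h)u - [h + (2-3h)u]\,x - (1-2h)(1-u)\,x^2}
#'                   {[1 + (1-2h)u] + (1-2h)(1-u)\,x}.}
#' With `h = 0`, `u = 0` this reduces to the textbook lethal-recessive force
#' `F(x) = -x^2 / (1 + x)`.
#'
#' @param x Adult frequency (or vector of frequencies) of the lethal allele,
#'   each in `[0, 1/2]`.
#' @param model A [lethal_model()] (its `N` is ignored; the force is the
#'   infinite-population drift term).
#' @return `F(x)`, same length as `x`.
#' @examples
#' selection_force(0.1, lethal_model(u = 0, h = 0))  # -0.1^2 / 1.1
#' @export
selection_force <- function(x, model) {
  stopifnot(inherits(model, "lethal_model"))
  assert_frequency(x)
  force_fn(x, model$h, model$u)
}

## bare (h, u) version used in inner loops
force_fn <- function(x, h, u) {
  num <- (1 - h) * u - (h + (2 - 3 * h) * u) * x - (1 - 2 * h) * (1 - u) * x^2
  den <- (1 + (1 - 2 * h) * u) + (1 - 2 * h) * (1 - u) * x
  num / den
}

## One deterministic generation; x + F(x) is guaranteed in [0, 1/2]
## analytically, so violations beyond rounding indicate a bug.
step_fn <- function(x, h, u, tol = 1e-12) {
  xp <- x + force_fn(x, h, u)
  bad <- xp < -tol | xp > 0.5 + tol
  if (any(bad))
    stop("internal consistency error: x + F(x) = ", xp[which(bad)[1]],
         " escapes [0, 1/2] beyond rounding tolerance", call. = FALSE)
  pmin(pmax(xp, 0), 0.5)
}

#' One generation of the deterministic (infinite-population) recursion
#'
#' Applies `x' = x + F(x)` once. The result always lies in `[0, 1/2]`;
#' rounding excursions up to `1e-12` are clamped, anything larger raises an
#' internal-consistency error.
#'
#' @inheritParams selection_force
#' @return The next-generation frequency, same length as `x`.
#' @examples
#' step_infinite(0.2, lethal_model(u = 0, h = 0))  # 0.2 / 1.2
#' @export
step_infinite <- function(x, model) {
  stopifnot(inherits(model, "lethal_model"))
  assert_frequency(x)
  step_fn(x, model$h, model$u)
}

#' Deterministic frequency trajectory under a dominance schedule
#'
#' Iterates the infinite-population recursion for `t_max` generations. The
#' dominance coefficient may change over time via a [dominance_schedule()]:
#' the epoch containing generation `t` supplies the `h` used for the
#' transition from `t` to `t + 1`.
#'
#' @param x0 Initial frequency in `[0, 1/2]`, or `"equilibrium"` to start at
#'   the exact equilibrium of the first epoch.
#' @param schedule A [dominance_schedule()], or a single numeric `h`.
#' @param u Mutation rate in `[0, 1]`.
#' @param t_max Number of generations to iterate (`>= 0`).
#' @return A data frame with columns `t` (0..`t_max`), `x` and `h` (the
#'   dominance coefficient in force during the transition out of `t`).
#' @examples
#' tr <- trajectory_infinite(0.5, schedule = 0, u = 0, t_max = 5)
#' all.equal(tr$x, 0.5 / (1 + 0.5 * tr$t))
#' @export
trajectory_infinite <- function(x0, schedule, u, t_max) {
  stopifnot(t_max >= 0, t_max == round(t_max))
  schedule <- as_dominance_schedule(schedule)
  if (identical(x0, "equilibrium"))
    x0 <- eq_hat(dominance_at(schedule, 0), u)
  assert_frequency(x0, "x0")
  stopifnot(length(x0) == 1L)
  hs <- dominance_at(schedule, 0:t_max)
  x <- numeric(t_max + 1L)
  x[1L] <- x0
  if (t_max > 0)
    for (t in seq_len(t_max)) x[t + 1L] <- step_fn(x[t], hs[t], u)
  data.frame(t = 0:t_max, x = x, h = hs)
}

## Exact equilibrium frequency, numerically stable over the whole h range.
## The equilibrium is the admissible root of the quadratic numerator of F:
##   (1-2h)(1-u) x^2 + [h + (2-3h)u] x - (1-h)u = 0,
## whose discriminant simplifies to D = h^2 (1+u)^2 + 4 (1-2h) u.
## For h >= 0 the direct form 2(1-h)u / (beta + sqrt(D)) with
## beta = h + (2-3h)u has no cancellation; for h < 0 the conjugate form
## (sqrt(D) - beta) / (2 (1-2h)(1-u)) (using D - beta^2 = 4u(1-h)(1-2h)(1-u))
## is used instead, since beta < 0 there and the direct denominator is a
## difference of nearly equal quantities (losing ~8 digits at u = 1e-8,
## h = -0.01).
eq_hat <- function(h, u) {
  if (u == 0 && h >= 0) return(0)
  D <- h^2 * (1 + u)^2 + 4 * (1 - 2 * h) * u
  beta <- h + (2 - 3 * h) * u
  if (h >= 0) {
    2 * (1 - h) * u / (beta + sqrt(D))
  } else {
    (sqrt(D) - beta) / (2 * (1 - 2 * h) * (1 - u))
  }
}

#' Exact mutation-selection(-overdominance) equilibrium frequency
#'
#' Closed-form equilibrium of the deterministic recursion, valid for the
#' full parameter range `h <= 1`, `0 <= u <= 1`. Evaluation is numerically
#' stable for overdominant `h < 0`, where the naive formula suffers severe
#' cancellation (see the source for the conjugate form used).
#'
#' @param model A [lethal_model()].
#' @return An object of class `"lethal_equilibrium"`: list with `x_hat`,
#'   `method = "exact"`, and the fixed-point residual `F(x_hat)`.
#' @examples
#' equilibrium_exact(lethal_model(u = 1e-8, h = 0))$x_hat      # ~1.0e-4
#' equilibrium_exact(lethal_model(u = 1e-8, h = -0.01))$x_hat  # ~9.8e-3
#' @export
equilibrium_exact <- function(model) {
  stopifnot(inherits(model, "lethal_model"))
  x_hat <- eq_hat(model$h, model$u)
  res <- structure(list(x_hat = x_hat, method = "exact",
                        residual = force_fn(x_hat, model$h, model$u)),
                   class = "lethal_equilibrium")
  assert_frequency(x_hat, "x_hat")
  res
}

#' Asymptotic equilibrium approximations
#'
#' Leading-order closed forms for the equilibrium frequency in the standard
#' parameter regimes:
#' \describe{
#'   \item{`"small-positive-h"`}{`(1-h) u / h`, valid for `u << h^2`, `h << 1`
#'     (mutation-selection balance with a partially recessive lethal).}
#'   \item{`"recessive"`}{`sqrt(u) / (1 + sqrt(u))`, the exact `h = 0` result
#'     (approximately `sqrt(u)` for small `u`).}
#'   \item{`"overdominant"`}{`|h| / (1 + 2|h|)`, valid for `u << |h| << 1`,
#'     `h < 0`; independent of `u` at leading order.}
#'   \item{`"zero-mutation-limit"`}{`0` for `h >= 0`, `|h| / (1 + 2|h|)` for
#'     `h < 0`.}
#' }
#' A warning (not an error) is issued when the regime's validity condition
#' is clearly violated.
#'
#' @param model A [lethal_model()].
#' @param regime One of `"small-positive-h"`, `"recessive"`,
#'   `"overdominant"`, `"zero-mutation-limit"`.
#' @return A `"lethal_equilibrium"` object with the chosen `method`.
#' @examples
#' equilibrium_approx(lethal_model(u = 1e-5, h = -0.01), "overdominant")$x_hat
#' @export
equilibrium_approx <- function(model,
                               regime = c("small-positive-h", "recessive",
                                          "overdominant",
                                          "zero-mutation-limit")) {
  stopifnot(inherits(model, "lethal_model"))
  regime <- match.arg(regime)
  h <- model$h; u <- model$u
  x_hat <- switch(regime,
    "small-positive-h" = {
      if (h <= 0 || u > h^2 / 100 || h > 0.1)
        warning("regime 'small-positive-h' expects u << h^2 and h << 1",
                call. = FALSE)
      (1 - h) * u / h
    },
    "recessive" = {
      if (h != 0)
        warning("regime 'recessive' is the h = 0 closed form", call. = FALSE)
      sqrt(u) / (1 + sqrt(u))
    },
    "overdominant" = {
      if (h >= 0 || u > abs(h) / 100 || abs(h) > 0.1)
        warning("regime 'overdominant' expects h < 0 and u << |h| << 1",
                call. = FALSE)
      abs(h) / (1 + 2 * abs(h))
    },
    "zero-mutation-limit" = if (h >= 0) 0 else abs(h) / (1 + 2 * abs(h)))
  structure(list(x_hat = x_hat, method = regime, residual = NA_real_),
            class = "lethal_equilibrium")
}

#' @export
print.lethal_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium frequency x_hat = %.10g  [%s]\n", x$x_hat, x$method))
  if (!is.na(x$residual))
    cat(sprintf("  fixed-point residual F(x_hat) = %.3g\n", x$residual))
  invisible(x)
}

## Shared crossing machinery: given a numeric trajectory m[1] = value at
## generation 0, m[k+1] = value at generation k, its target, and the
## midpoint, locate the first crossing and its linear interpolation.
crossing_time <- function(traj, mid, rising) {
  hit <- if (rising) traj >= mid else traj <= mid
  k <- which(hit)[1L]
  if (is.na(k)) return(NULL)
  k <- k - 1L                      # generation index (traj[1] is t = 0)
  if (k == 0L) return(list(k = 0L, tau = 0))
  x0 <- traj[k]; x1 <- traj[k + 1L]
  frac <- if (x1 == x0) 0 else (mid - x0) / (x1 - x0)
  list(k = k, tau = (k - 1L) + frac)
}

#' Half-time to equilibrium after a change in dominance (infinite population)
#'
#' The dominance coefficient changes discontinuously from its value in
#' `model_pre` to its value in `model_post`. Starting from the exact
#' pre-change equilibrium, the deterministic recursion is iterated under the
#' post-change parameters, and the time at which the frequency has covered
#' half the distance to the new equilibrium is located. Because the
#' underlying dynamics derive from a smooth analytical solution, the
#' crossing time is computed by linear interpolation between the bracketing
#' generations and reported rounded to the nearest generation (`t_half`),
#' alongside the real-valued crossing (`t_cross`).
#'
#' @param model_pre,model_post [lethal_model()]s sharing the same `u`.
#' @param t_cap Safety cap on iterations (default `1e6`).
#' @return Object of class `"half_time"`: list with integer `t_half`,
#'   real-valued `t_cross`, `x_start`, `x_final`, `x_mid`, and `direction`.
#' @examples
#' half_time_infinite(lethal_model(1e-8, 0), lethal_model(1e-8, -0.01))$t_half
#' @export
half_time_infinite <- function(model_pre, model_post, t_cap = 1e6) {
  stopifnot(inherits(model_pre, "lethal_model"),
            inherits(model_post, "lethal_model"))
  if (model_pre$u != model_post$u)
    stop("pre- and post-change models must share the mutation rate u",
         call. = FALSE)
  u <- model_post$u; h <- model_post$h
  x_start <- eq_hat(model_pre$h, u)
  x_final <- eq_hat(h, u)
  if (x_start == x_final)
    stop("degenerate input: pre- and post-change equilibria coincide, ",
         "no half-time is defined", call. = FALSE)
  x_mid <- (x_start + x_final) / 2
  rising <- x_final > x_start
  x <- x_start
  ## iterate in blocks, retaining the trajectory only near the crossing
  prev <- x_start
  for (t in seq_len(t_cap)) {
    x <- step_fn(x, h, u)
    if ((rising && x >= x_mid) || (!rising && x <= x_mid)) {
      frac <- if (x == prev) 0 else (x_mid - prev) / (x - prev)
      t_cross <- (t - 1) + frac
      return(structure(list(t_half = as.integer(round(t_cross)),
                            t_cross = t_cross,
                            x_start = x_start, x_final = x_final,
                            x_mid = x_mid,
                            direction = if (rising) "rise" else "fall"),
                       class = "half_time"))
    }
    prev <- x
  }
  stop("midpoint not reached within ", t_cap, " generations", call. = FALSE)
}

#' @export
print.half_time <- function(x, ...) {
  cat(sprintf("Half-time to equilibrium (%s): T_1/2 = %d generations\n",
              x$direction, x$t_half))
  if (!is.null(x$t_cross) && is.finite(x$t_cross))
    cat(sprintf("  interpolated crossing at t = %.2f\n", x$t_cross))
  cat(sprintf("  x_start = %.6g, x_final = %.6g, midpoint = %.6g\n",
              x$x_start, x$x_final, x$x_mid))
  invisible(x)
}

#' Closed-form half-time for the onset of overdominance
#'
#' Approximate half-time for the rise of the frequency after the dominance
#' coefficient jumps from 0 to a negative value `h_star`, starting at the
#' recessive equilibrium (about `sqrt(u)`) and converging to about
#' `|h*|/(1 + 2|h*|)`:
#' \deqn{T_{1/2} \approx
#'   \frac{\ln\!\big(\tfrac{|h^*|}{1+2|h^*|}\,/\sqrt{u}\big)}{\ln(1+|h^*|)}.}
#' Valid for `u << |h*| << 1`.
#'
#' @param h_star Post-change dominance coefficient, `h_star < 0`.
#' @param u Mutation rate, `0 < u < |h_star|`.
#' @return Real-valued approximate half-time in generations.
#' @examples
#' half_time_approx_rise(-0.01, 1e-8)  # ~461
#' @export
half_time_approx_rise <- function(h_star, u) {
  if (h_star >= 0) stop("'h_star' must be negative (overdominance)",
                        call. = FALSE)
  if (u <= 0 || u >= abs(h_star))
    stop("requires 0 < u < |h_star|", call. = FALSE)
  a <- abs(h_star)
  log((a / (1 + 2 * a)) / sqrt(u)) / log(1 + a)
}

#' Closed-form half-time for the loss of overdominance
#'
#' Approximate half-time for the fall of the frequency after the dominance
#' coefficient reverts from a negative `h_star` back to 0:
#' \deqn{T_{1/2} \approx
#'   \frac{\ln\!\big(1 + 2\sqrt{u}/|h^*| - 2u/h^{*2}\big)}{2\sqrt{u}}.}
#' Valid for `u << h*^2`.
#'
#' @inheritParams half_time_approx_rise
#' @return Real-valued approximate half-time in generations.
#' @examples
#' half_time_approx_fall(-0.01, 1e-8)  # ~98
#' @export
half_time_approx_fall <- function(h_star, u) {
  if (h_star >= 0) stop("'h_star' must be negative (overdominance)",
                        call. = FALSE)
  if (u <= 0 || u >= h_star^2)
    stop("requires 0 < u < h_star^2", call. = FALSE)
  su <- sqrt(u); a <- abs(h_star)
  log(1 + 2 * su / a - 2 * u / h_star^2) / (2 * su)
}
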