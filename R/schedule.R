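#' Piecewise-constant dominance schedule
#'
#' Describes a dominance coefficient that changes over time: each epoch
#' starts at `t_start` and applies until the next epoch begins. By
#' convention `h(t)` governs the transition from generation `t` to `t + 1`,
#' so a schedule `dominance_schedule(t_start = c(0, 2000), h = c(-0.01, 0))`
#' means the first 2000 transitions are computed with `h = -0.01` and all
#' later ones with `h = 0`.
#'
#' @param t_start Integer vector of epoch start generations, strictly
#'   increasing, first element 0.
#' @param h Numeric vector of dominance coefficients (each `<= 1`), same
#'   length as `t_start`.
#' @return Object of class `"dominance_schedule"`.
#' @examples
#' sch <- dominance_schedule(t_start = c(0, 2000), h = c(-0.01, 0))
#' dominance_at(sch, c(0, 1999, 2000))
#' @export
dominance_schedule <- function(t_start, h) {
  stopifnot(is.numeric(t_start), is.numeric(h), length(t_start) == length(h),
            length(h) >= 1L)
  if (any(t_start != round(t_start)))
    stop("'t_start' must be integer generations", call. = FALSE)
  if (t_start[1L] != 0)
    stop("the first epoch must start at generation 0", call. = FALSE)
  if (length(t_start) > 1L && any(diff(t_start) <= 0))
    stop("'t_start' must be strictly increasing", call. = FALSE)
  if (any(h > 1))
    stop("every 'h' must satisfy h <= 1", call. = FALSE)
  structure(list(t_start = as.integer(t_start), h = as.numeric(h)),
            class = "dominance_schedule")
}

## accepts a bare numeric h as a constant schedule
as_dominance_schedule <- function(x) {
  if (inherits(x, "dominance_schedule")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dominance_schedule(0L, x))
  stop("expected a dominance_schedule or a single numeric h", call. = FALSE)
}

#' Dominance coefficient in force at given generations
#'
#' @param schedule A [dominance_schedule()].
#' @param t Integer vector of generations (`>= 0`).
#' @return Numeric vector: the `h` governing the transition out of each `t`.
#' @export
dominance_at <- function(schedule, t) {
  schedule <- as_dominance_schedule(schedule)
  stopifnot(all(t >= 0))
  idx <- findInterval(t, schedule$t_start)
  if (any(idx == 0L))
    stop("schedule does not cover the requested generations", call. = FALSE)
  schedule$h[idx]
}

#' @export
print.dominance_schedule <- function(x, ...) {
  cat("Dominance schedule:\n")
  for (i in seq_along(x$t_start)) {
    end <- if (i < length(x$t_start))
      sprintf("t < %d", x$t_start[i + 1L]) else "onwards"
    cat(sprintf("  from t = %d %s: h = %g\n", x$t_start[i], end, x$h[i]))
  }
  invisible(x)
}
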