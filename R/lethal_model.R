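#' Population model for an allele that is lethal when homozygous
#'
#' Constructs the parameter object used throughout the package. The model
#' describes a single biallelic locus in a diploid, randomly mating,
#' discrete-generation population in which the `aa` homozygote has zero
#' viability (selection coefficient fixed at `s = 1`). The heterozygote has
#' relative fitness `1 - h`; one-way mutation `A -> a` occurs with
#' probability `u` per allele copy per generation.
#'
#' Because relative fitnesses cannot be negative, the dominance coefficient
#' is restricted to `h <= 1`: `h = 0` is a fully recessive lethal, `0 < h < 1`
#' a partially recessive one, `h = 1` fully dominant, and `h < 0` overdominant
#' (heterozygote advantage).
#'
#' @param u Per-allele, per-generation mutation probability, in `[0, 1]`.
#' @param h Dominance coefficient, `h <= 1` (any negative value is allowed).
#' @param N Adult census size: a positive integer, or `Inf` for the
#'   deterministic (effectively infinite population) model. Default `Inf`.
#' @param s Selection coefficient against the `aa` homozygote. Only `s = 1`
#'   (lethality) is admitted; the argument exists to make the assumption
#'   explicit.
#'
#' @return An object of class `"lethal_model"`: a list with elements `u`,
#'   `h`, `N` and `s`.
#'
#' @examples
#' m <- lethal_model(u = 1e-8, h = 0, N = Inf)
#' relative_fitnesses(m)
#' equilibrium_exact(m)$x_hat
#'
#' @seealso [equilibrium_exact()], [transition_matrix()], [summary.lethal_model()]
#' @export
lethal_model <- function(u, h, N = Inf, s = 1) {
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(N), length(N) == 1L, !is.na(N),
            is.numeric(s), length(s) == 1L)
  if (u < 0 || u > 1)
    stop("'u' must be a probability in [0, 1], got ", u, call. = FALSE)
  if (h > 1)
    stop("'h' must satisfy h <= 1 (heterozygote fitness 1 - h >= 0), got ",
         h, call. = FALSE)
  if (s != 1)
    stop("only s = 1 (a lethal homozygote) is supported, got s = ", s,
         call. = FALSE)
  if (u == 1 && h == 1)
    stop("u = 1 with h = 1 leaves no viable genotype (all offspring carry ",
         "the lethal allele and heterozygotes have zero fitness)",
         call. = FALSE)
  if (is.finite(N)) {
    if (N != round(N) || N < 1)
      stop("'N' must be a positive integer or Inf, got ", N, call. = FALSE)
    N <- as.integer(N)
  }
  structure(list(u = u, h = h, N = N, s = 1), class = "lethal_model")
}

#' @export
print.lethal_model <- function(x, ...) {
  cat("Lethal-allele population model (s = 1)\n")
  cat(sprintf("  mutation rate u        : %g\n", x$u))
  cat(sprintf("  dominance coefficient h: %g (%s)\n", x$h, dominance_class(x$h)))
  cat(sprintf("  adult census size N    : %s\n",
              if (is.finite(x$N)) format(x$N) else "infinite"))
  w <- relative_fitnesses(x)
  cat(sprintf("  fitnesses (aa, aA, AA) : (%g, %g, %g)\n", w[1], w[2], w[3]))
  invisible(x)
}

#' @export
coef.lethal_model <- function(object, ...) {
  c(u = object$u, h = object$h, N = object$N, s = object$s)
}

dominance_class <- function(h) {
  if (h < 0) "overdominant"
  else if (h == 0) "fully recessive"
  else if (h < 1) "partially recessive"
  else "fully dominant"
}

#' Relative genotype fitnesses of the lethal-allele model
#'
#' Returns the relative viabilities `(w_aa, w_aA, w_AA) = (0, 1 - h, 1)`
#' implied by lethality of the `aa` homozygote.
#'
#' @param model A [lethal_model()].
#' @return Named numeric vector `c(w_aa = 0, w_aA = 1 - h, w_AA = 1)`.
#' @examples
#' relative_fitnesses(lethal_model(u = 0, h = -0.01))
#' @export
relative_fitnesses <- function(model) {
  stopifnot(inherits(model, "lethal_model"))
  c(w_aa = 0, w_aA = 1 - model$h, w_AA = 1)
}

## Adult frequency of a lethal allele cannot exceed 1/2: the a allele occurs
## only in heterozygote adults, so x = n_aA / (2 n_aA + 2 n_AA) <= 1/2.
assert_frequency <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'", what, "' must be finite numeric", call. = FALSE)
  if (any(x < 0) || any(x > 0.5))
    stop("'", what, "' outside [0, 1/2]: adult frequency of a lethal allele ",
         "is bounded by one half", call. = FALSE)
  invisible(x)
}

#' Summarize a lethal-allele model
#'
#' For an infinite population the summary reports the exact equilibrium
#' frequency; for a finite population it reports the stationary mean of the
#' modified Wright-Fisher chain, together with `log10` values and the ratio
#' to the mutation rate (the layout used for stationary-frequency tables).
#'
#' @param object A [lethal_model()].
#' @param ... Unused.
#' @return An object of class `"summary.lethal_model"`.
#' @export
summary.lethal_model <- function(object, ...) {
  if (is.finite(object$N)) {
    m <- stationary_mean(object)
    out <- list(model = object, kind = "finite",
                mean_x = m$mean_x, log10_mean = m$log10_mean,
                ratio_u = m$ratio_u)
  } else {
    eq <- equilibrium_exact(object)
    out <- list(model = object, kind = "infinite",
                mean_x = eq$x_hat,
                log10_mean = if (eq$x_hat > 0) log10(eq$x_hat) else -Inf,
                ratio_u = if (object$u > 0) eq$x_hat / object$u else NA_real_)
  }
  class(out) <- "summary.lethal_model"
  out
}

#' @export
print.summary.lethal_model <- function(x, ...) {
  print(x$model)
  lab <- if (x$kind == "finite") "stationary mean E[X]" else "equilibrium X-hat"
  cat(sprintf("  %s: %.6g  (log10 = %.3f", lab, x$mean_x, x$log10_mean))
  if (!is.na(x$ratio_u)) cat(sprintf(", ratio to u = %.4g", x$ratio_u))
  cat(")\n")
  invisible(x)
}
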