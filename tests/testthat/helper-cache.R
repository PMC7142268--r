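## Shared lazily-computed objects: the larger chains (N up to 2000) are
## expensive to build and are reused by several test files.

.lwf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lwf_cache[[key]])) .lwf_cache[[key]] <- force(expr)
  .lwf_cache[[key]]
}

cached_stationary_mean <- function(u, h, N) {
  cached(paste("sm", u, h, N),
         stationary_mean(lethal_model(u = u, h = h, N = N)))
}

cached_half_time_finite <- function(u, h_pre, h_post, N) {
  cached(paste("ht", u, h_pre, h_post, N),
         half_time_finite(lethal_model(u = u, h = h_pre, N = N),
                          lethal_model(u = u, h = h_post, N = N)))
}

## brute-force stationary vector of a column-stochastic matrix via eigen
brute_stationary <- function(W) {
  e <- eigen(W)
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
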