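# Shared fixture builders.  Everything is generated in code at test
# time; sizes are kept small so the whole suite stays fast.

const_image <- function(value = 0.5, n = 8L) {
  gray_image(matrix(value, n, n))
}

random_image <- function(n = 12L, seed = 1L) {
  set.seed(seed)
  gray_image(matrix(runif(n * n), n, n))
}

# vertical step edge: left half `lo`, right half `hi`
step_image <- function(n = 16L, lo = 0.2, hi = 0.8) {
  m <- matrix(lo, n, n)
  m[, (n %/% 2 + 1L):n] <- hi
  gray_image(m)
}

small_phantom <- function(seed = 1L, n = 64L) {
  make_phantom(phantom_spec(n, n, c(0.2, 0.5, 0.8), seed = seed))
}

# a fast filter configuration for unit tests
fast_config <- function(...) {
  patch_config(patch_radius = 1L, search_radius = 4L, ...)
}
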