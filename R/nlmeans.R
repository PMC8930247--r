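#' NL-Means filter hyperparameters
#'
#' Collects every tunable of the non-local means filter.
#'
#' @param patch_radius Half-width of the square comparison patch, in
#'   pixels (`>= 1`; patch is `(2r+1) x (2r+1)`).
#' @param search_radius Half-width of the candidate search window, or
#'   `Inf` for whole-image search (the integral form of the filter
#'   ranges over the entire image domain; the windowed form is the
#'   practical default).
#' @param gaussian_sigma Standard deviation, in pixels, of the Gaussian
#'   kernel weighting pixel offsets inside the patch distance.  `Inf`
#'   gives a uniform kernel.  Default `patch_radius / 2`.
#' @param h Filter coefficient (bandwidth) in intensity units.  Larger
#'   `h` smooths more.  `NULL` (default) means "set from the image":
#'   `h = lambda * estimate_noise_std(image)` at filter time, tying the
#'   bandwidth to the image's own noise level.
#' @param lambda Proportionality constant applied to the estimated
#'   noise std when `h` is `NULL`.  Default 3: the patch distance of
#'   two same-class patches has a noise floor of about `2 * sigma^2`
#'   (each pixel difference contributes two independent noise terms),
#'   so the squared bandwidth must sit a few multiples above it for
#'   same-class candidates to keep substantial weight while dissimilar
#'   ones are still suppressed.
#' @param a Gaussian standard deviation appearing in the exponent
#'   denominator `a^2 h^2`; default 1 so the denominator reduces to
#'   `h^2`.
#' @param use_gradient Logical; select the gradient-augmented patch
#'   distance (see [nlmeans_gradient_denoise]).
#' @return A `patch_config` list.
#' @export
patch_config <- function(patch_radius = 2L, search_radius = 10L,
                         gaussian_sigma = patch_radius / 2,
                         h = NULL, lambda = 3, a = 1,
                         use_gradient = FALSE) {
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 1L) stop("`patch_radius` must be >= 1", call. = FALSE)
  if (!is.infinite(search_radius)) {
    search_radius <- as.integer(search_radius)
    if (search_radius < patch_radius) {
      stop("`search_radius` must be >= `patch_radius` (or Inf)",
           call. = FALSE)
    }
  }
  if (gaussian_sigma <= 0) stop("`gaussian_sigma` must be > 0", call. = FALSE)
  if (!is.null(h) && h <= 0) stop("`h` must be > 0", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  structure(list(patch_radius = patch_radius,
                 search_radius = search_radius,
                 gaussian_sigma = gaussian_sigma,
                 h = h, lambda = lambda, a = a,
                 use_gradient = isTRUE(use_gradient)),
            class = "patch_config")
}

# Gaussian patch kernel, truncated at the patch radius, renormalized to
# sum 1.  gaussian_sigma = Inf gives the uniform kernel 1/(2r+1)^2.
patch_kernel <- function(patch_radius, gaussian_sigma) {
  off <- -patch_radius:patch_radius
  if (is.infinite(gaussian_sigma)) {
    k <- matrix(1, length(off), length(off))
  } else {
    d2 <- outer(off^2, off^2, "+")
    k <- exp(-d2 / (2 * gaussian_sigma^2))
  }
  k / sum(k)
}

# Resolve the filter coefficient h for an image: explicit h wins,
# otherwise lambda * estimated noise std (floored well above 0 so a
# noiseless image does not produce a degenerate 0/0 exponent).
resolve_h <- function(image, config) {
  h <- config$h
  if (is.null(h)) h <- config$lambda * estimate_noise_std(image)
  max(h, 1e-8)
}

#' Gaussian-weighted squared distance between two patches
#'
#' The exponent numerator of the NL-Means weight: the sum over patch
#' offsets `l` of `G(l) * (w(i + l) - w(j + l))^2`, with `G` the
#' Gaussian patch kernel normalized to sum 1 and symmetric (mirror)
#' padding at the image border.  With `config$use_gradient = TRUE` the
#' per-offset difference is multiplied by the corresponding difference
#' of gradient magnitudes before squaring.
#'
#' @param image A [gray_image].
#' @param i,j Pixel coordinates as `(row, col)` pairs (1-based).
#' @param config A [patch_config].
#' @param grad Optional precomputed [gradient_magnitude] field.
#' @return Nonnegative scalar; 0 when `i == j`.
#' @export
patch_distance <- function(image, i, j, config = patch_config(),
                           grad = NULL) {
  image <- as_gray_image(image)
  stopifnot(inherits(config, "patch_config"),
            length(i) == 2L, length(j) == 2L)
  pr <- config$patch_radius
  kern <- patch_kernel(pr, config$gaussian_sigma)
  if (config$use_gradient && is.null(grad)) {
    grad <- gradient_magnitude(image)
  }
  off <- -pr:pr
  ri <- reflect_index(i[1] + off, nrow(image))
  ci <- reflect_index(i[2] + off, ncol(image))
  rj <- reflect_index(j[1] + off, nrow(image))
  cj <- reflect_index(j[2] + off, ncol(image))
  diff <- unclass(image)[ri, ci, drop = FALSE] -
    unclass(image)[rj, cj, drop = FALSE]
  if (config$use_gradient) {
    diff <- diff * (grad[ri, ci, drop = FALSE] - grad[rj, cj, drop = FALSE])
  }
  sum(kern * diff^2)
}

#' Per-pixel gradient magnitude
#'
#' Central differences over the mirror-padded image in both axes
#' (consistent with the filter's symmetric boundary convention), then
#' the Euclidean magnitude `sqrt(gx^2 + gy^2)`.  Exact for linear ramps
#' in the interior; at the border the mirror reflection halves the
#' one-sided difference.
#'
#' @param image A [gray_image], at least 2x2.
#' @return A numeric matrix of the same dimensions, nonnegative.
#' @export
gradient_magnitude <- function(image) {
  image <- as_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 2L || w < 2L) stop("image must be at least 2x2", call. = FALSE)
  m <- unclass(image)
  up <- m[reflect_index(0:(h - 1L), h), , drop = FALSE]
  down <- m[reflect_index(2:(h + 1L), h), , drop = FALSE]
  left <- m[, reflect_index(0:(w - 1L), w), drop = FALSE]
  right <- m[, reflect_index(2:(w + 1L), w), drop = FALSE]
  sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
}

# Shared driver for the three filter variants.  `labels` is an integer
# matrix restricting candidates to the same class; all-equal labels
# give the unrestricted filter on an identical floating-point path.
nlm_filter <- function(image, config, labels = NULL) {
  image <- as_gray_image(image)
  stopifnot(inherits(config, "patch_config"))
  m <- unclass(image)
  if (is.null(labels)) {
    labels <- matrix(0L, nrow(m), ncol(m))
  }
  storage.mode(labels) <- "integer"
  stopifnot(identical(dim(labels), dim(m)))
  h <- resolve_h(image, config)
  kern <- patch_kernel(config$patch_radius, config$gaussian_sigma)
  grad <- if (config$use_gradient) gradient_magnitude(image) else
    matrix(0, nrow(m), ncol(m))
  sr <- if (is.infinite(config$search_radius)) -1L else
    as.integer(config$search_radius)
  out <- nlm_core(m, grad, labels, kern, config$patch_radius, sr,
                  config$a^2 * h^2, config$use_gradient)
  gray_image(out)
}

#' Classic non-local means denoising
#'
#' Each output pixel is the weighted average of the candidate pixels in
#' its search window, the weight of candidate `j` for target `i` being
#' `exp(-d(i, j) / (a^2 h^2)) / K(i)` with `d` the Gaussian-weighted
#' squared patch distance ([patch_distance]) and `K(i)` the normalizer
#' making the weights sum to one.  The output is therefore a convex
#' combination of candidate intensities: it stays within their range,
#' and a constant image is an exact fixed point.
#'
#' @param image A [gray_image].
#' @param config A [patch_config] with `use_gradient = FALSE`.
#' @return The denoised [gray_image].
#' @examples
#' ph <- make_phantom(phantom_spec(48, 48))
#' noisy <- add_speckle(ph, speckle_params(sigma = 0.2, seed = 1))
#' den <- nlmeans_denoise(noisy, patch_config(search_radius = 5))
#' c(noisy = psnr(ph, noisy), denoised = psnr(ph, den))
#' @export
nlmeans_denoise <- function(image, config = patch_config()) {
  if (isTRUE(config$use_gradient)) {
    stop("config has use_gradient = TRUE; call nlmeans_gradient_denoise()",
         call. = FALSE)
  }
  nlm_filter(image, config)
}

#' Gradient-augmented non-local means denoising
#'
#' As [nlmeans_denoise], but the per-offset patch difference in the
#' exponent is the pointwise product of the intensity difference and
#' the difference of gradient magnitudes:
#' `d(i, j) = sum_l G(l) * [(w(i+l) - w(j+l)) * (D(i+l) - D(j+l))]^2`
#' where `D` is the [gradient_magnitude] field.  Across structural
#' edges both factors are large, so cross-edge candidates are strongly
#' down-weighted and edges are preserved; in flat regions the gradient
#' differences are small, the exponent shrinks and smoothing is
#' stronger.  When either factor vanishes at every offset the distance
#' is 0 and the candidate gets the maximal weight (the degenerate case
#' is intentional: a constant image remains an exact fixed point).
#'
#' @param image A [gray_image].
#' @param config A [patch_config]; `use_gradient` is forced on.
#' @return The denoised [gray_image].
#' @export
nlmeans_gradient_denoise <- function(image, config = patch_config()) {
  config$use_gradient <- TRUE
  nlm_filter(image, config)
}

#' NL-Means weight field for one target pixel
#'
#' Exposes the candidate set, the normalized weights `T(i, j)` and the
#' normalizer `K(i)` used by the filter at a single pixel — the
#' quantities the averaging is built from, mainly for inspection and
#' testing.
#'
#' @param image A [gray_image].
#' @param i Target pixel `(row, col)`.
#' @param config A [patch_config].
#' @param labels Optional integer label matrix; candidates are
#'   restricted to `labels[j] == labels[i]` as in [knl_denoise].
#' @return A list with `candidates` (n x 2 matrix of pixel coords),
#'   `weights` (normalized, summing to 1), and `normalizer` `K(i)`.
#' @export
nlmeans_weights <- function(image, i, config = patch_config(),
                            labels = NULL) {
  image <- as_gray_image(image)
  h <- resolve_h(image, config)
  grad <- if (config$use_gradient) gradient_magnitude(image) else NULL
  nr <- nrow(image); nc <- ncol(image)
  if (is.infinite(config$search_radius)) {
    rows <- 1:nr; cols <- 1:nc
  } else {
    sr <- config$search_radius
    rows <- max(1, i[1] - sr):min(nr, i[1] + sr)
    cols <- max(1, i[2] - sr):min(nc, i[2] + sr)
  }
  cand <- as.matrix(expand.grid(row = rows, col = cols))
  if (!is.null(labels)) {
    keep <- labels[cand] == labels[i[1], i[2]]
    cand <- cand[keep, , drop = FALSE]
  }
  raw <- apply(cand, 1L, function(j) {
    exp(-patch_distance(image, i, j, config, grad = grad) /
          (config$a^2 * h^2))
  })
  list(candidates = cand, weights = raw / sum(raw), normalizer = sum(raw))
}

#' Literal brute-force NL-Means oracle
#'
#' Direct, unaccelerated evaluation of the filter over all pixel pairs
#' of the image (whole-image search), in plain R, for both the classic
#' and the gradient-augmented distance.  This is the reference the fast
#' implementation is checked against; it is quadratic in the pixel
#' count and refuses images larger than 32x32.
#'
#' @param image A [gray_image] no larger than 32x32.
#' @param config A [patch_config]; `search_radius` is ignored (whole
#'   image).
#' @return The denoised [gray_image].
#' @export
naive_oracle_denoise <- function(image, config = patch_config()) {
  image <- as_gray_image(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr > 32L || nc > 32L) {
    stop("oracle restricted to images <= 32x32", call. = FALSE)
  }
  h <- resolve_h(image, config)
  ah2 <- config$a^2 * h^2
  grad <- if (config$use_gradient) gradient_magnitude(image) else NULL
  out <- matrix(NA_real_, nr, nc)
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      wsum <- 0; vsum <- 0
      for (c1 in seq_len(nc)) {
        for (r1 in seq_len(nr)) {
          d <- patch_distance(image, c(r0, c0), c(r1, c1), config,
                              grad = grad)
          wgt <- exp(-d / ah2)
          wsum <- wsum + wgt
          vsum <- vsum + wgt * unclass(image)[r1, c1]
        }
      }
      out[r0, c0] <- vsum / wsum
    }
  }
  gray_image(out)
}
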