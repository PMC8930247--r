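#' Specification of a synthetic kidney-like phantom
#'
#' The phantom is piecewise constant: a background at the first class
#' intensity, plus one nested, slightly rotated ellipse per remaining
#' class (outer ellipse standing in for parenchyma, inner for the renal
#' sinus).  Ellipse centers, semi-axes and orientation are jittered
#' deterministically by `seed`, so the geometry varies across seeds
#' while every tissue class keeps at least 5% of the pixels.
#'
#' @param height,width Image size in pixels (at least 16 each).
#' @param class_intensities Ordered vector of at least two distinct
#'   tissue intensity levels in \[0, 1\]; the first is the background.
#' @param seed Integer geometry seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         class_intensities = c(0.2, 0.5, 0.8),
                         seed = 0L) {
  if (height < 16L || width < 16L) {
    stop("phantom must be at least 16x16 pixels", call. = FALSE)
  }
  k <- length(class_intensities)
  if (k < 2L) stop("need at least 2 intensity classes", call. = FALSE)
  if (anyDuplicated(class_intensities)) {
    stop("class intensities must be distinct", call. = FALSE)
  }
  if (min(class_intensities) < 0 || max(class_intensities) > 1) {
    stop("class intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_intensities = as.numeric(class_intensities),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a piecewise-constant organ phantom
#'
#' Deterministic given the spec (including its geometry seed).  The set
#' of distinct pixel values of the result is exactly
#' `spec$class_intensities`, and each class occupies at least 5% of the
#' pixels; a spec whose geometry cannot honor that bound is rejected.
#'
#' @param spec A [phantom_spec].
#' @return A [gray_image].
#' @examples
#' ph <- make_phantom(phantom_spec(64, 64, c(0.2, 0.5, 0.8), seed = 1))
#' sort(unique(as.numeric(ph)))
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  k <- length(spec$class_intensities)
  lab <- with_seed(spec$seed, {
    cy <- h / 2 * (1 + runif(1, -0.06, 0.06))
    cx <- w / 2 * (1 + runif(1, -0.06, 0.06))
    theta <- runif(1, -pi / 12, pi / 12)
    ry0 <- 0.40 * h * runif(1, 0.95, 1.05)
    rx0 <- 0.34 * w * runif(1, 0.95, 1.05)
    rows <- matrix(seq_len(h), h, w) - cy
    cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    u <- cos(theta) * rows + sin(theta) * cols
    v <- -sin(theta) * rows + cos(theta) * cols
    lab <- matrix(1L, h, w)
    # nested ellipses: class j+1 inside scale factor sqrt((k-j)/(k-1))
    for (j in seq_len(k - 1L)) {
      f <- sqrt((k - j) / (k - 1))
      inside <- (u / (ry0 * f))^2 + (v / (rx0 * f))^2 <= 1
      lab[inside] <- j + 1L
    }
    lab
  })
  counts <- tabulate(lab, nbins = k)
  if (any(counts < 0.05 * h * w)) {
    stop("image too small to contain the requested regions ",
         "(a class would occupy < 5% of pixels)", call. = FALSE)
  }
  gray_image(matrix(spec$class_intensities[lab], h, w))
}

#' Multiplicative speckle-noise parameters
#'
#' @param sigma Standard deviation of the zero-mean Gaussian
#'   multiplicative noise field (dimensionless, `>= 0`).
#' @param seed Integer noise seed.
#' @return A `speckle_params` list.
#' @export
speckle_params <- function(sigma = 0.2, seed = 0L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  }
  structure(list(sigma = as.numeric(sigma), seed = as.integer(seed)),
            class = "speckle_params")
}

#' Corrupt an image with multiplicative speckle noise
#'
#' The noise model is `J(i) = I(i) * (1 + n(i))` with `n` i.i.d.
#' zero-mean Gaussian of standard deviation `params$sigma`, followed by
#' clipping to \[0, 1\] (part of the model, keeping the intensity
#' invariant of [gray_image]).  So `E[J] = I` and `sd(J) = I * sigma`
#' wherever clipping is inactive, i.e. the noise is signal-dependent as
#' in ultrasound speckle.  Bit-for-bit reproducible given the seed.
#'
#' @param image A [gray_image].
#' @param params A [speckle_params].
#' @return A [gray_image] of the same dimensions.
#' @export
add_speckle <- function(image, params = speckle_params()) {
  image <- as_gray_image(image)
  stopifnot(inherits(params, "speckle_params"))
  if (params$sigma == 0) return(image)
  noisy <- with_seed(params$seed, {
    n <- matrix(rnorm(length(image), sd = params$sigma),
                nrow(image), ncol(image))
    unclass(image) * (1 + n)
  })
  gray_image(pmin(pmax(noisy, 0), 1))
}

#' Robust estimate of the image noise standard deviation
#'
#' Estimates the additive-equivalent noise standard deviation from
#' Laplacian pseudo-residuals: the image is convolved (valid region
#' only) with the difference-of-Laplacians stencil
#' \preformatted{ 1 -2  1
#' -2  4 -2
#'  1 -2  1}
#' which annihilates locally planar structure, so the residuals carry
#' (almost) pure noise away from edges.  For i.i.d. noise of standard
#' deviation `sigma` the residual has standard deviation `6 * sigma`;
#' the residual scale is measured with the median absolute deviation
#' (consistent for a Gaussian), which suppresses the heavy-tailed
#' contribution of the edge pixels that inflates moment-based
#' estimators.  This estimate sets the NL-Means filter coefficient `h`
#' when none is supplied.
#'
#' @param image A [gray_image], at least 3x3.
#' @return Nonnegative scalar estimate of the noise std.
#' @export
estimate_noise_std <- function(image) {
  image <- as_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) {
    stop("image must be at least 3x3 for the residual stencil",
         call. = FALSE)
  }
  m <- unclass(image)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  r <- 4 * m[ri, ci, drop = FALSE] -
    2 * (m[ri - 1L, ci, drop = FALSE] + m[ri + 1L, ci, drop = FALSE] +
           m[ri, ci - 1L, drop = FALSE] + m[ri, ci + 1L, drop = FALSE]) +
    (m[ri - 1L, ci - 1L, drop = FALSE] + m[ri - 1L, ci + 1L, drop = FALSE] +
       m[ri + 1L, ci - 1L, drop = FALSE] + m[ri + 1L, ci + 1L, drop = FALSE])
  stats::mad(as.numeric(r), center = stats::median(as.numeric(r))) / 6
}
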