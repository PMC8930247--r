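#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities normalized to
#' \[0, 1\], the universal pixel container of the package.  Rows index
#' image rows (top to bottom), columns index image columns; all pixel
#' coordinates in the package are 1-based `(row, col)` pairs.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @return A numeric matrix with class `gray_image`.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains NA intensities", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", class(matrix())))
}

# Accept a gray_image or a bare numeric matrix; validate either way.
as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.4f, %.4f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Intensities are rescaled to \[0, 1\] by the format's maximum
#' representable value (255 for 8-bit, 65535 for 16-bit).  RGB input is
#' converted to luminance with the Rec. 601 weights
#' `0.299 R + 0.587 G + 0.114 B`; an alpha channel, if present, is
#' dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(arr) == 0L) stop("zero-sized image: ", path, call. = FALSE)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  # readers already scale by the bit depth's maximum; clamp float fuzz
  gray_image(pmin(pmax(arr, 0), 1))
}

#' Write a grayscale image to PNG or TIFF
#'
#' A `load_image(save_image(x))` round trip reproduces intensities to
#' within one quantization step of the chosen bit depth.
#'
#' @param image A [gray_image] or numeric matrix in \[0, 1\].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth for TIFF output: 8, 16 or 32 (float, lossless).
#'   PNG output is always 8-bit.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 8L) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  m <- unclass(image)
  ok <- switch(ext,
    png  = {
      png::writePNG(m, target = path)
      TRUE
    },
    tif  = ,
    tiff = {
      tiff::writeTIFF(m, where = path, bits.per.sample = as.integer(bits))
      TRUE
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (!ok || !file.exists(path)) stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Mean squared error between two images
#'
#' Mean over all pixels of the squared intensity difference, on the
#' normalized \[0, 1\] scale.
#'
#' @param reference,test Images of identical dimensions.
#' @return Nonnegative scalar.
#' @export
mse <- function(reference, test) {
  reference <- as_gray_image(reference)
  test <- as_gray_image(test)
  if (!identical(dim(reference), dim(test))) {
    stop("image dimensions differ: ",
         paste(dim(reference), collapse = "x"), " vs ",
         paste(dim(test), collapse = "x"), call. = FALSE)
  }
  mean((as.numeric(reference) - as.numeric(test))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX = 1` on the normalized intensity
#' scale.  Identical images have zero MSE; the PSNR is then reported as
#' the documented sentinel `Inf`, never as an error.
#'
#' @inheritParams mse
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(reference, test) {
  e <- mse(reference, test)
  if (e == 0) return(Inf)
  10 * log10(1 / e)
}

#' Quality metrics of a denoised image against a clean reference
#'
#' @inheritParams mse
#' @return A list with elements `mse` and `psnr`.
#' @export
quality_metrics <- function(reference, test) {
  e <- mse(reference, test)
  list(mse = e, psnr = if (e == 0) Inf else 10 * log10(1 / e))
}
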