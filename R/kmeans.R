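#' Per-pixel clustering features: local patch mean and std
#'
#' The objects handed to the K-means classifier.  Each pixel is
#' represented by the mean and the (population) standard deviation of
#' the intensities in the mirror-padded square patch centered on it.
#' Under multiplicative speckle the local std scales with the local
#' mean, so the pair separates tissue classes better than raw
#' intensity alone.
#'
#' @param image A [gray_image].
#' @param patch_radius Patch half-width in pixels (`>= 1`).
#' @return A `pixel_features` object: an `n_pixels x 2` matrix (columns
#'   `mean`, `sd`, pixels in column-major order) with attribute `dim_img`
#'   recording the image dimensions.
#' @export
pixel_features <- function(image, patch_radius = 2L) {
  image <- as_gray_image(image)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 1L) stop("`patch_radius` must be >= 1", call. = FALSE)
  f <- patch_moments(unclass(image), patch_radius)
  colnames(f) <- c("mean", "sd")
  structure(f, dim_img = dim(image), class = c("pixel_features", "matrix"))
}

#' Random initial cluster centers
#'
#' `K` distinct pixels are drawn uniformly without replacement and
#' their feature vectors become the initial centers; deterministic
#' given the seed.
#'
#' @param features A [pixel_features] matrix (or any numeric matrix of
#'   row-wise feature vectors).
#' @param K Number of clusters, `1 <= K <=` number of pixels.
#' @param seed Integer seed.
#' @return A `K x d` matrix of centers.
#' @export
init_centers <- function(features, K, seed = 0L) {
  K <- as.integer(K)
  n <- nrow(features)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (K > n) stop("`K` exceeds the number of pixels", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, K))
  unclass(features)[idx, , drop = FALSE]
}

# Squared Euclidean distances from every feature row to every center:
# n x K matrix.
dist2_to_centers <- function(features, centers) {
  f <- unclass(features)
  cross <- f %*% t(centers)
  sweep(sweep(-2 * cross, 2L, rowSums(centers^2), "+"),
        1L, rowSums(f^2), "+")
}

#' Nearest-center assignment step
#'
#' Labels every pixel with its nearest center by Euclidean distance in
#' feature space; ties break toward the lowest cluster index.
#'
#' @inheritParams init_centers
#' @param centers A `K x d` matrix of centers.
#' @return Integer label vector in `1..K` (one per pixel).
#' @export
assign_step <- function(features, centers) {
  if (nrow(centers) < 1L) stop("`centers` must be non-empty", call. = FALSE)
  # max.col(-d) with ties.method = "first" == argmin with lowest-index ties
  max.col(-dist2_to_centers(features, centers), ties.method = "first")
}

#' Center update step
#'
#' Each center becomes the arithmetic mean of its members' feature
#' vectors.  A cluster left empty by the reassignment is re-seeded to
#' the feature vector of the pixel farthest from its nearest center,
#' so K live clusters are maintained.
#'
#' @inheritParams assign_step
#' @param labels Integer labels in `1..K` as from [assign_step].
#' @param K Number of clusters.
#' @return A `K x d` matrix of updated centers.
#' @export
update_step <- function(features, labels, K = max(labels)) {
  f <- unclass(features)
  K <- as.integer(K)
  centers <- matrix(NA_real_, K, ncol(f))
  for (j in seq_len(K)) {
    members <- labels == j
    if (any(members)) {
      centers[j, ] <- colMeans(f[members, , drop = FALSE])
    }
  }
  empty <- which(is.na(centers[, 1L]))
  if (length(empty)) {
    live <- centers[!is.na(centers[, 1L]), , drop = FALSE]
    d2 <- dist2_to_centers(f, live)
    nearest <- apply(d2, 1L, min)
    for (j in empty) {
      far <- which.max(nearest)
      centers[j, ] <- f[far, ]
      nearest[far] <- -Inf          # don't reuse the same point
    }
  }
  centers
}

# Within-cluster sum of squared distances.
wcss <- function(features, labels, centers) {
  f <- unclass(features)
  sum((f - centers[labels, , drop = FALSE])^2)
}

#' Run K-means to convergence
#'
#' Alternates [assign_step] and [update_step] from random initial
#' centers until the centers stop moving (exact equality, with an
#' absolute tolerance fallback of `1e-12` for floating-point
#' arithmetic) or `max_iter` is reached.  The within-cluster sum of
#' squares is recorded after every update and is non-increasing.
#'
#' @inheritParams init_centers
#' @param max_iter Iteration cap (`>= 1`); exhausting it sets
#'   `converged = FALSE` rather than raising an error.
#' @return A `cluster_assignment` list: `labels` (integer vector in
#'   `1..K`, and as matrix `label_matrix` when the features carry image
#'   dimensions), `centers`, `iterations`, `converged`,
#'   `objective_trace`.
#' @export
kmeans_run <- function(features, K, seed = 0L, max_iter = 100L) {
  K <- as.integer(K); max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  centers <- init_centers(features, K, seed)
  trace <- numeric(0)
  labels <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    labels <- assign_step(features, centers)
    new_centers <- update_step(features, labels, K)
    trace <- c(trace, wcss(features, labels, new_centers))
    if (max(abs(new_centers - centers)) <= 1e-12) {
      centers <- new_centers
      converged <- TRUE
      break
    }
    centers <- new_centers
  }
  out <- list(labels = labels, centers = centers, iterations = iter,
              converged = converged, objective_trace = trace)
  dims <- attr(features, "dim_img")
  if (!is.null(dims)) out$label_matrix <- matrix(labels, dims[1], dims[2])
  structure(out, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment: K = %d, %d pixels, %d iteration%s, %s>\n",
    nrow(x$centers), length(x$labels), x$iterations,
    if (x$iterations == 1L) "" else "s",
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
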