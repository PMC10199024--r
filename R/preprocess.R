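# Tissue segmentation, de-noising and intensity normalization.

# run code with the global RNG stream saved/restored, seeded locally
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Segment tissue from background
#'
#' Projects each pixel's channel vector onto the top principal components and
#' partitions pixels into two k-means clusters; the cluster with the higher
#' mean total ion intensity is labeled tissue.
#'
#' @param stack an [ion_image_stack()] with at least 2 pixels and 2 channels.
#' @param n_components number of principal components (default 5, capped at
#'   the channel count).
#' @param seed RNG seed for k-means initialization (results are deterministic
#'   given the seed).
#' @return A `segmentation_mask`: logical `width x height` matrix (`TRUE` =
#'   tissue) with method metadata attributes.
#' @export
segment_tissue <- function(stack, n_components = 5, seed = 1) {
  stopifnot(inherits(stack, "ion_image_stack"))
  d <- dim(stack$tensor)
  if (d[2] * d[3] < 2L || d[1] < 2L) stop("need >= 2 pixels and >= 2 channels")
  X <- matrix(aperm(stack$tensor, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
  if (all(apply(X, 2, stats::var) == 0)) {
    stop("all pixels identical: no variance to decompose")
  }
  k <- min(n_components, d[1], nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  km <- .with_seed(seed, stats::kmeans(pc$x, centers = 2, nstart = 10))
  tic <- rowSums(X)
  tissue_cluster <- which.max(tapply(tic, km$cluster, mean))
  mask <- matrix(km$cluster == tissue_cluster, nrow = d[2], ncol = d[3])
  structure(mask, class = c("segmentation_mask", class(mask)),
            n_components = k, k = 2L, seed = seed)
}

#' 3x3 Gaussian blur
#'
#' Replaces each pixel by a 3x3 Gaussian-weighted neighborhood average
#' (kernel normalized to sum 1, default sigma 1 pixel); edges are handled by
#' reflection. The operation is linear and leaves constant images unchanged.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (default 1, truncated
#'   to the 3x3 support).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_denoise <- function(image, sigma = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  g <- exp(-(-1:1)^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  nr <- nrow(image); nc <- ncol(image)
  # reflect-pad by one pixel
  ri <- c(if (nr > 1) 2L else 1L, seq_len(nr), if (nr > 1) nr - 1L else nr)
  ci <- c(if (nc > 1) 2L else 1L, seq_len(nc), if (nc > 1) nc - 1L else nc)
  pad <- image[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + kern[di + 1L, dj + 1L] *
      pad[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
  }
  out
}

#' Blur every channel of a stack
#'
#' Applies [gaussian_denoise()] to each per-isotopologue intensity image.
#'
#' @inheritParams gaussian_denoise
#' @param stack an [ion_image_stack()].
#' @return The stack with blurred tensor.
#' @export
denoise_stack <- function(stack, sigma = 1) {
  for (ch in seq_len(dim(stack$tensor)[1])) {
    stack$tensor[ch, , ] <- gaussian_denoise(stack$tensor[ch, , ], sigma)
  }
  stack
}

#' Per-pixel intensity normalization
#'
#' `"tic"` divides each pixel's channel vector by its total ion current
#' (summed over all extracted channels) and rescales by the grid-median TIC;
#' `"none"` is the identity. Zero-TIC pixels are left unchanged and counted
#' in the `zero_tic_pixels` attribute. Downstream fractional labeling is
#' invariant to this step (ratios cancel).
#'
#' @param stack an [ion_image_stack()].
#' @param mode `"none"` or `"tic"`.
#' @return The normalized stack.
#' @export
normalize_pixels <- function(stack, mode = c("none", "tic")) {
  mode <- match.arg(mode)
  if (mode == "none") return(stack)
  d <- dim(stack$tensor)
  tic <- apply(stack$tensor, c(2, 3), sum)
  nz <- tic > 0
  med <- stats::median(tic[nz])
  scale <- matrix(1, d[2], d[3])
  scale[nz] <- med / tic[nz]
  for (ch in seq_len(d[1])) stack$tensor[ch, , ] <- stack$tensor[ch, , ] * scale
  attr(stack, "zero_tic_pixels") <- sum(!nz)
  stack
}
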