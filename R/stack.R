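# Per-target isotopologue intensity tensor over a pixel grid.

#' Construct an ion image stack
#'
#' The central data container: an `n x w x h` tensor of extracted
#' isotopologue intensities, where `n` runs over every ladder m/z of every
#' target metabolite. Usually built by [extract_ion_images()] or
#' [generate_phantom()].
#'
#' @param tensor numeric array, dim `c(n_channels, width, height)`; negative
#'   values are clipped to 0 with a warning.
#' @param channels data frame with columns `target`, `k` (isotopologue index,
#'   0-based) and `mz`, one row per tensor slice.
#' @param targets list of [target_metabolite()] objects.
#' @param grid a [pixel_grid()].
#' @param labeled whether the source tissue was tracer-fed.
#' @return An `ion_image_stack` object.
#' @export
ion_image_stack <- function(tensor, channels, targets, grid, labeled = TRUE) {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3L)
  stopifnot(dim(tensor)[1] == nrow(channels),
            dim(tensor)[2] == grid$width,
            dim(tensor)[3] == grid$height)
  if (any(tensor < 0)) {
    warning(sum(tensor < 0), " negative intensities clipped to 0")
    tensor[tensor < 0] <- 0
  }
  names(targets) <- vapply(targets, `[[`, "", "name")
  structure(list(tensor = tensor, channels = channels, targets = targets,
                 grid = grid, labeled = labeled),
            class = "ion_image_stack")
}

#' @export
print.ion_image_stack <- function(x, ...) {
  cat(sprintf("Ion image stack: %d channels x %d x %d pixels (%s)\n",
              dim(x$tensor)[1], x$grid$width, x$grid$height,
              if (x$labeled) "labeled" else "unlabeled"))
  cat("  targets:", paste(names(x$targets), collapse = ", "), "\n")
  invisible(x)
}

# row indices into channels/tensor for one target, ordered M0..Mn
.target_rows <- function(stack, target) {
  name <- if (inherits(target, "target_metabolite")) target$name else target
  if (!name %in% stack$channels$target) stop("target not in stack: ", name)
  rows <- which(stack$channels$target == name)
  rows[order(stack$channels$k[rows])]
}

#' Per-pixel isotopologue matrix for one target
#'
#' Returns the `(n_carbons + 1) x n_pixels` matrix of intensities for the
#' pixels listed in the stack's grid (column order follows `grid$coords`).
#'
#' @param stack an [ion_image_stack()].
#' @param target target name or [target_metabolite()].
#' @return Numeric matrix, rows M0..Mn.
#' @export
target_pixel_matrix <- function(stack, target) {
  rows <- .target_rows(stack, target)
  cc <- stack$grid$coords
  idx <- cbind(rep(rows, times = nrow(cc)),
               rep(cc$x + 1L, each = length(rows)),
               rep(cc$y + 1L, each = length(rows)))
  matrix(stack$tensor[idx], nrow = length(rows))
}

#' Extract isotopologue ion images from spectra
#'
#' For every ladder m/z of every target, sums all peaks within a ppm window
#' at each pixel and assembles the result into an [ion_image_stack()].
#' Pixels absent from the file get zero intensity. Overlapping extraction
#' windows of different targets are reported with a warning but both
#' extracted; exclusion of compromised isotopologues is the job of
#' [screen_interferences()].
#'
#' @param spectra an [msi_spectra()] collection.
#' @param targets list of [target_metabolite()] objects.
#' @param tol_ppm half-width of the extraction window in ppm (default 10,
#'   chosen for a resolving power of ~43,000 FWHM).
#' @param labeled whether the tissue was tracer-fed (stored in the stack).
#' @return An `ion_image_stack`.
#' @export
extract_ion_images <- function(spectra, targets, tol_ppm = 10, labeled = TRUE) {
  stopifnot(inherits(spectra, "msi_spectra"), tol_ppm > 0)
  if (inherits(targets, "target_metabolite")) targets <- list(targets)
  channels <- do.call(rbind, lapply(targets, function(t) {
    data.frame(target = t$name, k = 0:t$n_carbons, mz = t$mz_ladder)
  }))
  rownames(channels) <- NULL

  # flag ambiguous windows across different targets
  ord <- order(channels$mz)
  mzs <- channels$mz[ord]
  gap_ok <- diff(mzs) > 2 * tol_ppm * 1e-6 * mzs[-length(mzs)]
  clash <- which(!gap_ok)
  clash <- clash[channels$target[ord][clash] != channels$target[ord][clash + 1L]]
  if (length(clash)) {
    warning("ambiguous extraction windows (< 2*tol_ppm apart) between targets: ",
            paste(sprintf("%s M%d / %s M%d",
                          channels$target[ord][clash], channels$k[ord][clash],
                          channels$target[ord][clash + 1L], channels$k[ord][clash + 1L]),
                  collapse = "; "))
  }

  grid <- spectra$grid
  tensor <- array(0, dim = c(nrow(channels), grid$width, grid$height))
  lo <- channels$mz * (1 - tol_ppm * 1e-6)
  hi <- channels$mz * (1 + tol_ppm * 1e-6)
  for (i in seq_len(nrow(grid$coords))) {
    mz <- spectra$mz[[i]]
    if (!length(mz)) next
    o <- order(mz)
    mz <- mz[o]
    csum <- cumsum(spectra$intensity[[i]][o])
    a <- findInterval(lo, mz, left.open = TRUE)   # peaks strictly below lo
    b <- findInterval(hi, mz)                      # peaks <= hi
    vals <- ifelse(b > a, csum[pmax(b, 1L)] - c(0, csum)[a + 1L], 0)
    tensor[, grid$coords$x[i] + 1L, grid$coords$y[i] + 1L] <- vals
  }
  ion_image_stack(tensor, channels, targets, grid, labeled = labeled)
}

#' Convert an ion image stack back to spectra
#'
#' Each pixel becomes a peak list at the channel m/z values (zero-intensity
#' channels dropped), suitable for [write_imzml()]. Pixels not listed in the
#' grid are omitted.
#'
#' @param stack an [ion_image_stack()].
#' @param drop_zero drop zero-intensity peaks (default TRUE).
#' @return An [msi_spectra()] object.
#' @export
as_msi_spectra <- function(stack, drop_zero = TRUE) {
  stopifnot(inherits(stack, "ion_image_stack"))
  cc <- stack$grid$coords
  mzs <- stack$channels$mz
  mz_list <- vector("list", nrow(cc)); int_list <- vector("list", nrow(cc))
  o <- order(mzs)
  for (i in seq_len(nrow(cc))) {
    v <- stack$tensor[, cc$x[i] + 1L, cc$y[i] + 1L]
    keep <- if (drop_zero) which(v[o] > 0) else seq_along(o)
    mz_list[[i]] <- mzs[o][keep]
    int_list[[i]] <- v[o][keep]
  }
  msi_spectra(stack$grid, mz_list, int_list, mode = "processed")
}

#' Export per-pixel channel values as a long table
#'
#' @param stack an [ion_image_stack()].
#' @return data frame with columns x, y, target, k, mz, intensity.
#' @export
stack_table <- function(stack) {
  cc <- stack$grid$coords
  n_ch <- nrow(stack$channels)
  idx <- cbind(rep(seq_len(n_ch), times = nrow(cc)),
               rep(cc$x + 1L, each = n_ch),
               rep(cc$y + 1L, each = n_ch))
  data.frame(
    x = rep(cc$x, each = n_ch), y = rep(cc$y, each = n_ch),
    target = rep(stack$channels$target, times = nrow(cc)),
    k = rep(stack$channels$k, times = nrow(cc)),
    mz = rep(stack$channels$mz, times = nrow(cc)),
    intensity = stack$tensor[idx]
  )
}
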