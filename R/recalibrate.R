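# Adaptive per-pixel mass recalibration against high-confidence reference
# annotations. Each pixel gets a smooth ppm-shift model (linear in m/z over
# its matched references, constant with < 3 matches, the grid-median model
# with < 2 matches); intensities are never touched.

#' Per-pixel mass recalibration
#'
#' Matches, in every pixel, the nearest observed peak within `search_ppm` to
#' each reference m/z, fits a per-pixel ppm-shift model
#' `shift(mz) = a + b * mz`, and divides the pixel's m/z axis by
#' `1 + shift * 1e-6`. Pixels with fewer than 3 matches fall back to a
#' constant offset; pixels with fewer than 2 matches inherit the grid-median
#' model.
#'
#' @param spectra an [msi_spectra()] collection.
#' @param reference_mzs numeric vector of annotated (theoretical) m/z values;
#'   at least 3 should be detectable in a majority of pixels.
#' @param search_ppm half-width of the matching window in ppm (default 50).
#' @return List with `spectra` (corrected axes, same intensities) and
#'   `model` (a `recalibration_model`: per-pixel coefficients and match
#'   counts).
#' @export
recalibrate <- function(spectra, reference_mzs, search_ppm = 50) {
  stopifnot(inherits(spectra, "msi_spectra"), length(reference_mzs) >= 1)
  n <- nrow(spectra$grid$coords)
  coefs <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("a", "b")))
  n_match <- integer(n)
  matches <- vector("list", n)

  for (i in seq_len(n)) {
    mz <- spectra$mz[[i]]
    if (!length(mz)) next
    obs <- vapply(reference_mzs, function(r) {
      j <- which.min(abs(mz - r))
      if (abs(mz[j] - r) <= search_ppm * 1e-6 * r) mz[j] else NA_real_
    }, 0)
    ok <- !is.na(obs)
    n_match[i] <- sum(ok)
    if (n_match[i] == 0L) next
    ref <- reference_mzs[ok]
    shift <- (obs[ok] - ref) / ref * 1e6
    matches[[i]] <- cbind(reference = ref, observed = obs[ok])
    if (n_match[i] >= 3L) {
      fit <- stats::lm.fit(cbind(1, ref), shift)
      coefs[i, ] <- fit$coefficients
    } else {
      coefs[i, ] <- c(mean(shift), 0)
    }
  }

  if (all(n_match == 0L)) {
    stop("no reference m/z matched in any pixel; skip recalibration for this dataset")
  }
  # grid-median fallback for sparse pixels
  good <- n_match >= 2L
  med <- if (any(good)) apply(coefs[good, , drop = FALSE], 2, stats::median)
         else apply(coefs[n_match >= 1L, , drop = FALSE], 2, stats::median)
  fallback <- n_match < 2L
  coefs[fallback, 1] <- med[1]
  coefs[fallback, 2] <- med[2]

  mz_new <- vector("list", n)
  for (i in seq_len(n)) {
    mz <- spectra$mz[[i]]
    mz_new[[i]] <- if (length(mz)) mz / (1 + (coefs[i, 1] + coefs[i, 2] * mz) * 1e-6) else mz
  }
  model <- structure(list(coefficients = coefs, n_matched = n_match,
                          reference_peaks = matches, search_ppm = search_ppm),
                     class = "recalibration_model")
  list(spectra = msi_spectra(spectra$grid, mz_new, spectra$intensity,
                             mode = spectra$mode),
       model = model)
}

#' @export
print.recalibration_model <- function(x, ...) {
  cat(sprintf("Recalibration model: %d pixels, median offset %.3f ppm, %d pixels on fallback\n",
              nrow(x$coefficients), stats::median(x$coefficients[, 1]),
              sum(x$n_matched < 2L)))
  invisible(x)
}

#' Undo a recalibration
#'
#' Restores the observed m/z axes from recalibrated spectra (relative error
#' below 1e-9), used to verify model invertibility.
#'
#' @param spectra recalibrated [msi_spectra()].
#' @param model the paired `recalibration_model`.
#' @return An `msi_spectra` with the original axes.
#' @export
invert_recalibration <- function(spectra, model) {
  n <- nrow(spectra$grid$coords)
  mz_new <- vector("list", n)
  for (i in seq_len(n)) {
    mzc <- spectra$mz[[i]]
    if (!length(mzc)) { mz_new[[i]] <- mzc; next }
    a <- model$coefficients[i, 1]; b <- model$coefficients[i, 2]
    # solve mz_obs = mzc * (1 + (a + b*mz_obs)*1e-6) for mz_obs
    mz_new[[i]] <- mzc * (1 + a * 1e-6) / (1 - mzc * b * 1e-6)
  }
  msi_spectra(spectra$grid, mz_new, spectra$intensity, mode = spectra$mode)
}
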