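# Per-pixel flux maps and region summaries.

#' Per-pixel SISA flux image
#'
#' Runs [fit_sisa()] (or [fit_elongation()]) on the fractional labeling of
#' every tissue pixel of one target and assembles the fitted `g` (and `e`)
#' into images. The stack should be NA-corrected first
#' ([na_correct_stack()]).
#'
#' @param stack a corrected [ion_image_stack()].
#' @param target target name or [target_metabolite()] (needs `n_subunits`).
#' @param model `"sisa"` (17-isotopologue palmitate-style fit) or
#'   `"elongation"` (19-isotopologue stearate fit).
#' @param tissue_mask logical `width x height` matrix from
#'   [segment_tissue()]; `NULL` fits every pixel with signal.
#' @param iso_mask isotopologue usability mask (e.g. from
#'   [interference_mask()]); default all usable.
#' @param N pre-existing-pool monomer labeling (default `c(1,0,0)` for
#'   corrected input).
#' @param min_intensity pixels whose summed unmasked intensity is at or
#'   below this are skipped rather than fitted to noise.
#' @param t_hours labeling duration, metadata only.
#' @param starts,reltol optimizer settings per pixel; the default (3 starts,
#'   reltol 1e-9) balances per-pixel cost against the noise floor of real
#'   images.
#' @return A `flux_image`: matrices `g`, `e` (elongation only), `sse`,
#'   `converged`, plus counts of skipped/failed pixels.
#' @export
flux_image <- function(stack, target, model = c("sisa", "elongation"),
                       tissue_mask = NULL, iso_mask = NULL, N = c(1, 0, 0),
                       min_intensity = 0, t_hours = NA_real_,
                       starts = NULL, reltol = 1e-9) {
  model <- match.arg(model)
  tgt <- if (inherits(target, "target_metabolite")) target
         else stack$targets[[target]]
  if (model == "elongation" && tgt$n_carbons != 18L) {
    stop("elongation model needs a 19-isotopologue (18-carbon) target")
  }
  n_sub <- if (model == "elongation") 9L else tgt$n_subunits
  if (is.na(n_sub)) stop("target has no n_subunits: ", tgt$name)
  len <- 2L * n_sub + 1L
  if (tgt$n_carbons + 1L != len) {
    stop("target ladder length does not match model order")
  }
  if (is.null(iso_mask)) iso_mask <- rep(TRUE, len)
  N <- .check_simplex(N, "N")
  if (is.null(starts)) starts <- .x_starts(N, n_random = 0)[1:3]

  A <- target_pixel_matrix(stack, tgt)
  cc <- stack$grid$coords
  keep <- if (is.null(tissue_mask)) rep(TRUE, nrow(cc))
          else tissue_mask[cbind(cc$x + 1L, cc$y + 1L)]

  w <- stack$grid$width; h <- stack$grid$height
  g_img <- e_img <- sse_img <- matrix(NA_real_, w, h)
  conv_img <- matrix(NA, w, h)
  n_skipped <- n_failed <- 0L
  for (p in which(keep)) {
    a <- A[, p]
    tot <- sum(a[iso_mask])
    if (tot <= min_intensity) { n_skipped <- n_skipped + 1L; next }
    f <- a / tot
    fit <- tryCatch({
      if (model == "sisa") {
        fit_sisa(f, N = N, n_subunits = n_sub, mask = iso_mask,
                 starts = starts, reltol = reltol)
      } else {
        fit_elongation(f, N = N, mask = iso_mask,
                       starts = starts, reltol = reltol)
      }
    }, error = function(err) NULL)
    i <- cc$x[p] + 1L; j <- cc$y[p] + 1L
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    g_img[i, j] <- fit$g
    e_img[i, j] <- fit$e
    sse_img[i, j] <- fit$sse
    conv_img[i, j] <- TRUE
  }
  n_attempted <- sum(keep) - n_skipped
  if (n_attempted > 0 && n_failed > n_attempted / 2) {
    stop("flux fitting failed on ", n_failed, " of ", n_attempted,
         " pixels; check NA correction, masks and signal levels")
  }
  structure(list(g = g_img, e = if (model == "elongation") e_img else NULL,
                 sse = sse_img, converged = conv_img,
                 target = tgt$name, model = model, t_hours = t_hours,
                 n_fitted = n_attempted - n_failed,
                 n_skipped = n_skipped, n_failed = n_failed),
            class = "flux_image")
}

#' @export
print.flux_image <- function(x, ...) {
  cat(sprintf("Flux image: %s (%s model), t = %s h\n", x$target, x$model,
              format(x$t_hours)))
  cat(sprintf("  %d pixels fitted (%d skipped, %d failed); g: median %.3f [%.3f, %.3f]\n",
              x$n_fitted, x$n_skipped, x$n_failed,
              stats::median(x$g, na.rm = TRUE),
              min(x$g, na.rm = TRUE), max(x$g, na.rm = TRUE)))
  invisible(x)
}

#' Heatmap of a flux image
#'
#' @param x a `flux_image`.
#' @param which `"g"`, `"e"` or `"g+e"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.flux_image <- function(x, which = "g", ...) {
  img <- switch(which, g = x$g, e = x$e, `g+e` = x$g + x$e,
                stop("which must be 'g', 'e' or 'g+e'"))
  if (is.null(img)) stop("no '", which, "' channel in this flux image")
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)),
                  img, ylim = c(ncol(img) + 0.5, 0.5),
                  xlab = "x", ylab = "y",
                  main = sprintf("%s %s(%s h)", x$target, which,
                                 format(x$t_hours)), ...)
  invisible(x)
}

#' Per-pixel table of a flux image
#'
#' @param x a `flux_image`.
#' @return data frame (x, y, g, e, sse, converged) over fitted pixels.
#' @export
flux_table <- function(x) {
  idx <- which(!is.na(x$g), arr.ind = TRUE)
  data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L,
             g = x$g[idx],
             e = if (is.null(x$e)) NA_real_ else x$e[idx],
             sse = x$sse[idx], converged = TRUE)
}

#' Compare flux between two regions of interest
#'
#' Reports per-ROI mean and SD of `g` (and `g + e` for elongation fits) and
#' their ratio. Given a single image, a two-tailed Welch t statistic over
#' pixel values is reported (descriptive: pixels are spatially correlated).
#' Given a list of replicate images, ROI means are computed per replicate
#' and compared with a paired two-tailed t test.
#'
#' @param flux a `flux_image` or list of replicate `flux_image`s.
#' @param roi_a,roi_b disjoint logical `width x height` matrices, each with
#'   at least one pixel.
#' @param channel `"g"` or `"g+e"`.
#' @return A `region_summary` list: `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `ratio` (a over b), `t`, `p`, `n_a`, `n_b`.
#' @export
region_summary <- function(flux, roi_a, roi_b, channel = c("g", "g+e")) {
  channel <- match.arg(channel)
  if (any(roi_a & roi_b)) stop("ROIs must be disjoint")
  if (!any(roi_a) || !any(roi_b)) stop("empty ROI")
  imgs <- if (inherits(flux, "flux_image")) list(flux) else flux
  grab <- function(im) {
    v <- if (channel == "g") im$g else im$g + im$e
    list(a = v[roi_a & !is.na(v)], b = v[roi_b & !is.na(v)])
  }
  vals <- lapply(imgs, grab)
  if (length(imgs) == 1L) {
    a <- vals[[1]]$a; b <- vals[[1]]$b
    tt <- if (length(a) > 1 && length(b) > 1) {
      stats::t.test(a, b, alternative = "two.sided")
    } else NULL
    out <- list(mean_a = mean(a), sd_a = stats::sd(a),
                mean_b = mean(b), sd_b = stats::sd(b),
                ratio = mean(a) / mean(b),
                t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                p = if (is.null(tt)) NA_real_ else tt$p.value,
                n_a = length(a), n_b = length(b), n_replicates = 1L)
  } else {
    ma <- vapply(vals, function(v) mean(v$a), 0)
    mb <- vapply(vals, function(v) mean(v$b), 0)
    tt <- stats::t.test(ma, mb, paired = TRUE, alternative = "two.sided")
    out <- list(mean_a = mean(ma), sd_a = stats::sd(ma),
                mean_b = mean(mb), sd_b = stats::sd(mb),
                ratio = mean(ma) / mean(mb),
                t = unname(tt$statistic), p = tt$p.value,
                n_a = length(ma), n_b = length(mb),
                n_replicates = length(imgs))
  }
  structure(c(out, list(channel = channel)), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region comparison (%s, %d replicate%s):\n", x$channel,
              x$n_replicates, if (x$n_replicates > 1) "s" else ""))
  cat(sprintf("  ROI A: %.4f +/- %.4f (n = %d)\n", x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  ROI B: %.4f +/- %.4f (n = %d)\n", x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  ratio A/B = %.3f; t = %.3f, p = %.3g\n", x$ratio, x$t, x$p))
  invisible(x)
}
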