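# Ground-truth phantom generator: a two-region (tumor / healthy tissue)
# labeled brain image plus its unlabeled twin, so every pipeline stage is
# testable without instrument data.

#' Default phantom targets: palmitate and stearate
#'
#' @return List of two [target_metabolite()] objects (C16, 8 subunits;
#'   C18, 9 subunits), deprotonated.
#' @export
default_targets <- function() {
  list(
    target_metabolite("palmitate", "C16H32O2", "[M-H]-", 16, 8),
    target_metabolite("stearate", "C18H36O2", "[M-H]-", 18, 9)
  )
}

#' Phantom specification
#'
#' Describes a synthetic two-region MSI dataset: an elliptical tissue section
#' containing an elliptical tumor sub-region, with per-region fractional
#' turnover `g` (and elongation `e` for stearate), per-region monomer
#' labeling `X`, natural-abundance convolution, per-region pool-size scaling
#' (emulating matrix effects), fractional Gaussian noise, optional
#' contaminant peaks and an optional ppm mass-shift field.
#'
#' Default turnover values place ~2.75-fold higher palmitate synthesis and
#' ~8-fold higher stearate synthesis-plus-elongation in the tumor
#' (`g_palm` 0.55 vs 0.20; `g + e` for stearate 0.40 vs 0.05).
#'
#' @param width,height grid size in pixels (default 60 x 40).
#' @param pixel_size micrometers, metadata only.
#' @param targets list of [target_metabolite()]; default palmitate +
#'   stearate.
#' @param g named per-region lists of per-target fractional turnover.
#' @param e as `g`, elongation fraction (targets with 9 subunits only).
#' @param X per-region monomer labeling simplex 3-vectors.
#' @param p13 13C natural abundance applied as forward convolution.
#' @param pool_scale per-region multiplicative pool-size factors (matrix
#'   effects); fractional labeling must be invariant to these.
#' @param base_intensity tissue pool intensity scale (arbitrary units).
#' @param background_intensity off-tissue M0 signal level.
#' @param noise_rel relative SD of the per-channel multiplicative log-normal
#'   intensity noise (default 0.01, i.e. 1% measurement noise). This is the
#'   phantom's primary noise model: proportional, so it cannot push
#'   near-zero isotopologues negative.
#' @param noise_frac additive Gaussian SD on isotopologue fractions
#'   (clipped at zero, renormalized), default 0. This is the error-
#'   propagation noise model ([noise_gradient_simulation()]); switch it on
#'   to build phantoms for calibrating that analysis.
#' @param pool_sdlog SD of a per-pixel log-normal factor on the whole pool
#'   (pixel-to-pixel matrix-effect variation).
#' @param noise_floor additive intensity floor on every channel.
#' @param contaminants `NULL` or data frame with columns `mz`, `intensity`,
#'   `region` (`"tissue"`, `"tumor"`, `"all"`), `labeled_only`/`unlabeled_only`
#'   optional logical columns.
#' @param tol_ppm window used to map contaminant m/z onto channels.
#' @param seed RNG seed; identical specs give identical phantoms.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(width = 60, height = 40, pixel_size = 50,
                         targets = default_targets(),
                         g = list(tumor = c(palmitate = 0.55, stearate = 0.25),
                                  healthy = c(palmitate = 0.20, stearate = 0.02)),
                         e = list(tumor = c(stearate = 0.15),
                                  healthy = c(stearate = 0.03)),
                         X = list(tumor = c(0.35, 0.25, 0.40),
                                  healthy = c(0.55, 0.25, 0.20)),
                         p13 = P13C_DEFAULT,
                         pool_scale = list(tumor = 2, healthy = 1),
                         base_intensity = 1e4,
                         background_intensity = 100,
                         noise_rel = 0.01,
                         noise_frac = 0,
                         pool_sdlog = 0,
                         noise_floor = 0,
                         contaminants = NULL,
                         tol_ppm = 10,
                         seed = 1) {
  for (r in c("tumor", "healthy")) {
    X[[r]] <- .check_simplex(X[[r]], paste0("X$", r))
    for (t in names(g[[r]])) {
      gv <- g[[r]][[t]]
      ev <- if (!is.null(e[[r]]) && t %in% names(e[[r]])) e[[r]][[t]] else 0
      if (gv < 0 || ev < 0 || gv + ev > 1) {
        stop("infeasible flux fractions for ", t, " in region ", r)
      }
    }
  }
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 targets = targets, g = g, e = e, X = X, p13 = p13,
                 pool_scale = pool_scale, base_intensity = base_intensity,
                 background_intensity = background_intensity,
                 noise_rel = noise_rel, noise_frac = noise_frac,
                 pool_sdlog = pool_sdlog,
                 noise_floor = noise_floor, contaminants = contaminants,
                 tol_ppm = tol_ppm, seed = seed),
            class = "phantom_spec")
}

# elliptical region masks: tissue fills most of the grid, tumor is a
# unilateral sub-ellipse (~15% of tissue area)
.phantom_masks <- function(width, height) {
  x <- (seq_len(width) - 0.5) / width
  y <- (seq_len(height) - 0.5) / height
  ell <- function(cx, cy, rx, ry) {
    outer(x, y, function(a, b) ((a - cx) / rx)^2 + ((b - cy) / ry)^2 <= 1)
  }
  tissue <- ell(0.5, 0.5, 0.45, 0.42)
  tumor <- ell(0.70, 0.40, 0.14, 0.22) & tissue
  list(tissue = tissue, tumor = tumor)
}

#' Generate a phantom dataset
#'
#' Runs the forward pipeline per pixel: SISA / elongation forward model at
#' the region's parameters, natural-abundance convolution, pool-size
#' scaling, noise, and optional contaminants — once with the specified flux
#' fractions (labeled) and once with `g = e = 0` (unlabeled twin). Ground
#' truth (region masks and parameter maps) is returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @return List with `labeled` and `unlabeled` [ion_image_stack()]s and
#'   `truth` (masks, per-target `g`/`e` maps, `X` per region, pool images).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- .phantom_masks(spec$width, spec$height)
  region_of <- matrix("background", spec$width, spec$height)
  region_of[masks$tissue] <- "healthy"
  region_of[masks$tumor] <- "tumor"

  channels <- do.call(rbind, lapply(spec$targets, function(t) {
    data.frame(target = t$name, k = 0:t$n_carbons, mz = t$mz_ladder)
  }))
  rownames(channels) <- NULL
  coords <- expand.grid(x = 0:(spec$width - 1L), y = 0:(spec$height - 1L))
  grid <- pixel_grid(spec$width, spec$height, coords, spec$pixel_size)

  N0 <- c(1, 0, 0)
  # per-region, per-target noiseless observed fractions (after NA
  # convolution), for labeled and unlabeled variants
  frac_of <- function(t, region, labeled) {
    M <- na_correction_matrix(t$n_carbons, spec$p13)
    gv <- if (labeled) spec$g[[region]][[t$name]] else 0
    if (is.null(gv)) gv <- 0
    ev <- 0
    if (labeled && !is.null(spec$e[[region]]) &&
        t$name %in% names(spec$e[[region]])) {
      ev <- spec$e[[region]][[t$name]]
    }
    P <- if (!is.na(t$n_subunits) && t$n_subunits == 9L) {
      elongation_forward(spec$X[[region]], N0, gv, ev)
    } else if (!is.na(t$n_subunits)) {
      sisa_forward(spec$X[[region]], N0, gv, t$n_subunits)
    } else {
      c(1, rep(0, t$n_carbons))  # non-polymer target: unlabeled pool
    }
    as.numeric(M %*% P)
  }

  build_stack <- function(labeled, seed) {
    base_frac <- list()
    for (t in spec$targets) for (r in c("tumor", "healthy")) {
      base_frac[[paste(t$name, r)]] <- frac_of(t, r, labeled)
    }
    tensor <- array(0, dim = c(nrow(channels), spec$width, spec$height))
    .with_seed(seed, {
      for (ti in seq_along(spec$targets)) {
        t <- spec$targets[[ti]]
        rows <- which(channels$target == t$name)
        nk <- length(rows)
        theo_na <- stats::dbinom(0:t$n_carbons, t$n_carbons, spec$p13)
        noisy_frac <- function(f) {
          if (spec$noise_frac > 0) {
            f <- pmax(f + stats::rnorm(nk, 0, spec$noise_frac), 0)
            f <- f / sum(f)
          }
          f
        }
        for (ix in seq_len(spec$width)) for (iy in seq_len(spec$height)) {
          r <- region_of[ix, iy]
          if (r == "background") {
            if (spec$background_intensity > 0) {
              v <- noisy_frac(theo_na) * spec$background_intensity
              if (spec$noise_rel > 0) v <- v * stats::rlnorm(nk, 0, spec$noise_rel)
              tensor[rows, ix, iy] <- v
            }
            next
          }
          f <- noisy_frac(base_frac[[paste(t$name, r)]])
          pool <- spec$base_intensity * spec$pool_scale[[r]]
          if (spec$pool_sdlog > 0) {
            pool <- pool * stats::rlnorm(1, 0, spec$pool_sdlog)
          }
          v <- f * pool
          if (spec$noise_rel > 0) v <- v * stats::rlnorm(nk, 0, spec$noise_rel)
          tensor[rows, ix, iy] <- v + spec$noise_floor
        }
      }
    })
    if (!is.null(spec$contaminants)) {
      cont <- spec$contaminants
      for (ci in seq_len(nrow(cont))) {
        if (labeled && isTRUE(cont$unlabeled_only[ci])) next
        if (!labeled && isTRUE(cont$labeled_only[ci])) next
        hit <- which(abs(channels$mz - cont$mz[ci]) <=
                       spec$tol_ppm * 1e-6 * cont$mz[ci])
        reg_mask <- switch(cont$region[ci],
                           tumor = masks$tumor,
                           tissue = masks$tissue,
                           all = matrix(TRUE, spec$width, spec$height),
                           stop("unknown contaminant region: ", cont$region[ci]))
        for (ch in hit) {
          tensor[ch, , ][reg_mask] <- tensor[ch, , ][reg_mask] + cont$intensity[ci]
        }
      }
    }
    ion_image_stack(tensor, channels, spec$targets, grid, labeled = labeled)
  }

  labeled <- build_stack(TRUE, spec$seed)
  unlabeled <- build_stack(FALSE, spec$seed + 1L)

  g_maps <- e_maps <- list()
  for (t in spec$targets) {
    gm <- em <- matrix(NA_real_, spec$width, spec$height)
    for (r in c("tumor", "healthy")) {
      gv <- spec$g[[r]][[t$name]]; if (is.null(gv)) gv <- 0
      ev <- if (!is.null(spec$e[[r]]) && t$name %in% names(spec$e[[r]])) {
        spec$e[[r]][[t$name]]
      } else 0
      gm[region_of == r] <- gv
      em[region_of == r] <- ev
    }
    g_maps[[t$name]] <- gm; e_maps[[t$name]] <- em
  }

  list(labeled = labeled, unlabeled = unlabeled,
       truth = list(tissue = masks$tissue, tumor = masks$tumor,
                    healthy = masks$tissue & !masks$tumor,
                    g = g_maps, e = e_maps, X = spec$X,
                    region = region_of),
       spec = spec)
}

#' Contaminants mimicking the DESI palmitate background
#'
#' Interfering peaks at the palmitate M1, M4 and M5 m/z positions, present
#' across the whole image (slide background), for exercising
#' [screen_interferences()].
#'
#' @param intensity peak intensity.
#' @return Data frame usable as `phantom_spec(contaminants = ...)`.
#' @export
palmitate_contaminants <- function(intensity = 2000) {
  ladder <- build_target_ladder("C16H32O2", "[M-H]-", 16)
  data.frame(mz = ladder[c(2, 5, 6)], intensity = intensity, region = "all")
}

#' Apply a ppm mass-shift field to spectra
#'
#' Perturbs every pixel's m/z axis by `mz * (1 + shift * 1e-6)` where
#' `shift` is a constant or a `function(x, y, mz)` (0-based coordinates).
#' Intensities are untouched. Used to exercise [recalibrate()].
#'
#' @param spectra an [msi_spectra()].
#' @param shift ppm offset, scalar or function.
#' @return Shifted `msi_spectra`.
#' @export
apply_ppm_shift <- function(spectra, shift) {
  n <- nrow(spectra$grid$coords)
  mz_new <- vector("list", n)
  for (i in seq_len(n)) {
    mz <- spectra$mz[[i]]
    s <- if (is.function(shift)) {
      shift(spectra$grid$coords$x[i], spectra$grid$coords$y[i], mz)
    } else shift
    mz_new[[i]] <- mz * (1 + s * 1e-6)
  }
  msi_spectra(spectra$grid, mz_new, spectra$intensity, mode = spectra$mode)
}
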