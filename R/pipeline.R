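# Pipeline configuration and the stage commands behind the command-line
# entry point (inst/cli/sisaflux.R): simulate -> extract -> screen -> flux
# -> errorprop, with provenance records.

#' Read and validate a pipeline configuration
#'
#' YAML file with (all optional unless a stage needs them): `labeled_imzml`,
#' `unlabeled_imzml`, `target_list`, `out_dir`, `tol_ppm`, `recalibrate`
#' (list: `reference_mzs`, `search_ppm`), `segmentation` (`n_components`,
#' `seed`), `blur_sigma` (0 = off), `normalization` ("none"/"tic"), `p13`,
#' `interference_threshold`, `sisa` (`model`, `target`, `min_intensity`,
#' `t_hours`), `errorprop` (`sigma_levels`, `n_reps`, `seed`, `target`),
#' `phantom` (overrides for [phantom_spec()]).
#'
#' @param path YAML config path.
#' @return A `pipeline_config` list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(tol_ppm = 10, blur_sigma = 0, normalization = "none",
                   p13 = P13C_DEFAULT, interference_threshold = 0.02,
                   segmentation = list(n_components = 5, seed = 1),
                   out_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("labeled_imzml", "unlabeled_imzml", "target_list")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("configured file does not exist: ", k, " = ", cfg[[k]])
    }
  }
  if (!cfg$normalization %in% c("none", "tic")) {
    stop("normalization must be 'none' or 'tic'")
  }
  stopifnot(cfg$tol_ppm > 0, cfg$p13 >= 0, cfg$p13 < 1)
  cfg$config_path <- path
  class(cfg) <- "pipeline_config"
  cfg
}

.provenance <- function(cfg, out_dir, seeds = NULL) {
  rec <- list(
    package = "sisaflux",
    version = as.character(utils::packageVersion("sisaflux")),
    config_md5 = if (!is.null(cfg$config_path) && file.exists(cfg$config_path)) {
      unname(tools::md5sum(cfg$config_path))
    } else NA_character_,
    seeds = seeds,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}

.load_inputs <- function(cfg) {
  targets <- read_target_list(cfg$target_list)
  prep <- function(path, labeled) {
    if (is.null(path)) return(NULL)
    sp <- read_imzml(path)
    if (!is.null(cfg$recalibrate)) {
      sp <- recalibrate(sp, as.numeric(cfg$recalibrate$reference_mzs),
                        search_ppm = cfg$recalibrate$search_ppm %||% 50)$spectra
    }
    st <- extract_ion_images(sp, targets, tol_ppm = cfg$tol_ppm,
                             labeled = labeled)
    if (cfg$blur_sigma > 0) st <- denoise_stack(st, cfg$blur_sigma)
    normalize_pixels(st, cfg$normalization)
  }
  list(targets = targets,
       labeled = prep(cfg$labeled_imzml, TRUE),
       unlabeled = prep(cfg$unlabeled_imzml, FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract stage: imzML to ion image stacks, mask and tables
#'
#' @param cfg a [read_pipeline_config()] result.
#' @return Invisibly, list of the stacks and mask written to `out_dir`.
#' @export
cmd_extract <- function(cfg) {
  if (is.null(cfg$labeled_imzml) || is.null(cfg$target_list)) {
    stop("cmd_extract needs labeled_imzml and target_list in the config")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(cfg)
  mask <- segment_tissue(inp$labeled, cfg$segmentation$n_components,
                         cfg$segmentation$seed)
  utils::write.csv(stack_table(inp$labeled),
                   file.path(cfg$out_dir, "stack_labeled.csv"),
                   row.names = FALSE)
  if (!is.null(inp$unlabeled)) {
    utils::write.csv(stack_table(inp$unlabeled),
                     file.path(cfg$out_dir, "stack_unlabeled.csv"),
                     row.names = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  utils::write.csv(data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L),
                   file.path(cfg$out_dir, "tissue_mask.csv"),
                   row.names = FALSE)
  .provenance(cfg, cfg$out_dir, seeds = list(segmentation = cfg$segmentation$seed))
  invisible(list(labeled = inp$labeled, unlabeled = inp$unlabeled,
                 mask = mask, targets = inp$targets))
}

#' Flux stage: screen, correct, fit, export
#'
#' Runs the full targeted workflow on the configured imzML pair and writes
#' per-pixel flux tables, a flux imzML, and the interference report. A
#' prominent warning is logged when no unlabeled control is configured
#' (unscreened analysis).
#'
#' @param cfg a [read_pipeline_config()] result with a `sisa` block.
#' @return Invisibly, the [flux_image()].
#' @export
cmd_flux <- function(cfg) {
  if (is.null(cfg$sisa) || is.null(cfg$sisa$target)) {
    stop("cmd_flux needs a sisa block with a target name")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- cmd_extract(cfg)
  report <- screen_interferences(ext$unlabeled, ext$targets,
                                 threshold = cfg$interference_threshold,
                                 tissue_mask = ext$mask, p13 = cfg$p13)
  if (attr(report, "status") == "unscreened") {
    warning("no unlabeled control configured: isotopologue interferences NOT screened")
  }
  utils::write.csv(as.data.frame(report),
                   file.path(cfg$out_dir, "interference_report.csv"),
                   row.names = FALSE)
  iso_masks <- if (attr(report, "status") == "screened") {
    stats::setNames(lapply(names(ext$labeled$targets), function(nm) {
      interference_mask(report, nm)
    }), names(ext$labeled$targets))
  } else NULL
  corrected <- na_correct_stack(ext$labeled, p13 = cfg$p13,
                                tissue_mask = ext$mask,
                                iso_masks = iso_masks)
  model <- cfg$sisa$model %||% "sisa"
  fx <- flux_image(corrected, cfg$sisa$target, model = model,
                   tissue_mask = ext$mask,
                   iso_mask = interference_mask(report, cfg$sisa$target),
                   min_intensity = cfg$sisa$min_intensity %||% 0,
                   t_hours = cfg$sisa$t_hours %||% NA_real_)
  utils::write.csv(flux_table(fx),
                   file.path(cfg$out_dir, sprintf("flux_%s.csv", cfg$sisa$target)),
                   row.names = FALSE)
  .provenance(cfg, cfg$out_dir, seeds = list(segmentation = cfg$segmentation$seed))
  invisible(fx)
}

#' Simulate stage: write a phantom imzML pair plus ground truth
#'
#' @param cfg a [read_pipeline_config()] result; `cfg$phantom` entries
#'   override [phantom_spec()] defaults.
#' @return Invisibly, the [generate_phantom()] result.
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- cfg$phantom %||% list()
  spec <- do.call(phantom_spec, args)
  ph <- generate_phantom(spec)
  write_imzml(ph$labeled, file.path(cfg$out_dir, "phantom_labeled.imzML"))
  write_imzml(ph$unlabeled, file.path(cfg$out_dir, "phantom_unlabeled.imzML"))
  for (t in names(ph$truth$g)) {
    idx <- which(ph$truth$tissue, arr.ind = TRUE)
    utils::write.csv(
      data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L,
                 g = ph$truth$g[[t]][idx], e = ph$truth$e[[t]][idx],
                 tumor = ph$truth$tumor[idx]),
      file.path(cfg$out_dir, sprintf("truth_%s.csv", t)), row.names = FALSE)
  }
  .provenance(cfg, cfg$out_dir, seeds = list(phantom = spec$seed))
  invisible(ph)
}

#' Error-propagation stage
#'
#' Runs the noise-gradient simulation, measures labeling error from the
#' configured unlabeled imzML (when present) and writes the projection.
#'
#' @param cfg a [read_pipeline_config()] result with an `errorprop` block.
#' @return Invisibly, list(result, projection or NULL).
#' @export
cmd_errorprop <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ep <- cfg$errorprop %||% list()
  res <- noise_gradient_simulation(
    model = ep$model %||% "sisa",
    sigma_levels = as.numeric(ep$sigma_levels %||%
                                exp(seq(log(0.001), log(0.05), length.out = 8))),
    n_reps = ep$n_reps %||% 200,
    seed = ep$seed %||% 1)
  utils::write.csv(res$levels, file.path(cfg$out_dir, "noise_gradient.csv"),
                   row.names = FALSE)
  proj <- NULL
  if (!is.null(cfg$unlabeled_imzml) && !is.null(ep$target)) {
    inp <- .load_inputs(cfg)
    mask <- segment_tissue(inp$unlabeled, cfg$segmentation$n_components,
                           cfg$segmentation$seed)
    err <- measure_labeling_error(inp$unlabeled, ep$target,
                                  tissue_mask = mask, p13 = cfg$p13)
    proj <- project_error(res, err)
    jsonlite::write_json(
      list(measured_error = err, projected_mean = proj$mean,
           projected_sd = proj$sd, slope = res$slope,
           intercept = res$intercept),
      file.path(cfg$out_dir, "error_projection.json"),
      auto_unbox = TRUE, digits = NA)
  }
  .provenance(cfg, cfg$out_dir, seeds = list(errorprop = ep$seed %||% 1))
  invisible(list(result = res, projection = proj))
}
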