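#' Analysis run configuration
#'
#' Collects the method constants in one place. The defaults reproduce the
#' standard procedure exactly: candidate peak at mean + 4 SD, convergence at
#' z > 0.99, thresholds 5-70% of peak in 5% steps, supra-peak voxels
#' excluded strictly (`>`) from iteration statistics and functional volumes
#' delineated inclusively (`>=`), clipped voxels included in functional
#' volumes. They are exposed so sensitivity analyses can vary them.
#'
#' @param thresholds Threshold grid, each in (0, 1].
#' @param convergence_cutoff Convergence ratio in (0, 1). Default 0.99.
#' @param sigma_multiplier SD multiplier for the candidate peak. Default 4.
#' @param include_clipped_in_volume Keep clipped voxels in functional
#'   volumes. Default `TRUE`.
#' @param seed Optional integer seed for stochastic stages (phantoms,
#'   simulated cohorts).
#' @return An object of class `run_config`.
#' @export
run_config <- function(thresholds = default_thresholds(),
                       convergence_cutoff = 0.99,
                       sigma_multiplier = 4,
                       include_clipped_in_volume = TRUE,
                       seed = NULL) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0), all(thresholds <= 1),
            convergence_cutoff > 0, convergence_cutoff < 1,
            sigma_multiplier > 0,
            is.logical(include_clipped_in_volume))
  structure(
    list(thresholds = as.numeric(thresholds),
         convergence_cutoff = convergence_cutoff,
         sigma_multiplier = sigma_multiplier,
         include_clipped_in_volume = include_clipped_in_volume,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a [run_config()]; for `write_run_config`,
#'   invisibly `path`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full delineation pipeline for one patient
#'
#' Ties the stages together in the standard order: geometry checks, peak
#' convergence per modality, threshold sweep, matched-volume intersection,
#' and a per-patient results table. Writes normalized volumes, one binary
#' functional mask per modality and threshold, a per-threshold CSV, and a
#' JSON provenance record (configuration, package version, input checksums)
#' into `out_dir`. A perfusion-only patient (no ventilation path) produces
#' perfusion outputs and no matched outputs.
#'
#' @param config A [run_config()].
#' @param ventilation_path,perfusion_path NIfTI paths; either (but not both)
#'   may be `NULL`.
#' @param mask_path NIfTI path of the binary lung mask.
#' @param out_dir Output directory, created if needed.
#' @param write_masks Write the per-threshold binary masks (default `TRUE`;
#'   disable to keep only tables and reports).
#' @return Invisibly, a list with per-modality `peak_normalization` objects,
#'   the combined per-threshold tibble (`results`), and the output paths.
#' @export
run_pipeline <- function(config, ventilation_path = NULL,
                         perfusion_path = NULL, mask_path, out_dir,
                         write_masks = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(ventilation_path) && is.null(perfusion_path)) {
    stop("at least one of ventilation or perfusion input is required",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- read_mask(mask_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mods <- list()
  sweeps <- list()
  paths <- list(ventilation = ventilation_path, perfusion = perfusion_path)
  for (mod in c("ventilation", "perfusion")) {
    p <- paths[[mod]]
    if (is.null(p)) next
    vol <- stage(paste0("read ", mod), read_volume(p, mod))
    stage(paste0("geometry ", mod), check_geometry(vol, mask))
    norm <- stage(paste0("normalize ", mod), converge_peak(
      vol, mask, sigma_multiplier = config$sigma_multiplier,
      convergence_cutoff = config$convergence_cutoff))
    sw <- stage(paste0("delineate ", mod), sweep_thresholds(
      norm, mask, thresholds = config$thresholds,
      include_clipped = config$include_clipped_in_volume))
    mods[[mod]] <- norm
    sweeps[[mod]] <- sw
    write_volume(norm$normalized,
                 file.path(out_dir, paste0(mod, "_normalized.nii.gz")))
    report <- c(glance.peak_normalization(norm),
                list(iterations = norm$iterations))
    jsonlite::write_json(report,
                         file.path(out_dir, paste0(mod, "_peak.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (write_masks) {
      for (fv in sw$volumes) {
        fmask <- lung_mask(fv$mask, spacing = fv$spacing, origin = fv$origin)
        write_volume(fmask, file.path(out_dir, sprintf(
          "%s_functional_%02d.nii.gz", mod,
          round(100 * fv$threshold_fraction))))
      }
    }
  }

  results <- dplyr::bind_rows(lapply(sweeps, tidy.threshold_sweep))
  if (length(sweeps) == 2L) {
    matched <- stage("matched volumes", purrr::map2(
      sweeps$ventilation$volumes, sweeps$perfusion$volumes, matched_volume))
    results <- dplyr::bind_rows(results, tibble::tibble(
      modality = "matched",
      threshold = vapply(matched, `[[`, 1.0, "threshold_fraction"),
      n_voxels = vapply(matched, `[[`, 1L, "n_voxels"),
      fractional_volume = vapply(matched, `[[`, 1.0, "fractional_volume"),
      absolute_volume_ml = vapply(matched, `[[`, 1.0, "absolute_volume_ml")))
    if (write_masks) {
      for (fv in matched) {
        fmask <- lung_mask(fv$mask, spacing = fv$spacing, origin = fv$origin)
        write_volume(fmask, file.path(out_dir, sprintf(
          "matched_functional_%02d.nii.gz",
          round(100 * fv$threshold_fraction))))
      }
    }
  }
  results_path <- file.path(out_dir, "functional_volumes.csv")
  utils::write.csv(results, results_path, row.names = FALSE)

  inputs <- Filter(Negate(is.null),
                   c(paths, list(mask = mask_path)))
  provenance <- list(
    package = "vqfunc",
    version = as.character(utils::packageVersion("vqfunc")),
    config = unclass(config),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(normalizations = mods, results = results,
                 out_dir = out_dir, results_path = results_path))
}
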