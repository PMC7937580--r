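#' Default threshold grid
#'
#' The standard sweep spans 5% to 70% of the converged peak intensity in 5%
#' increments: 14 thresholds.
#'
#' @return Numeric vector of 14 threshold fractions.
#' @export
default_thresholds <- function() seq(0.05, 0.70, by = 0.05)

#' Delineate a functional lung volume at one threshold
#'
#' The functional volume at threshold fraction `t` is the set of lung voxels
#' whose normalized uptake is at least `t` times the converged peak
#' intensity. The comparison is inclusive (`>=`), which guarantees that
#' hotspot voxels clipped to the peak are reintroduced into the functional
#' volume at every threshold up to 100%. Setting `include_clipped = FALSE`
#' removes the clipped voxels from the functional volume instead, for
#' sensitivity analyses of how much the reintroduced hotspot volume
#' contributes.
#'
#' @param normalized A `peak_normalization` from [converge_peak()].
#' @param mask The [lung_mask()] used for the normalization.
#' @param threshold_fraction A single fraction of peak intensity in (0, 1].
#' @param include_clipped Keep clipped hotspot voxels in the functional
#'   volume (default `TRUE`).
#'
#' @return An object of class `functional_volume`: list with `mask` (0/1
#'   array), `threshold_fraction`, `modality`, `n_voxels`,
#'   `fractional_volume` (functional voxels / lung voxels),
#'   `absolute_volume_ml`, and geometry (`spacing`, `origin`).
#' @export
delineate <- function(normalized, mask, threshold_fraction,
                      include_clipped = TRUE) {
  stopifnot(inherits(normalized, "peak_normalization"),
            inherits(mask, "lung_mask"))
  check_geometry(normalized$normalized, mask)
  if (length(threshold_fraction) != 1L || !is.finite(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("`threshold_fraction` must be a single value in (0, 1], got ",
         format(threshold_fraction), call. = FALSE)
  }
  in_lung <- mask$values == 1
  fmask <- in_lung &
    normalized$normalized$values >= threshold_fraction * normalized$peak_intensity
  if (!include_clipped) {
    fmask <- fmask & !normalized$clipped
  }
  n_lung <- sum(in_lung)
  n_fun <- sum(fmask)
  structure(
    list(
      mask = array(as.double(fmask), dim(fmask)),
      threshold_fraction = threshold_fraction,
      modality = normalized$normalized$modality,
      n_voxels = as.integer(n_fun),
      n_lung_voxels = as.integer(n_lung),
      fractional_volume = n_fun / n_lung,
      absolute_volume_ml = n_fun * voxel_volume_ml(mask$spacing),
      spacing = mask$spacing,
      origin = mask$origin
    ),
    class = "functional_volume"
  )
}

#' @export
print.functional_volume <- function(x, ...) {
  cat("<functional_volume>", x$modality,
      sprintf("@ %.0f%% of peak | %d voxels (%.1f%% of lung, %.1f mL)\n",
              100 * x$threshold_fraction, x$n_voxels,
              100 * x$fractional_volume, x$absolute_volume_ml))
  invisible(x)
}

#' Sweep functional volumes over a threshold grid
#'
#' Applies [delineate()] at each threshold. Because the functional mask at a
#' higher threshold is a subset of the mask at any lower threshold, the
#' fractional volume is non-increasing along the sweep.
#'
#' @inheritParams delineate
#' @param thresholds Vector of threshold fractions in (0, 1]; default
#'   [default_thresholds()] (5-70% by 5%).
#'
#' @return An object of class `threshold_sweep`: list with `volumes` (list
#'   of `functional_volume`) and `table`, a tibble with one row per
#'   threshold (`modality`, `threshold`, `n_voxels`, `fractional_volume`,
#'   `absolute_volume_ml`).
#' @export
sweep_thresholds <- function(normalized, mask,
                             thresholds = default_thresholds(),
                             include_clipped = TRUE) {
  if (length(thresholds) == 0L) {
    stop("`thresholds` must be non-empty", call. = FALSE)
  }
  vols <- lapply(thresholds, function(t) {
    delineate(normalized, mask, t, include_clipped = include_clipped)
  })
  tab <- tibble::tibble(
    modality = vapply(vols, `[[`, "", "modality"),
    threshold = as.numeric(thresholds),
    n_voxels = vapply(vols, `[[`, 1L, "n_voxels"),
    fractional_volume = vapply(vols, `[[`, 1.0, "fractional_volume"),
    absolute_volume_ml = vapply(vols, `[[`, 1.0, "absolute_volume_ml")
  )
  structure(list(volumes = vols, table = tab), class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep> of", nrow(x$table), "thresholds\n")
  print(x$table)
  invisible(x)
}

#' @rdname sweep_thresholds
#' @param x A `threshold_sweep`.
#' @param ... Unused.
#' @return For `tidy.threshold_sweep`: the per-threshold tibble.
#' @method tidy threshold_sweep
#' @export
tidy.threshold_sweep <- function(x, ...) x$table

#' Matched ventilation-perfusion functional volume
#'
#' The matched volume at a threshold is the voxelwise intersection of the
#' ventilation and perfusion functional volumes delineated at that same
#' threshold (each against its own independently converged peak).
#'
#' @param ventilation,perfusion `functional_volume` objects at the same
#'   threshold on the same geometry, with modalities `"ventilation"` and
#'   `"perfusion"`.
#' @return A `functional_volume` with `modality = "matched"`.
#' @export
matched_volume <- function(ventilation, perfusion) {
  stopifnot(inherits(ventilation, "functional_volume"),
            inherits(perfusion, "functional_volume"))
  if (!identical(sort(c(ventilation$modality, perfusion$modality)),
                 c("perfusion", "ventilation"))) {
    stop("matched volume needs one ventilation and one perfusion volume, got '",
         ventilation$modality, "' and '", perfusion$modality, "'",
         call. = FALSE)
  }
  if (abs(ventilation$threshold_fraction - perfusion$threshold_fraction) > 1e-9) {
    stop("threshold mismatch: ", ventilation$threshold_fraction, " vs ",
         perfusion$threshold_fraction, call. = FALSE)
  }
  if (!identical(dim(ventilation$mask), dim(perfusion$mask)) ||
      any(abs(ventilation$spacing - perfusion$spacing) > 1e-3)) {
    stop("geometry mismatch between ventilation and perfusion volumes",
         call. = FALSE)
  }
  if (ventilation$n_lung_voxels != perfusion$n_lung_voxels) {
    stop("ventilation and perfusion volumes reference different lung masks",
         call. = FALSE)
  }
  inter <- ventilation$mask * perfusion$mask
  n_fun <- sum(inter)
  structure(
    list(
      mask = inter,
      threshold_fraction = ventilation$threshold_fraction,
      modality = "matched",
      n_voxels = as.integer(n_fun),
      n_lung_voxels = ventilation$n_lung_voxels,
      fractional_volume = n_fun / ventilation$n_lung_voxels,
      absolute_volume_ml = n_fun * voxel_volume_ml(ventilation$spacing),
      spacing = ventilation$spacing,
      origin = ventilation$origin
    ),
    class = "functional_volume"
  )
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for disjoint
#' masks, and `NaN` when both are empty.
#'
#' @param a,b Binary 3D arrays, logical arrays, or `functional_volume`
#'   objects.
#' @return The Dice coefficient.
#' @export
dice_coefficient <- function(a, b) {
  get_mask <- function(x) {
    if (inherits(x, "functional_volume") || inherits(x, "lung_mask")) {
      x$mask %||% x$values
    } else x
  }
  ma <- get_mask(a) != 0
  mb <- get_mask(b) != 0
  if (!identical(dim(ma), dim(mb))) {
    stop("masks have different shapes", call. = FALSE)
  }
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
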