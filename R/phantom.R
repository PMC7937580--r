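#' Specify a synthetic V/Q PET/CT lung phantom
#'
#' Describes a digital thorax phantom with two ellipsoidal lungs inside a
#' soft-tissue body, a designed high-function region with heterogeneous
#' tracer uptake, optional gravity-direction uptake gradient, focal
#' airway-clumping hotspots, and ventilation-to-perfusion hotspot
#' shine-through. The spec plus its seed fully determine the generated
#' volumes.
#'
#' The uptake model: functional-region lung voxels sit at a mean level of
#' 1 (arbitrary activity units) and the remaining lung at
#' `low_uptake_ratio`; both are modulated by multiplicative lognormal
#' heterogeneity with coefficient of variation `background_cv` (lognormal is
#' chosen over Gaussian to keep uptake positive and right-skewed, as tracer
#' uptake is) and, optionally, a linear gravity gradient
#' `1 + gradient_magnitude * s` where `s` runs from -1 to 1 along
#' `gradient_axis`. Hotspots are spheres of constant intensity
#' `intensity_multiple` times the functional-region mean, wholly inside the
#' lung.
#'
#' @param grid_shape Integer length-3, voxels per axis. Default 64^3.
#' @param spacing Voxel size in mm. Default 4 mm isotropic.
#' @param functional_fraction Designed fraction of lung voxels in the
#'   high-function region, in (0, 1]. Default 0.6.
#' @param low_uptake_ratio Uptake level of non-functional lung relative to
#'   functional lung. Default 0.1.
#' @param background_cv Coefficient of variation of the lognormal
#'   heterogeneity. Default 0.15.
#' @param gradient_magnitude Linear gradient amplitude in \[0, 1); 0 disables.
#' @param gradient_axis Axis (1-3) of the gradient. Default 3
#'   (cranio-caudal stand-in for posture).
#' @param n_hotspots Number of clumping hotspots in the ventilation image.
#' @param hotspot_fraction Designed total hotspot volume as a fraction of
#'   lung volume. Default 0.005.
#' @param hotspot_intensity_multiple Hotspot intensity as a multiple of the
#'   functional-region mean uptake; must be > 1. Default 30.
#' @param shine_through_fraction Fraction of ventilation hotspot intensity
#'   visible at the same locations in the perfusion image, in \[0, 1\].
#'   Default 0.3.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the local
#'   mean, applied on top of the lognormal heterogeneity. Default 0.
#' @param seed Integer seed; fully determines the phantom.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(4, 4, 4),
                         functional_fraction = 0.6,
                         low_uptake_ratio = 0.1,
                         background_cv = 0.15,
                         gradient_magnitude = 0,
                         gradient_axis = 3L,
                         n_hotspots = 3L,
                         hotspot_fraction = 0.005,
                         hotspot_intensity_multiple = 30,
                         shine_through_fraction = 0.3,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16),
            length(spacing) == 3L, all(spacing > 0),
            functional_fraction > 0, functional_fraction <= 1,
            low_uptake_ratio >= 0, low_uptake_ratio < 1,
            background_cv >= 0,
            gradient_magnitude >= 0, gradient_magnitude < 1,
            gradient_axis %in% 1:3,
            n_hotspots >= 0,
            hotspot_fraction >= 0, hotspot_fraction < 0.2,
            shine_through_fraction >= 0, shine_through_fraction <= 1,
            noise_sd >= 0)
  if (n_hotspots > 0 && hotspot_intensity_multiple <= 1) {
    stop("`hotspot_intensity_multiple` must be > 1", call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         functional_fraction = functional_fraction,
         low_uptake_ratio = low_uptake_ratio,
         background_cv = background_cv,
         gradient_magnitude = gradient_magnitude,
         gradient_axis = as.integer(gradient_axis),
         n_hotspots = as.integer(n_hotspots),
         hotspot_fraction = hotspot_fraction,
         hotspot_intensity_multiple = hotspot_intensity_multiple,
         shine_through_fraction = shine_through_fraction,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# ellipsoid membership on voxel-centre coordinates scaled to [0,1] per axis
ellipsoid_mask <- function(dims, centre, semi) {
  x <- (seq_len(dims[1]) - 0.5) / dims[1]
  y <- (seq_len(dims[2]) - 0.5) / dims[2]
  z <- (seq_len(dims[3]) - 0.5) / dims[3]
  dx2 <- ((x - centre[1]) / semi[1])^2
  dy2 <- ((y - centre[2]) / semi[2])^2
  dz2 <- ((z - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate a synthetic V/Q PET/CT phantom with ground truth
#'
#' Realises a [phantom_spec()] into paired ventilation and perfusion uptake
#' volumes, a CT volume, and a `phantom_truth` record of the designed voxel
#' sets. The CT places the two lung ellipsoids at -800 HU inside a 40 HU
#' body on a -1000 HU air background, so [derive_lung_mask_from_ct()]
#' recovers the lungs exactly. Ventilation carries the clumping hotspots;
#' the perfusion image carries `shine_through_fraction` of the hotspot
#' intensity at the same voxels on top of its own independent uptake draw.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ventilation`, `perfusion`, `ct`
#'   ([uptake_volume()]s), and `truth`: list with `lung_mask`
#'   ([lung_mask()]), `hotspot_mask`, `functional_region_mask` (0/1
#'   arrays), `true_functional_fraction`, and `hotspot_fraction` (realised
#'   hotspot voxels / lung voxels).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24), seed = 7))
#' sum(ph$truth$lung_mask$values) > 0
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dims <- spec$grid_shape

  left <- ellipsoid_mask(dims, c(0.30, 0.50, 0.52), c(0.13, 0.26, 0.33))
  right <- ellipsoid_mask(dims, c(0.70, 0.50, 0.52), c(0.13, 0.26, 0.33))
  lung <- left | right
  body <- ellipsoid_mask(dims, c(0.50, 0.50, 0.52), c(0.42, 0.40, 0.44))
  body <- body | lung
  n_lung <- sum(lung)

  # CT: air background, soft-tissue body, low-attenuation lungs
  ct_vals <- array(-1000, dims)
  ct_vals[body] <- 40
  ct_vals[lung] <- -800

  # designed high-function region: most-anterior fraction of lung voxels,
  # exact voxel count by construction
  lung_idx <- which(lung)
  coords <- arrayInd(lung_idx, dims)
  ord <- order(coords[, 2], lung_idx)
  n_fun <- max(1L, floor(spec$functional_fraction * n_lung))
  fun_idx <- lung_idx[ord[seq_len(n_fun)]]
  functional <- array(FALSE, dims)
  functional[fun_idx] <- TRUE

  # hotspot placement: spheres fully inside the functional region
  hotspot <- array(FALSE, dims)
  if (spec$n_hotspots > 0 && spec$hotspot_fraction > 0) {
    target_vox <- max(spec$n_hotspots, round(spec$hotspot_fraction * n_lung))
    per_spot <- target_vox / spec$n_hotspots
    radius_mm <- (3 * per_spot * prod(spec$spacing) / (4 * pi))^(1 / 3)
    for (h in seq_len(spec$n_hotspots)) {
      placed <- FALSE
      for (try in 1:200) {
        centre_idx <- fun_idx[sample.int(length(fun_idx), 1L)]
        cc <- arrayInd(centre_idx, dims)[1, ]
        sph <- sphere_voxels(cc, radius_mm, dims, spec$spacing)
        if (length(sph) > 0 && all(functional[sph])) {
          hotspot[sph] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place hotspot ", h, " inside the lung; ",
             "reduce `hotspot_fraction` or `n_hotspots`", call. = FALSE)
      }
    }
  }

  grad <- gradient_field(dims, spec$gradient_axis, spec$gradient_magnitude)
  base <- array(0, dims)
  base[lung] <- spec$low_uptake_ratio
  base[functional] <- 1

  draw_uptake <- function() {
    vals <- array(0, dims)
    level <- base[lung] * grad[lung]
    if (spec$background_cv > 0) {
      sdlog <- sqrt(log(1 + spec$background_cv^2))
      level <- level * stats::rlnorm(n_lung, -sdlog^2 / 2, sdlog)
    }
    if (spec$noise_sd > 0) {
      level <- pmax(0, level + stats::rnorm(n_lung, 0, spec$noise_sd * level))
    }
    vals[lung] <- level
    vals
  }

  vent_vals <- draw_uptake()
  hot_val <- spec$hotspot_intensity_multiple # x functional-region mean (= 1)
  vent_vals[hotspot] <- hot_val

  perf_vals <- draw_uptake()
  if (any(hotspot)) {
    shine <- spec$shine_through_fraction * hot_val
    perf_vals[hotspot] <- pmax(perf_vals[hotspot], shine)
  }

  truth_mask <- lung_mask(array(as.double(lung), dims),
                          spacing = spec$spacing)
  list(
    ventilation = uptake_volume(vent_vals, spec$spacing,
                                modality = "ventilation"),
    perfusion = uptake_volume(perf_vals, spec$spacing,
                              modality = "perfusion"),
    ct = uptake_volume(ct_vals, spec$spacing, modality = "ct"),
    truth = list(
      lung_mask = truth_mask,
      hotspot_mask = array(as.double(hotspot), dims),
      functional_region_mask = array(as.double(functional), dims),
      true_functional_fraction = n_fun / n_lung,
      hotspot_fraction = sum(hotspot) / n_lung
    )
  )
}

# voxel linear indices of a sphere of radius_mm around centre (voxel coords)
sphere_voxels <- function(centre, radius_mm, dims, spacing) {
  r_vox <- ceiling(radius_mm / spacing)
  rng <- lapply(1:3, function(a) {
    seq(max(1L, centre[a] - r_vox[a]), min(dims[a], centre[a] + r_vox[a]))
  })
  grid <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  d2 <- ((grid$x - centre[1]) * spacing[1])^2 +
    ((grid$y - centre[2]) * spacing[2])^2 +
    ((grid$z - centre[3]) * spacing[3])^2
  keep <- d2 <= radius_mm^2
  (grid$z[keep] - 1L) * dims[1] * dims[2] + (grid$y[keep] - 1L) * dims[1] +
    grid$x[keep]
}

gradient_field <- function(dims, axis, magnitude) {
  if (magnitude == 0) return(array(1, dims))
  s <- 2 * ((seq_len(dims[axis]) - 0.5) / dims[axis]) - 1
  mult <- 1 + magnitude * s
  if (axis == 1L) array(mult, dims)
  else if (axis == 2L) array(rep(mult, each = dims[1]), dims)
  else array(rep(mult, each = dims[1] * dims[2]), dims)
}
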