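#' Construct a 3D uptake volume
#'
#' An `uptake_volume` carries a 3D scalar grid of tracer uptake (or CT
#' attenuation) together with its voxel geometry. It is the geometry carrier
#' for every downstream operation: PET ventilation/perfusion images and CT
#' volumes share the same representation, distinguished by `modality`.
#'
#' @param values A 3D numeric array. All values must be finite; for the PET
#'   modalities (`"ventilation"`, `"perfusion"`) values must be non-negative.
#'   CT volumes may be negative (Hounsfield units).
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param origin Numeric length-3 vector, world coordinates (mm) of the first
#'   voxel. Default `c(0, 0, 0)`.
#' @param modality One of `"ventilation"`, `"perfusion"`, `"ct"`.
#'
#' @return An object of class `uptake_volume`: a list with elements `values`,
#'   `spacing`, `origin`, `modality`.
#' @examples
#' v <- uptake_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' dim(v$values)
#' @export
uptake_volume <- function(values, spacing,
                          origin = c(0, 0, 0),
                          modality = c("ventilation", "perfusion", "ct")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (any(dim(values) < 1L)) {
    stop("`values` must have at least one voxel per axis", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("`values` contains non-finite data (NA/NaN/Inf)", call. = FALSE)
  }
  if (modality != "ct" && any(values < 0)) {
    stop("uptake values must be non-negative for modality '", modality, "'",
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel sizes in mm",
         call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite coordinates in mm", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality),
    class = "uptake_volume"
  )
}

#' Construct a binary lung mask
#'
#' A `lung_mask` defines the total lung volume on the same voxel grid as its
#' paired [uptake_volume()]. All statistics of the normalization step and all
#' fractional volumes are computed over (and relative to) this mask.
#'
#' @param values A 3D array of 0/1 (or logical) values with at least one
#'   foreground voxel.
#' @param template An `uptake_volume` supplying `spacing` and `origin`;
#'   alternatively pass them explicitly.
#' @param spacing,origin Geometry, used when `template` is `NULL`.
#'
#' @return An object of class `lung_mask`: list with `values` (0/1 double
#'   array), `spacing`, `origin`.
#' @examples
#' v <- uptake_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' m <- lung_mask(array(1, c(4, 4, 4)), template = v)
#' @export
lung_mask <- function(values, template = NULL, spacing = NULL,
                      origin = c(0, 0, 0)) {
  if (!is.null(template)) {
    stopifnot(inherits(template, "uptake_volume"))
    spacing <- template$spacing
    origin <- template$origin
  }
  if (is.null(spacing)) {
    stop("supply either `template` or `spacing`", call. = FALSE)
  }
  if (is.logical(values)) values <- array(as.double(values), dim(values))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("mask `values` must be a 3D array", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (!all(values %in% c(0, 1))) {
    stop("mask values must be 0/1", call. = FALSE)
  }
  if (sum(values) < 1) {
    stop("mask is empty: at least one voxel must be 1", call. = FALSE)
  }
  if (!is.null(template) && !identical(dim(values), dim(template$values))) {
    stop("mask shape ", paste(dim(values), collapse = "x"),
         " does not match template shape ",
         paste(dim(template$values), collapse = "x"), call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "lung_mask"
  )
}

#' @export
print.uptake_volume <- function(x, ...) {
  cat("<uptake_volume> modality:", x$modality,
      "| shape:", paste(dim(x$values), collapse = "x"),
      "| spacing (mm):", paste(format(x$spacing), collapse = " x "),
      "\n  range: [", format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("<lung_mask> shape:", paste(dim(x$values), collapse = "x"),
      "| voxels:", sum(x$values),
      "| volume (mL):", format(sum(x$values) * prod(x$spacing) / 1000), "\n")
  invisible(x)
}

voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' Check geometric consistency of a volume/mask pair
#'
#' Verifies that a volume and mask live on the same voxel grid: identical
#' shape, spacing equal to within 1e-3 mm, and origin equal to within
#' 1e-3 mm. Every downstream operation that pairs an uptake volume with a
#' lung mask calls this first; geometry mismatches are never silently
#' resampled away, because resampling would corrupt the uptake histogram on
#' which peak convergence depends.
#'
#' @param volume An [uptake_volume()].
#' @param mask A [lung_mask()] (or second `uptake_volume`).
#' @return Invisibly `TRUE`; raises an error listing every differing
#'   attribute otherwise.
#' @export
check_geometry <- function(volume, mask) {
  problems <- character(0)
  if (!identical(dim(volume$values), dim(mask$values))) {
    problems <- c(problems, paste0(
      "shape: ", paste(dim(volume$values), collapse = "x"), " vs ",
      paste(dim(mask$values), collapse = "x")))
  }
  if (any(abs(volume$spacing - mask$spacing) > 1e-3)) {
    problems <- c(problems, paste0(
      "spacing: (", paste(format(volume$spacing), collapse = ", "), ") vs (",
      paste(format(mask$spacing), collapse = ", "), ") mm"))
  }
  if (any(abs(volume$origin - mask$origin) > 1e-3)) {
    problems <- c(problems, paste0(
      "origin: (", paste(format(volume$origin), collapse = ", "), ") vs (",
      paste(format(mask$origin), collapse = ", "), ") mm"))
  }
  if (length(problems)) {
    stop("geometry mismatch between volume and mask:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a volume or mask from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file into an [uptake_volume()], taking voxel
#' spacing and origin from the header. DICOM series directories are not
#' supported; convert to NIfTI first (e.g. with dcm2niix).
#'
#' @param path Path to a NIfTI file.
#' @param modality Modality tag for the result, see [uptake_volume()].
#' @return An `uptake_volume`.
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, modality = c("ventilation", "perfusion", "ct")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (dir.exists(path)) {
    stop("'", path, "' is a directory; DICOM series input is not supported, ",
         "convert to NIfTI first", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume in '", path, "', got ",
         length(dim(arr)), "D", call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (!all(is.finite(as.numeric(arr)))) {
    stop("'", path, "' contains non-finite voxel data", call. = FALSE)
  }
  uptake_volume(array(as.double(arr), dim(arr)), spacing = spacing,
                origin = origin, modality = modality)
}

#' Read a binary lung mask from a NIfTI file
#'
#' @param path Path to a NIfTI file containing 0/1 voxels.
#' @return A [lung_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, modality = "ct")
  vals <- v$values
  if (!all(vals %in% c(0, 1))) {
    stop("'", path, "' is not a binary mask (values outside {0,1})",
         call. = FALSE)
  }
  lung_mask(vals, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to a NIfTI file
#'
#' Writes values with spacing and origin into the NIfTI header; masks are
#' written as integer grids so that a write/read round-trip is bit-exact,
#' uptake volumes round-trip at float64 precision.
#'
#' @param x An [uptake_volume()] or [lung_mask()].
#' @param path Destination `.nii` / `.nii.gz` path; the parent directory must
#'   exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "uptake_volume") || inherits(x, "lung_mask"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  vals <- x$values
  is_mask <- inherits(x, "lung_mask")
  if (is_mask) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  affine <- diag(c(x$spacing, 1))
  affine[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  tryCatch(
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "int16" else "double"),
    error = function(e) {
      stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
    })
  if (!file.exists(path)) {
    stop("cannot write '", path, "'", call. = FALSE)
  }
  invisible(path)
}
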