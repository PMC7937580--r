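# 3D connected components on a logical array, 6-connectivity.
# Returns an integer array of component labels (0 = background).
label_components_3d <- function(fg) {
  dims <- dim(fg)
  idx <- which(fg)
  labels <- array(0L, dims)
  if (length(idx) == 0L) return(labels)
  vox <- integer(prod(dims))
  vox[idx] <- seq_along(idx)

  edges <- list()
  coord <- arrayInd(idx, dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (ax in 1:3) {
    ok <- coord[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    both <- vox[nb] > 0L
    if (any(both)) {
      edges[[length(edges) + 1L]] <-
        cbind(vox[idx[ok][both]], vox[nb[both]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Derive a simple lung mask from a CT volume
#'
#' Segments low-attenuation voxels (below `air_threshold`) into connected
#' components, discards components that touch the grid boundary (exterior
#' air), and keeps components of at least `min_component_volume` millilitres.
#' This is a convenience stand-in for clinical lung contouring: whenever a
#' curated mask is available it should be supplied directly and this function
#' bypassed. The supplied or derived mask is treated as authoritative; no
#' attempt is made to carve out tumour volume.
#'
#' @param ct An [uptake_volume()] with `modality = "ct"`, values in
#'   Hounsfield units.
#' @param air_threshold Voxels strictly below this HU value are candidate
#'   lung/air. Default -400 HU.
#' @param min_component_volume Minimum connected-component volume in mL to
#'   count as lung. Default 200 mL.
#' @return A [lung_mask()] on the CT geometry.
#' @examples
#' ct <- array(40, c(12, 12, 12))
#' ct[3:5, 3:10, 3:10] <- -800  # left lung block
#' ct[8:10, 3:10, 3:10] <- -800 # right lung block
#' vol <- uptake_volume(ct, spacing = c(10, 10, 10), modality = "ct")
#' m <- derive_lung_mask_from_ct(vol)
#' sum(m$values) == 2 * 3 * 8 * 8
#' @export
derive_lung_mask_from_ct <- function(ct, air_threshold = -400,
                                     min_component_volume = 200) {
  stopifnot(inherits(ct, "uptake_volume"))
  if (ct$modality != "ct") {
    stop("`ct` must have modality 'ct', got '", ct$modality, "'",
         call. = FALSE)
  }
  fg <- ct$values < air_threshold
  if (!any(fg)) {
    stop("no lung found: no voxels below ", air_threshold, " HU",
         call. = FALSE)
  }
  labels <- label_components_3d(fg)
  dims <- dim(labels)

  # components touching any boundary face are exterior air
  boundary <- unique(c(
    labels[1, , ], labels[dims[1], , ],
    labels[, 1, ], labels[, dims[2], ],
    labels[, , 1], labels[, , dims[3]]))
  boundary <- boundary[boundary > 0L]

  counts <- tabulate(labels[labels > 0L])
  vol_ml <- counts * voxel_volume_ml(ct$spacing)
  keep <- setdiff(which(vol_ml >= min_component_volume), boundary)
  if (length(keep) == 0L) {
    stop("no lung found: no interior component of at least ",
         min_component_volume, " mL below ", air_threshold, " HU",
         call. = FALSE)
  }
  mask <- array(as.double(labels %in% keep), dims)
  lung_mask(mask, spacing = ct$spacing, origin = ct$origin)
}
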