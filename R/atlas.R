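#' Label atlas container
#'
#' An integer-label volume on an MNI-convention grid plus a region map from
#' region names to label sets.  Composite regions `striatum` (caudate plus
#' putamen) and `background` (occipital) are always available.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param region_map named list mapping region name to integer label(s);
#'   must contain `caudate_L`, `caudate_R`, `putamen_L`, `putamen_R`,
#'   `occipital_L`, `occipital_R`.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, affine, region_map) {
  need <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
            "occipital_L", "occipital_R")
  miss <- setdiff(need, names(region_map))
  if (length(miss)) stop("region_map missing: ", paste(miss, collapse = ", "))
  labs <- unlist(region_map)
  present <- labs %in% unique(as.integer(labels))
  if (!all(present))
    stop("labels absent from volume: ", paste(labs[!present], collapse = ", "))
  structure(list(labels = labels, affine = unname(as.matrix(affine)),
                 region_map = region_map),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s, regions: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(names(x$region_map), collapse = ", ")))
  invisible(x)
}

# Resolve a region name (individual, composite, or unsided) to labels.
atlas_labels_for <- function(atlas, region) {
  rm_ <- atlas$region_map
  if (region %in% names(rm_)) return(unlist(rm_[[region]]))
  comp <- switch(region,
    striatum = c("caudate_L", "caudate_R", "putamen_L", "putamen_R"),
    background = ,
    occipital = c("occipital_L", "occipital_R"),
    caudate = c("caudate_L", "caudate_R"),
    putamen = c("putamen_L", "putamen_R"),
    stop("unknown region: ", region))
  unlist(rm_[comp])
}

#' Logical mask of an atlas region
#'
#' @param atlas a [label_atlas()].
#' @param region region name (individual label name, `caudate`, `putamen`,
#'   `occipital`, `striatum`, or `background`).
#' @return logical 3D array.
#' @export
atlas_mask <- function(atlas, region) {
  array(atlas$labels %in% atlas_labels_for(atlas, region), dim(atlas$labels))
}

#' Mean image intensity over atlas regions
#'
#' @param image a [vol_image()] on the identical grid as the atlas.
#' @param atlas a [label_atlas()].
#' @param regions character vector of region names.
#' @param exclude_zeros drop exactly-zero voxels (the out-of-field fill of
#'   reslicing) before averaging; the dropped fraction is returned as an
#'   attribute `dropped`.
#' @return named numeric vector of region means.
#' @export
roi_means <- function(image, atlas, regions, exclude_zeros = FALSE) {
  stopifnot(is_vol(image), inherits(atlas, "label_atlas"))
  if (!identical(dim(image$data), dim(atlas$labels)) ||
      !affines_equal(image$affine, atlas$affine))
    stop("image and atlas are not on the identical grid")
  out <- numeric(length(regions)); names(out) <- regions
  dropped <- numeric(length(regions)); names(dropped) <- regions
  for (rg in regions) {
    m <- atlas_mask(atlas, rg)
    v <- image$data[m]
    if (exclude_zeros) {
      keep <- v != 0
      dropped[rg] <- 1 - mean(keep)
      v <- v[keep]
    }
    if (!length(v))
      stop("region '", rg, "' is empty",
           if (exclude_zeros) " after zero exclusion" else "")
    out[rg] <- mean(v)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read a label atlas from NIfTI labels plus a JSON region map
#'
#' Supports real AAL-style atlases: an integer NIfTI label volume and a JSON
#' object mapping the six required region names to label numbers (scalars or
#' arrays).
#'
#' @param nifti_path integer label volume.
#' @param region_map_path JSON name-to-label map.
#' @export
read_label_atlas <- function(nifti_path, region_map_path) {
  v <- read_volume(nifti_path)
  rm_ <- jsonlite::read_json(region_map_path, simplifyVector = TRUE)
  label_atlas(array(as.integer(round(v$data)), dim(v$data)), v$affine,
              as.list(rm_))
}

#' Write a label atlas (NIfTI labels + JSON region map)
#'
#' @param atlas a [label_atlas()].
#' @param nifti_path,region_map_path output paths.
#' @export
write_label_atlas <- function(atlas, nifti_path, region_map_path) {
  write_volume(vol_image(atlas$labels + 0, atlas$affine, "label atlas"),
               nifti_path)
  jsonlite::write_json(atlas$region_map, region_map_path, auto_unbox = FALSE)
  invisible(c(nifti_path, region_map_path))
}
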