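#' Construct a volume image
#'
#' The universal image carrier: a 3D intensity array plus a 4x4 affine that
#' maps 0-based voxel indices to world coordinates (MNI RAS, millimetres).
#'
#' @param data 3D numeric array (no NaN).
#' @param affine 4x4 numeric matrix, invertible spatial submatrix.
#' @param desc free-text provenance tag.
#' @return An object of class `vol`.
#' @export
vol_image <- function(data, affine, desc = "") {
  if (length(dim(data)) == 4L) {
    if (dim(data)[4] != 1L)
      stop("expected a single 3D frame, got ", dim(data)[4], " frames")
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (anyNA(data)) stop("volume data contains NA/NaN")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine spatial submatrix is singular")
  structure(list(data = data, affine = unname(affine), desc = as.character(desc)),
            class = "vol")
}

#' @export
print.vol <- function(x, ...) {
  d <- dim(x$data)
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<vol> %d x %d x %d, voxel %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3],
              if (nzchar(x$desc)) paste0("  [", x$desc, "]") else ""))
  invisible(x)
}

#' @export
dim.vol <- function(x) dim(x$data)

is_vol <- function(x) inherits(x, "vol")

#' Define a sampling grid from a bounding box
#'
#' Grids use inclusive endpoints: voxel (0,0,0) sits at `bbox_min` and the
#' last voxel at `bbox_max`, so dims = (max - min)/voxel + 1 per axis.  The
#' default is the standard MNI bounding box at 2 mm, which yields the
#' familiar 91 x 109 x 91 normalized grid.
#'
#' @param bbox_min,bbox_max numeric length-3, world mm.
#' @param voxel_size scalar or length-3 mm.
#' @return An object of class `grid_spec` with fields `bbox_min`, `bbox_max`,
#'   `voxel_size`, `dims`, `affine`.
#' @export
grid_spec <- function(bbox_min = c(-90, -126, -72),
                      bbox_max = c(90, 90, 108),
                      voxel_size = 2) {
  bbox_min <- as.numeric(bbox_min); bbox_max <- as.numeric(bbox_max)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  if (any(bbox_max < bbox_min)) stop("bbox_max must be >= bbox_min")
  ext <- bbox_max - bbox_min
  steps <- ext / voxel_size
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("(bbox_max - bbox_min) must be an integer multiple of voxel_size")
  dims <- as.integer(round(steps)) + 1L
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- bbox_min
  structure(list(bbox_min = bbox_min, bbox_max = bbox_max,
                 voxel_size = voxel_size, dims = dims, affine = affine),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> dims %s, voxel %s mm, bbox [%s; %s]\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(x$bbox_min, collapse = " "),
              paste(x$bbox_max, collapse = " ")))
  invisible(x)
}

# Accept a grid_spec or a vol wherever a target grid is needed.
as_grid <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (is_vol(x)) {
    return(structure(list(bbox_min = NULL, bbox_max = NULL, voxel_size = NULL,
                          dims = dim(x$data), affine = x$affine),
                     class = "grid_spec"))
  }
  stop("expected a grid_spec or vol")
}

# World coordinates (N x 4 homogeneous) of every voxel centre of a grid,
# x fastest (R array order).
grid_world_coords <- function(grid) {
  d <- grid$dims
  ii <- rep.int(0:(d[1] - 1L), times = d[2] * d[3])
  jj <- rep.int(rep(0:(d[2] - 1L), each = d[1]), times = d[3])
  kk <- rep(0:(d[3] - 1L), each = d[1] * d[2])
  vox <- cbind(ii, jj, kk, 1)
  vox %*% t(grid$affine)
}

affines_equal <- function(a, b, tol = 1e-4) max(abs(a - b)) <= tol

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file holding a single 3D frame (a 4D
#'   file with one frame is squeezed).
#' @return A [vol_image()] with the affine taken from the header (sform
#'   preferred, qform fallback).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("expected a single 3D frame in ", path, ", got dims ",
           paste(d, collapse = "x"))
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), d)
  } else stop("expected a 3D volume in ", path)
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  vol_image(img2, unclass(xf), desc = basename(path))
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as float32 with the sform set to the volume's affine.
#'
#' @param image a [vol_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(image, path) {
  stopifnot(is_vol(image))
  if (anyNA(image$data)) stop("refusing to write a volume containing NaN")
  nim <- RNifti::asNifti(image$data, datatype = "float")
  RNifti::sform(nim) <- structure(image$affine, code = 2L)
  RNifti::qform(nim) <- structure(image$affine, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

# Sample a volume at continuous 0-based voxel coordinates (N x 3).
sample_vol <- function(image, vox_coords, want_grad = FALSE) {
  c_sample_trilinear(as.numeric(image$data), dim(image$data),
                     vox_coords, want_grad)
}

#' Resample a volume onto a target grid by trilinear interpolation
#'
#' Each output voxel takes the trilinearly interpolated value of `image` at
#' the world location `transform %*% x`, where `x` is the output voxel's
#' world position.  Locations outside the source field of view are filled
#' with 0.
#'
#' @param image source [vol_image()].
#' @param target a `grid_spec` or a `vol` whose grid is used.
#' @param transform 4x4 world-to-world matrix mapping target-world to
#'   source-world coordinates (default identity).
#' @return A [vol_image()] on the target grid.
#' @export
resample_trilinear <- function(image, target, transform = diag(4)) {
  stopifnot(is_vol(image))
  grid <- as_grid(target)
  transform <- as.matrix(transform)
  if (abs(det(transform)) < .Machine$double.eps * 100)
    stop("transform is singular")
  xw <- grid_world_coords(grid)
  src_vox <- xw %*% t(solve(image$affine) %*% transform)
  vals <- sample_vol(image, src_vox[, 1:3, drop = FALSE])
  vol_image(array(vals[, 1], grid$dims), grid$affine, desc = image$desc)
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  # Row-normalized truncated Gaussian: constants are preserved exactly and
  # interior mass to high accuracy (symmetric taps away from the edges).
  if (sigma_vox < 1e-8) return(diag(n))
  r <- min(n - 1L, as.integer(ceiling(4 * sigma_vox)))
  taps <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- taps[ok]
  }
  K / rowSums(K)
}

#' Gaussian smoothing specified in millimetres FWHM
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis, converted to voxel units through the affine.  FWHM 0 is the
#' identity.
#'
#' @param image a [vol_image()].
#' @param fwhm_mm scalar or length-3 FWHM in mm (>= 0).
#' @export
gaussian_smooth <- function(image, fwhm_mm) {
  stopifnot(is_vol(image))
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be >= 0")
  if (all(fwhm_mm == 0)) return(image)
  vs <- sqrt(colSums(image$affine[1:3, 1:3]^2))
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  d <- dim(image$data)
  x <- image$data
  if (sigma_vox[1] > 0) {
    K <- gaussian_kernel_matrix(d[1], sigma_vox[1])
    x <- array(K %*% matrix(x, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- gaussian_kernel_matrix(d[2], sigma_vox[2])
    x <- aperm(array(K %*% matrix(aperm(x, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
               c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- gaussian_kernel_matrix(d[3], sigma_vox[3])
    x <- aperm(array(K %*% matrix(aperm(x, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
               c(2, 3, 1))
  }
  vol_image(x, image$affine, desc = image$desc)
}

#' Voxelwise average of volumes on a common grid
#'
#' @param images list of [vol_image()]s with identical dims and affines
#'   (affines equal to 1e-4 mm).
#' @export
average_volumes <- function(images) {
  if (length(images) < 1L) stop("need at least one image")
  ref <- images[[1]]
  for (im in images) {
    stopifnot(is_vol(im))
    if (!identical(dim(im$data), dim(ref$data)))
      stop("dimension mismatch between volumes")
    if (!affines_equal(im$affine, ref$affine))
      stop("affine mismatch between volumes")
  }
  acc <- Reduce(`+`, lapply(images, function(v) v$data))
  vol_image(acc / length(images), ref$affine,
            desc = sprintf("mean of %d volumes", length(images)))
}
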