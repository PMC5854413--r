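#' Specific uptake ratio
#'
#' SUR = (Target - Background) / Background, where Target and Background
#' are mean intensities of the target (striatum) and background (occipital)
#' regions.  May be negative; a negative value signals that the selected
#' target region holds less activity than the reference, the signature of a
#' failed normalization.
#'
#' @param target_mean,background_mean region mean intensities;
#'   `background_mean` must be > 0.
#' @return scalar SUR.
#' @export
compute_sur <- function(target_mean, background_mean) {
  if (!is.finite(background_mean) || background_mean <= 0)
    stop("background mean must be > 0 (empty reference or failed normalization)")
  (target_mean - background_mean) / background_mean
}

new_sur_result <- function(subject_id, method, target_mean, background_mean,
                           params = NULL) {
  structure(list(subject_id = subject_id, method = method,
                 target_mean = target_mean, background_mean = background_mean,
                 sur = compute_sur(target_mean, background_mean),
                 params = params),
            class = "sur_result")
}

#' @export
print.sur_result <- function(x, ...) {
  cat(sprintf("<sur_result> %s [%s]: target %.4g, background %.4g, SUR %.4f\n",
              x$subject_id, x$method, x$target_mean, x$background_mean, x$sur))
  invisible(x)
}

#' Automatic atlas-driven SUR quantification
#'
#' The automatic ROI path: spatially normalize the image to the tracer
#' template, reslice onto the atlas grid, take mean uptake over the striatum
#' (caudate plus putamen) as target and the occipital region as background,
#' and compute the SUR.  Zero-filled out-of-field voxels are excluded from
#' region means by default so reslicing cannot dilute the occipital
#' reference.
#'
#' @param image native-space tracer [vol_image()].
#' @param template normalization target [vol_image()] (tracer template).
#' @param atlas a [label_atlas()]; the image is resliced onto its grid.
#' @param ctrl a [reg_control()].
#' @param target,background region names passed to [roi_means()].
#' @param exclude_zeros exclude zero-fill voxels from region means.
#' @param subject_id,method labels carried into the result.
#' @return A `sur_result`; the normalization parameters used are attached
#'   as `$params`.
#' @export
auto_quantify <- function(image, template, atlas, ctrl = reg_control(),
                          target = "striatum", background = "background",
                          exclude_zeros = TRUE, subject_id = "subject",
                          method = "auto") {
  stopifnot(inherits(atlas, "label_atlas"))
  params <- normalise_estimate(image, template, ctrl)
  agrid <- structure(list(dims = dim(atlas$labels), affine = atlas$affine),
                     class = "grid_spec")
  norm <- normalise_write(image, params, agrid)
  mns <- roi_means(norm, atlas, c(target, background),
                   exclude_zeros = exclude_zeros)
  new_sur_result(subject_id, method, mns[[target]], mns[[background]],
                 params = params)
}

#' Manual-method emulation: SUR from the summed hottest slices
#'
#' Emulates the conventional manual procedure: rank transverse (z) slices
#' by total in-slice intensity, sum the `n_slices` hottest (ties broken
#' toward the lower slice index) into a single 2D image, apply the target
#' and background masks, and compute the SUR.
#'
#' @param image native-space [vol_image()].
#' @param target_mask,background_mask logical masks, either 2D (applied to
#'   the summed slab) or 3D (collapsed by union over z).
#' @param n_slices number of hottest slices to sum (default 3).
#' @param subject_id label carried into the result.
#' @return A `sur_result` with method `"manual"`; the selected slice
#'   indices are attached as attribute `slices`.
#' @export
manual_slab_quantify <- function(image, target_mask, background_mask,
                                 n_slices = 3, subject_id = "subject") {
  stopifnot(is_vol(image), n_slices >= 1)
  d <- dim(image$data)
  if (n_slices > d[3])
    stop("n_slices (", n_slices, ") exceeds volume depth (", d[3], ")")
  totals <- apply(image$data, 3, sum)
  sel <- order(-totals, seq_along(totals))[seq_len(n_slices)]
  slab <- apply(image$data[, , sel, drop = FALSE], c(1, 2), sum)
  collapse <- function(m, what) {
    if (is.null(dim(m)) || !length(dim(m)) %in% c(2L, 3L))
      stop(what, " must be a 2D or 3D mask")
    if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), any)
    if (!all(dim(m) == d[1:2]))
      stop(what, " in-plane dimensions do not match the image")
    m
  }
  tm <- collapse(target_mask, "target_mask")
  bm <- collapse(background_mask, "background_mask")
  if (!any(tm)) stop("empty target mask")
  if (!any(bm)) stop("empty background mask")
  res <- new_sur_result(subject_id, "manual", mean(slab[tm]), mean(slab[bm]))
  attr(res, "slices") <- sel
  res
}

#' Collect SUR results into a paired table
#'
#' @param results list of `sur_result`s (one `manual` plus one or more
#'   automatic methods per subject).
#' @return data.frame with one row per subject: `subject_id`, `sur_manual`
#'   and one `sur_<method>` column per automatic method.
#' @export
sur_table <- function(results) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(subject_id = r$subject_id, method = r$method, sur = r$sur,
               stringsAsFactors = FALSE)))
  wide <- stats::reshape(df, idvar = "subject_id", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^sur\\.", "sur_", names(wide))
  rownames(wide) <- NULL
  wide
}
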