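#' Build a tracer template by iterative group averaging
#'
#' Two-pass procedure: every input image is spatially normalized to the
#' seed template, resliced onto the target grid and averaged, giving a
#' preliminary template; all original images are then re-normalized to the
#' preliminary template and averaged again.  The final average is smoothed
#' (default 8 mm FWHM).  Subjects whose normalization hard-fails are
#' excluded with a logged reason; the build errors only if all inputs fail.
#'
#' @param images list of native-space [vol_image()]s (>= 1).
#' @param seed_template initial normalization target [vol_image()].
#' @param smooth_fwhm_mm final smoothing, mm FWHM.
#' @param passes number of normalization passes (default 2; 1 stops at the
#'   preliminary template).
#' @param grid output [grid_spec()].
#' @param ctrl a [reg_control()].
#' @return list with `template` ([vol_image()]) and `report`
#'   (`template_report`).
#' @export
build_template_iterative <- function(images, seed_template, smooth_fwhm_mm = 8,
                                     passes = 2, grid = grid_spec(),
                                     ctrl = reg_control()) {
  stopifnot(length(images) >= 1, passes >= 1)
  grid <- as_grid(grid)
  target <- seed_template
  subjects <- NULL
  avg <- NULL
  for (pass in seq_len(passes)) {
    written <- list()
    subjects <- vector("list", length(images))
    for (i in seq_along(images)) {
      res <- tryCatch({
        params <- normalise_estimate(images[[i]], target, ctrl)
        w <- normalise_write(images[[i]], params, grid)
        list(ok = TRUE, converged = params$converged, vol = w, reason = NA)
      }, error = function(e) list(ok = FALSE, converged = FALSE, vol = NULL,
                                  reason = conditionMessage(e)))
      subjects[[i]] <- list(index = i, ok = res$ok, converged = res$converged,
                            reason = res$reason)
      if (res$ok) written[[length(written) + 1L]] <- res$vol
    }
    if (!length(written))
      stop("all inputs failed normalization in pass ", pass)
    avg <- average_volumes(written)
    target <- avg  # pass 2+ re-normalizes to the preliminary template
  }
  tpl <- gaussian_smooth(avg, smooth_fwhm_mm)
  tpl$desc <- "iterative tracer template"
  report <- structure(list(mode = "iterative", n_inputs = length(images),
                           passes = passes, smooth_fwhm_mm = smooth_fwhm_mm,
                           subjects = subjects, grid_dims = grid$dims),
                      class = "template_report")
  list(template = tpl, report = report)
}

#' Build a tracer template by MRI-indirect parameter transfer
#'
#' Per pair: rigidly coregister the tracer image to its T1; estimate the
#' normalization of the T1 to the T1 template; apply those parameters to
#' the coregistered tracer image ("parameter transfer").  All normalized
#' tracer images are averaged and smoothed.
#'
#' @param pairs list of `list(spect = vol, t1 = vol)` pairs (>= 1), each
#'   anatomically co-located up to a rigid offset.
#' @param t1_template anatomical normalization target [vol_image()].
#' @inheritParams build_template_iterative
#' @return list with `template` and `report`.
#' @export
build_template_indirect <- function(pairs, t1_template, smooth_fwhm_mm = 8,
                                    grid = grid_spec(), ctrl = reg_control()) {
  stopifnot(length(pairs) >= 1)
  grid <- as_grid(grid)
  written <- list()
  subjects <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    res <- tryCatch({
      pr <- pairs[[i]]
      co <- coregister_rigid(pr$spect, pr$t1, ctrl = ctrl)
      spect_in_t1 <- resample_trilinear(pr$spect, pr$t1,
                                        transform = affine_matrix(co$params))
      params <- normalise_estimate(pr$t1, t1_template, ctrl)
      w <- normalise_write(spect_in_t1, params, grid)
      list(ok = TRUE, converged = params$converged, vol = w, reason = NA)
    }, error = function(e) list(ok = FALSE, converged = FALSE, vol = NULL,
                                reason = conditionMessage(e)))
    subjects[[i]] <- list(index = i, ok = res$ok, converged = res$converged,
                          reason = res$reason)
    if (res$ok) written[[length(written) + 1L]] <- res$vol
  }
  if (!length(written)) stop("all pairs failed the indirect normalization")
  tpl <- gaussian_smooth(average_volumes(written), smooth_fwhm_mm)
  tpl$desc <- "MRI-indirect tracer template"
  report <- structure(list(mode = "indirect", n_inputs = length(pairs),
                           passes = 1L, smooth_fwhm_mm = smooth_fwhm_mm,
                           subjects = subjects, grid_dims = grid$dims),
                      class = "template_report")
  list(template = tpl, report = report)
}

#' @export
print.template_report <- function(x, ...) {
  ok <- vapply(x$subjects, function(s) isTRUE(s$ok), logical(1))
  cat(sprintf("<template_report> mode %s: %d/%d inputs used, %d pass(es), %g mm smoothing\n",
              x$mode, sum(ok), x$n_inputs, x$passes, x$smooth_fwhm_mm))
  for (s in x$subjects[!ok])
    cat(sprintf("  excluded input %d: %s\n", s$index, s$reason))
  invisible(x)
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return 2|A n B| / (|A| + |B|); 1 if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
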