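#' Rigid (6-parameter) coregistration
#'
#' Estimates the rigid transform aligning a source image to a reference
#' image, by default maximizing normalized mutual information (NMI,
#' 64 x 64-bin joint histogram with linear partial-volume binning) under a
#' derivative-free simplex search, with zooms fixed at 1 and shears at 0.
#' Intended for multimodal pairs (SPECT to T1); `metric = "msd"` minimizes
#' the mean squared difference with a profiled global scale for
#' same-modality use.
#'
#' The returned parameters map reference-world coordinates to source-world
#' coordinates: `source(affine_matrix(params) %*% x)` is aligned with
#' `reference(x)`.
#'
#' @param source,reference [vol_image()]s.
#' @param metric `"nmi"` (default) or `"msd"`.
#' @param ctrl a [reg_control()]; the smoothing ladder and working voxel
#'   size are reused.
#' @param bins joint-histogram bins per axis for NMI.
#' @return list with `params` ([affine_params()], rigid), `metric_value`,
#'   `metric`.
#' @export
coregister_rigid <- function(source, reference, metric = c("nmi", "msd"),
                             ctrl = reg_control(), bins = 64L) {
  metric <- match.arg(metric)
  stopifnot(is_vol(source), is_vol(reference))
  if (sd(source$data) == 0 || sd(reference$data) == 0)
    stop("degenerate (constant) image: coregistration metric is undefined")
  wg <- working_grid(reference, ctrl$working_voxel)
  xw_all <- grid_world_coords(wg)
  inv_src_aff <- solve(source$affine)
  par <- rep(0, 6)
  value <- NA_real_
  for (fwhm in ctrl$fwhm_ladder) {
    ref_w <- resample_trilinear(gaussian_smooth(reference, fwhm), wg)
    rv_all <- as.vector(ref_w$data)
    mask <- which(rv_all > ctrl$mask_thresh * max(rv_all))
    mask <- mask[seq(1L, length(mask), by = 2L)]  # decimate for speed
    rv <- rv_all[mask]
    xw <- xw_all[mask, , drop = FALSE]
    src_s <- gaussian_smooth(source, fwhm)
    # fix the joint-histogram binning for the whole rung: shared range from
    # the reference values and the source sampled at the starting estimate
    # (identical images then bin to an exact histogram diagonal at identity)
    M0 <- affine_matrix(rigid_params(par[1:3], par[4:6]))
    sv0 <- sample_vol(src_s, (xw %*% t(inv_src_aff %*% M0))[, 1:3,
                                                            drop = FALSE])[, 1]
    rng <- range(rv, sv0)
    objective <- function(par) {
      M <- affine_matrix(rigid_params(par[1:3], par[4:6]))
      vox <- xw %*% t(inv_src_aff %*% M)
      sv <- sample_vol(src_s, vox[, 1:3, drop = FALSE])[, 1]
      if (metric == "nmi") {
        -nmi_histogram(rv, sv, bins = bins, a_range = rng, b_range = rng)
      } else {
        s <- profile_scale(rv, sv)
        mean((rv - s * sv)^2)
      }
    }
    opt <- stats::optim(par, objective, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-9,
                                       parscale = c(2, 2, 2, 0.02, 0.02, 0.02)))
    par <- opt$par
    value <- opt$value
  }
  list(params = rigid_params(par[1:3], par[4:6]),
       metric_value = if (metric == "nmi") -value else value,
       metric = metric)
}

#' Normalized mutual information of two intensity samples
#'
#' NMI = (H(A) + H(B)) / H(A, B) from a nearest-bin joint histogram.  Hard
#' binning makes NMI attain its exact maximum for identical samples (the
#' joint histogram is then strictly diagonal), so coregistering an image to
#' itself returns the exact identity.
#'
#' @param a,b numeric vectors of paired samples.
#' @param bins bins per axis.
#' @param a_range,b_range fixed binning ranges (defaults to sample range).
#' @return scalar NMI (>= 1 in the usual convention).
#' @export
nmi_histogram <- function(a, b, bins = 64L, a_range = range(a),
                          b_range = range(b)) {
  stopifnot(length(a) == length(b))
  bins <- as.integer(bins)
  ia <- floor((a - a_range[1]) /
                max(a_range[2] - a_range[1], .Machine$double.xmin) * bins)
  ib <- floor((b - b_range[1]) /
                max(b_range[2] - b_range[1], .Machine$double.xmin) * bins)
  ia <- pmin(pmax(ia, 0), bins - 1L)
  ib <- pmin(pmax(ib, 0), bins - 1L)
  h <- tabulate(ia + bins * ib + 1L, nbins = bins * bins)
  p <- h / sum(h)
  pm <- matrix(p, bins, bins)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hab <- ent(p)
  if (hab <= 0) return(1)
  (ent(rowSums(pm)) + ent(colSums(pm))) / hab
}
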