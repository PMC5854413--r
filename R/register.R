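#' Registration control settings
#'
#' Numerical settings for spatial normalization and rigid coregistration.
#' Defaults follow the normalization configuration used throughout the
#' package: 12-parameter affine estimated by damped Gauss-Newton on the mean
#' squared difference (MSD) with a jointly profiled global intensity scale,
#' followed by a regularized 7 x 9 x 7 discrete-cosine (DCT) warp.
#'
#' @param fwhm_ladder coarse-to-fine working smoothing, mm FWHM.
#' @param working_voxel working grid resolution for the affine stage, mm.
#' @param max_iter total affine Gauss-Newton iteration cap.
#' @param tol_obj relative objective-change convergence tolerance.
#' @param tol_step parameter-step convergence tolerance.
#' @param mask_thresh template mask threshold, fraction of template maximum.
#' @param nonlinear run the DCT warp stage after the affine.
#' @param nl_iter outer iterations of the nonlinear stage.
#' @param nl_voxel working grid resolution for the nonlinear stage, mm.
#' @param nl_reg nonlinear regularization weight (lambda); the quadratic
#'   penalty is frequency-weighted (membrane-like) and internally scaled by
#'   `nl_reg_scale` times the masked template second moment so that
#'   `nl_reg = 1` is a usable default.
#' @param nl_reg_scale internal scaling constant of the penalty.
#' @param cutoff_mm DCT cutoff wavelength; the per-axis basis order is
#'   `round(FOV / cutoff_mm)`, giving 7 x 9 x 7 on the default MNI bounding
#'   box at 25 mm.
#' @param verbose print per-iteration objective values.
#' @return A list of class `reg_control`.
#' @export
reg_control <- function(fwhm_ladder = c(8, 4), working_voxel = 4,
                        max_iter = 32, tol_obj = 1e-5, tol_step = 1e-4,
                        mask_thresh = 0.05, nonlinear = TRUE, nl_iter = 16,
                        nl_voxel = 8, nl_reg = 1, nl_reg_scale = 0.02,
                        cutoff_mm = 25, verbose = FALSE) {
  structure(list(fwhm_ladder = fwhm_ladder, working_voxel = working_voxel,
                 max_iter = max_iter, tol_obj = tol_obj, tol_step = tol_step,
                 mask_thresh = mask_thresh, nonlinear = nonlinear,
                 nl_iter = nl_iter, nl_voxel = nl_voxel, nl_reg = nl_reg,
                 nl_reg_scale = nl_reg_scale, cutoff_mm = cutoff_mm,
                 verbose = verbose),
            class = "reg_control")
}

# A working grid covering (a superset of) the template bounding box at the
# requested resolution, endpoints snapped outward to keep steps integral.
working_grid <- function(tpl_grid, voxel) {
  g <- as_grid(tpl_grid)
  bmin <- g$affine[1:3, 4]
  span <- abs(g$affine[1:3, 1:3] %*% (g$dims - 1))
  bmax <- bmin + as.numeric(span)
  lo <- pmin(bmin, bmax); hi <- pmax(bmin, bmax)
  n <- pmax(1L, as.integer(floor((hi - lo) / voxel)))
  grid_spec(lo, lo + n * voxel, voxel)
}

# Shared setup for the MSD stages: working template values, head mask and
# the masked world coordinates.
msd_working <- function(template, ctrl, voxel) {
  wg <- working_grid(template, voxel)
  xw <- grid_world_coords(wg)
  list(grid = wg, xw = xw)
}

sample_source_msd <- function(src_s, inv_src_affine, M, xw, displacement = NULL) {
  if (is.null(displacement)) {
    vox <- xw %*% t(inv_src_affine %*% M)
  } else {
    y <- xw
    y[, 1:3] <- y[, 1:3] + displacement
    vox <- y %*% t(inv_src_affine %*% M)
  }
  sample_vol(src_s, vox[, 1:3, drop = FALSE], want_grad = TRUE)
}

profile_scale <- function(tpl_vals, src_vals) {
  den <- sum(src_vals^2)
  if (den < .Machine$double.eps) return(0)
  sum(tpl_vals * src_vals) / den
}

#' Estimate a 12-parameter affine normalization
#'
#' Minimizes the mean squared difference between a template and an
#' intensity-scaled, affinely resampled source image,
#' sum over template voxels of (template - s * source(M_p x))^2, by damped
#' Gauss-Newton with analytic image-gradient Jacobians and a jointly
#' profiled global scale `s`.  A coarse-to-fine working-smoothing ladder
#' (default 8 mm then 4 mm) is applied to both images; the objective trace
#' over accepted iterations is non-increasing within each rung.
#'
#' @param source,template [vol_image()]s.
#' @param ctrl a [reg_control()].
#' @param init optional initial [affine_params()].
#' @return list with `params` ([affine_params()]), `scale`, `objective`,
#'   `trace` (accepted objective values per rung), `converged`.
#' @export
estimate_affine <- function(source, template, ctrl = reg_control(),
                            init = affine_params()) {
  stopifnot(is_vol(source), is_vol(template))
  if (sd(source$data) == 0 || sd(template$data) == 0)
    stop("degenerate (constant) image: affine estimation is undefined")
  ws <- msd_working(template, ctrl, ctrl$working_voxel)
  inv_src_aff <- solve(source$affine)
  p <- as.numeric(init)
  s <- 1
  traces <- list()
  converged <- FALSE
  iter_budget <- ctrl$max_iter

  for (fwhm in ctrl$fwhm_ladder) {
    tpl_s <- gaussian_smooth(template, fwhm)
    tpl_w <- resample_trilinear(tpl_s, ws$grid)
    mask <- as.vector(tpl_w$data) > ctrl$mask_thresh * max(tpl_w$data)
    if (!any(mask)) stop("empty template mask; lower mask_thresh")
    t_vals <- as.vector(tpl_w$data)[mask]
    xw <- ws$xw[mask, , drop = FALSE]
    src_s <- gaussian_smooth(source, fwhm)

    eval_at <- function(p) {
      samp <- sample_source_msd(src_s, inv_src_aff, affine_matrix(p), xw)
      s <- profile_scale(t_vals, samp[, 1])
      r <- t_vals - s * samp[, 1]
      list(f = mean(r^2), s = s, samp = samp, r = r)
    }

    cur <- eval_at(p)
    trace <- cur$f
    lam <- 1e-3
    it <- 0
    while (it < iter_budget) {
      it <- it + 1
      g <- cur$samp[, 2:4, drop = FALSE]
      dM <- affine_matrix_grad(p)
      n <- nrow(xw)
      J <- matrix(0, n, 12L)
      A <- inv_src_aff[1:3, 1:3]
      for (k in 1:12) {
        Dk <- xw %*% t(A %*% dM[[k]][1:3, , drop = FALSE])
        J[, k] <- -cur$s * rowSums(g * Dk)
      }
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, cur$r)
      accepted <- FALSE
      for (try in 1:8) {
        H <- JtJ + lam * diag(diag(JtJ) + 1e-12)
        delta <- tryCatch(solve(H, -Jtr), error = function(e) NULL)
        if (is.null(delta)) { lam <- lam * 10; next }
        p_new <- p + as.numeric(delta)
        if (any(p_new[7:9] <= 0.05)) { lam <- lam * 10; next }
        cand <- eval_at(p_new)
        if (cand$f <= cur$f) {
          rel <- (cur$f - cand$f) / max(cur$f, .Machine$double.eps)
          step <- max(abs(delta))
          p <- p_new; cur <- cand
          trace <- c(trace, cand$f)
          lam <- max(lam / 3, 1e-8)
          accepted <- TRUE
          if (ctrl$verbose) message(sprintf("  affine it %d f=%.6g", it, cur$f))
          if (rel < ctrl$tol_obj || step < ctrl$tol_step) converged <- TRUE
          break
        }
        lam <- lam * 10
      }
      if (!accepted || converged) break
    }
    iter_budget <- iter_budget - it
    traces[[as.character(fwhm)]] <- trace
    s <- cur$s
    if (iter_budget <= 0) break
  }
  list(params = as_affine_params(p), scale = s,
       objective = trace[length(trace)], trace = traces,
       converged = converged)
}

# Continuous low-frequency cosine basis over [0, 1]: phi_0 = 1,
# phi_q(u) = sqrt(2) cos(pi q u).  Grid-independent, so coefficients
# estimated on a coarse working grid apply exactly on any output grid.
dct_basis_1d <- function(u, order) {
  B <- matrix(1, length(u), order)
  if (order > 1L)
    for (q in 1:(order - 1L)) B[, q + 1L] <- sqrt(2) * cos(pi * q * u)
  B
}

dct_orders <- function(tpl_grid, cutoff_mm) {
  g <- as_grid(tpl_grid)
  bmin <- g$affine[1:3, 4]
  fov <- abs(as.numeric(g$affine[1:3, 1:3] %*% (g$dims - 1)))
  pmax(1L, as.integer(round(fov / cutoff_mm)))
}

# Full separable basis (N x prod(orders)) for axis-aligned grid world
# coordinates; rows follow the x-fastest voxel order of `keep`.
dct_basis_grid <- function(grid, orders, bbox_min, fov, keep = NULL) {
  g <- as_grid(grid)
  d <- g$dims
  ax <- lapply(1:3, function(a) {
    lev <- g$affine[a, 4] + g$affine[a, a] * (0:(d[a] - 1L))
    dct_basis_1d((lev - bbox_min[a]) / fov[a], orders[a])
  })
  ii <- rep.int(seq_len(d[1]), times = d[2] * d[3])
  jj <- rep.int(rep(seq_len(d[2]), each = d[1]), times = d[3])
  kk <- rep(seq_len(d[3]), each = d[1] * d[2])
  if (!is.null(keep)) { ii <- ii[keep]; jj <- jj[keep]; kk <- kk[keep] }
  Bx <- ax[[1]][ii, , drop = FALSE]
  By <- ax[[2]][jj, , drop = FALSE]
  Bz <- ax[[3]][kk, , drop = FALSE]
  n <- length(ii)
  B <- matrix(0, n, prod(orders))
  col <- 0L
  for (qz in seq_len(orders[3])) for (qy in seq_len(orders[2]))
    for (qx in seq_len(orders[1])) {
      col <- col + 1L
      B[, col] <- Bx[, qx] * By[, qy] * Bz[, qz]
    }
  B
}

# Membrane-like frequency weights per basis function (mm^-2 scale):
# pi^2 (qx^2/Lx^2 + qy^2/Ly^2 + qz^2/Lz^2).
dct_penalty_weights <- function(orders, fov) {
  w <- numeric(prod(orders))
  col <- 0L
  for (qz in seq_len(orders[3])) for (qy in seq_len(orders[2]))
    for (qx in seq_len(orders[1])) {
      col <- col + 1L
      w[col] <- pi^2 * ((qx - 1)^2 / fov[1]^2 + (qy - 1)^2 / fov[2]^2 +
                          (qz - 1)^2 / fov[3]^2)
    }
  # the constant component is redundant with the affine translations;
  # regularize it at the lowest nonzero frequency weight so the penalty is
  # positive definite and the large-lambda limit collapses every coefficient
  w[w == 0] <- min(w[w > 0])
  w
}

#' Estimate the DCT nonlinear warp
#'
#' Regularized Gauss-Newton updates of the discrete-cosine displacement
#' coefficients, minimizing MSD plus `lambda` times a frequency-weighted
#' quadratic penalty (membrane-like energy) on the coefficients.  The warp
#' acts in template world space: the source is sampled at
#' `M_affine (x + d(x))` with `d(x) = sum_k c_k phi_k(x)` in mm.
#'
#' @param source,template [vol_image()]s.
#' @param affine the previously estimated [affine_params()].
#' @param n_iter outer iterations (default 16).
#' @param lambda regularization weight (default 1).
#' @param ctrl a [reg_control()].
#' @return list with `coef` (n_basis x 3 matrix, mm), `orders`, `bbox_min`,
#'   `fov`, `scale`, `trace`, `converged`.
#' @export
estimate_nonlinear <- function(source, template, affine, n_iter = 16,
                               lambda = 1, ctrl = reg_control()) {
  stopifnot(is_vol(source), is_vol(template))
  g <- as_grid(template)
  orders <- dct_orders(g, ctrl$cutoff_mm)
  bmin <- g$affine[1:3, 4]
  fov <- abs(as.numeric(g$affine[1:3, 1:3] %*% (g$dims - 1)))
  nb <- prod(orders)
  out0 <- list(coef = matrix(0, nb, 3), orders = orders, bbox_min = bmin,
               fov = fov, scale = 1, trace = numeric(), converged = TRUE)
  if (n_iter <= 0) return(out0)

  fwhm <- ctrl$fwhm_ladder[length(ctrl$fwhm_ladder)]
  wg <- working_grid(template, ctrl$nl_voxel)
  tpl_w <- resample_trilinear(gaussian_smooth(template, fwhm), wg)
  mask <- as.vector(tpl_w$data) > ctrl$mask_thresh * max(tpl_w$data)
  if (!any(mask)) stop("empty template mask; lower mask_thresh")
  t_vals <- as.vector(tpl_w$data)[mask]
  xw <- grid_world_coords(wg)[mask, , drop = FALSE]
  src_s <- gaussian_smooth(source, fwhm)
  inv_src_aff <- solve(source$affine)
  M <- affine_matrix(affine)
  B <- dct_basis_grid(wg, orders, bmin, fov, keep = mask)
  w_pen <- dct_penalty_weights(orders, fov)
  n <- length(t_vals)
  alpha <- lambda * ctrl$nl_reg_scale * n * mean(t_vals^2)
  pen <- rep(alpha * w_pen, 3L)

  C <- matrix(0, nb, 3)
  eval_at <- function(C) {
    D <- B %*% C
    samp <- sample_source_msd(src_s, inv_src_aff, M, xw, displacement = D)
    s <- profile_scale(t_vals, samp[, 1])
    r <- t_vals - s * samp[, 1]
    cvec <- as.numeric(C)
    list(f = mean(r^2) + sum(pen * cvec^2) / n, s = s, samp = samp, r = r)
  }
  cur <- eval_at(C)
  trace <- cur$f
  lam <- 1e-3
  converged <- FALSE
  Klin <- (inv_src_aff %*% M)[1:3, 1:3]
  for (it in seq_len(n_iter)) {
    h <- (cur$samp[, 2:4, drop = FALSE] %*% Klin) * cur$s
    W1 <- B * h[, 1]; W2 <- B * h[, 2]; W3 <- B * h[, 3]
    W <- cbind(W1, W2, W3)
    JtJ <- crossprod(W)
    Jtr <- -crossprod(W, cur$r)
    cvec <- as.numeric(C)
    grad <- Jtr + pen * cvec
    accepted <- FALSE
    for (try in 1:8) {
      H <- JtJ + diag(pen) + lam * diag(diag(JtJ) + 1e-8)
      delta <- tryCatch(solve(H, -grad), error = function(e) {
        warning("ill-conditioned normal equations; ridge-stabilized solve")
        solve(H + diag(nrow(H)) * 1e-6 * mean(diag(H)), -grad)
      })
      C_new <- C + matrix(delta, nb, 3)
      cand <- eval_at(C_new)
      if (cand$f <= cur$f) {
        rel <- (cur$f - cand$f) / max(cur$f, .Machine$double.eps)
        C <- C_new; cur <- cand
        trace <- c(trace, cand$f)
        lam <- max(lam / 3, 1e-8)
        accepted <- TRUE
        if (ctrl$verbose) message(sprintf("  nl it %d f=%.6g", it, cur$f))
        if (rel < ctrl$tol_obj) converged <- TRUE
        break
      }
      lam <- lam * 10
    }
    if (!accepted || converged) break
  }
  list(coef = C, orders = orders, bbox_min = bmin, fov = fov, scale = cur$s,
       trace = trace, converged = converged || n_iter == 0)
}

#' Estimate full spatial-normalization parameters
#'
#' Affine estimation followed (unless disabled in `ctrl`) by the DCT warp;
#' no spatial weighting of source or template is applied.
#'
#' @inheritParams estimate_affine
#' @return An object of class `norm_params`: affine parameters, global
#'   intensity scale, optional warp, grids and objective traces.
#' @export
normalise_estimate <- function(source, template, ctrl = reg_control()) {
  af <- estimate_affine(source, template, ctrl)
  warp <- NULL
  if (isTRUE(ctrl$nonlinear)) {
    warp <- estimate_nonlinear(source, template, af$params,
                               n_iter = ctrl$nl_iter, lambda = ctrl$nl_reg,
                               ctrl = ctrl)
  }
  tg <- as_grid(template)
  structure(list(affine = af$params,
                 intensity_scale = if (is.null(warp)) af$scale else warp$scale,
                 warp = warp,
                 template_grid = list(dims = tg$dims, affine = tg$affine),
                 source_grid = list(dims = dim(source$data),
                                    affine = source$affine),
                 trace_affine = af$trace,
                 converged = af$converged),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat("<norm_params>\n  ")
  print(x$affine)
  cat(sprintf("  intensity scale %.4g; nonlinear: %s; converged: %s\n",
              x$intensity_scale,
              if (is.null(x$warp)) "none"
              else paste(x$warp$orders, collapse = "x"),
              x$converged))
  invisible(x)
}

#' Apply normalization parameters and reslice onto a grid
#'
#' Resamples the image through the estimated affine (and warp, if present)
#' onto the requested grid with trilinear interpolation.  Intensities are
#' NOT modulated by the local volume change ("preserve concentrations" off):
#' values are interpolated, never rescaled by the Jacobian.
#'
#' @param image source [vol_image()].
#' @param params a `norm_params` from [normalise_estimate()].
#' @param grid target [grid_spec()] (default: MNI bounding box at 2 mm).
#' @return The normalized [vol_image()] on `grid`.
#' @export
normalise_write <- function(image, params, grid = grid_spec()) {
  stopifnot(is_vol(image), inherits(params, "norm_params"))
  grid <- as_grid(grid)
  xw <- grid_world_coords(grid)
  if (!is.null(params$warp) && any(params$warp$coef != 0)) {
    B <- dct_basis_grid(grid, params$warp$orders, params$warp$bbox_min,
                        params$warp$fov)
    xw[, 1:3] <- xw[, 1:3] + B %*% params$warp$coef
  }
  M <- affine_matrix(params$affine)
  vox <- xw %*% t(solve(image$affine) %*% M)
  vals <- sample_vol(image, vox[, 1:3, drop = FALSE])
  vol_image(array(vals[, 1], grid$dims), grid$affine,
            desc = paste0(image$desc, " [normalized]"))
}

#' Serialize normalization parameters to JSON
#'
#' The persisted file holds the affine parameter vector, the warp
#' coefficient tensor (column order: basis index x component), grids and
#' intensity scale; [read_norm_params()] restores a `norm_params` whose
#' application is identical to the original.
#'
#' @param params a `norm_params`.
#' @param path output JSON path.
#' @export
write_norm_params <- function(params, path) {
  stopifnot(inherits(params, "norm_params"))
  obj <- list(affine = as.numeric(params$affine),
              intensity_scale = params$intensity_scale,
              template_grid = params$template_grid,
              source_grid = params$source_grid,
              converged = params$converged)
  if (!is.null(params$warp)) {
    obj$warp <- list(coef = params$warp$coef, orders = params$warp$orders,
                     bbox_min = params$warp$bbox_min, fov = params$warp$fov)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  warp <- NULL
  if (!is.null(obj$warp)) {
    warp <- list(coef = matrix(as.numeric(obj$warp$coef),
                               ncol = 3),
                 orders = as.integer(obj$warp$orders),
                 bbox_min = as.numeric(obj$warp$bbox_min),
                 fov = as.numeric(obj$warp$fov),
                 scale = obj$intensity_scale)
  }
  structure(list(affine = as_affine_params(obj$affine),
                 intensity_scale = obj$intensity_scale,
                 warp = warp,
                 template_grid = list(dims = as.integer(obj$template_grid$dims),
                                      affine = matrix(as.numeric(unlist(obj$template_grid$affine)), 4, 4)),
                 source_grid = list(dims = as.integer(obj$source_grid$dims),
                                    affine = matrix(as.numeric(unlist(obj$source_grid$affine)), 4, 4)),
                 converged = obj$converged),
            class = "norm_params")
}
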