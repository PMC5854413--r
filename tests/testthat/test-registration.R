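test_that("affine parameter vector maps to the stated matrix composition", {
  expect_equal(affine_matrix(affine_params()), diag(4))
  # zoom acts on coordinates before translation
  p <- affine_params(tx = 5, zx = 2)
  expect_equal(as.numeric(affine_matrix(p) %*% c(1, 0, 0, 1)), c(7, 0, 0, 1))
  # rotation matrices are orthonormal; full matrix invertible
  p2 <- affine_params(rx = 0.3, ry = -0.2, rz = 0.5)
  R <- affine_matrix(p2)[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_error(affine_params(zx = -1), "> 0")
})

test_that("affine estimation: identity case returns identity parameters", {
  tpl <- make_matched_template(grid4())
  fit <- estimate_affine(tpl, tpl)
  p <- as.numeric(fit$params)
  expect_true(all(abs(p[1:3]) <= 0.5))
  expect_true(all(abs(p[4:6]) <= 0.005))
  expect_true(all(abs(p[7:9] - 1) <= 0.005))
  expect_true(fit$converged)
  expect_error(estimate_affine(vol_image(array(1, c(8, 8, 8)), diag(4)), tpl),
               "constant")
})

test_that("affine estimation recovers known transforms on noiseless subjects", {
  g <- grid4()
  base <- clean_subject_spec(psf_fwhm_mm = 8)
  ref <- make_synthetic_subject(base, g)$spect
  set.seed(14)
  for (case in 1:3) {
    mis <- list(t = runif(3, -10, 10), r = runif(3, -0.1, 0.1),
                z = runif(3, 0.96, 1.04))
    sp <- base; sp$misalignment <- mis
    sub <- make_synthetic_subject(sp, g)
    fit <- estimate_affine(sub$spect, ref)
    p <- as.numeric(fit$params)
    expect_true(all(abs(p[1:3] - mis$t) < 1))
    expect_true(all(abs(p[4:6] - mis$r) < 0.01))
    expect_true(all(abs(p[7:9] - mis$z) < 0.01))
    # accepted-iteration objective trace is monotone non-increasing
    for (tr in fit$trace) expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("DCT warp basics: orders from cutoff, identity, zero iterations", {
  expect_identical(datspect:::dct_orders(grid2(), 25), c(7L, 9L, 7L))
  expect_identical(datspect:::dct_orders(grid4(), 25), c(7L, 9L, 7L))
  tpl <- make_matched_template(grid4())
  z <- estimate_nonlinear(tpl, tpl, affine_params(), n_iter = 0)
  expect_true(all(z$coef == 0))
  nl <- estimate_nonlinear(tpl, tpl, affine_params(), n_iter = 4)
  expect_lt(max(abs(nl$coef)), 1e-3)
})

test_that("infinite regularization collapses the warp to pure affine", {
  g <- grid4()
  tpl <- make_matched_template(g)
  sub <- make_synthetic_subject(clean_subject_spec(
    misalignment = list(t = c(5, 0, -3), r = c(0, 0.04, 0),
                        z = c(1.02, 1, 0.98))), g)
  af <- estimate_affine(sub$spect, tpl)
  free <- estimate_nonlinear(sub$spect, tpl, af$params, n_iter = 4)
  stiff <- estimate_nonlinear(sub$spect, tpl, af$params, n_iter = 4,
                              lambda = 1e9)
  expect_lt(max(abs(stiff$coef)), 1e-2 * max(max(abs(free$coef)), 1))
})

test_that("a smooth low-frequency warp is recovered by the DCT stage", {
  g <- grid4()
  tpl <- make_matched_template(g)
  orders <- c(7L, 9L, 7L)
  set.seed(7)
  C <- matrix(0, prod(orders), 3)
  idx <- c(2, 3, 8, 9, 50)  # low-frequency components only, ~2 mm amplitude
  for (k in 1:3) C[idx, k] <- runif(5, -2, 2)
  p0 <- structure(list(affine = affine_params(), intensity_scale = 1,
                       warp = list(coef = C, orders = orders,
                                   bbox_min = g$bbox_min,
                                   fov = g$bbox_max - g$bbox_min),
                       template_grid = NULL, source_grid = NULL,
                       converged = TRUE), class = "norm_params")
  warped <- normalise_write(tpl, p0, g)
  af <- estimate_affine(warped, tpl)
  nl <- estimate_nonlinear(warped, tpl, af$params)
  expect_lt(utils::tail(nl$trace, 1), 0.2 * af$objective)
  expect_true(all(diff(nl$trace) <= 1e-12))
})

test_that("normalise_write honors the grid and the no-modulation contract", {
  g4 <- grid4()
  tpl <- make_matched_template(g4)
  id <- normalise_estimate(tpl, tpl, reg_control(nonlinear = FALSE))
  out <- normalise_write(tpl, id, grid_spec())
  expect_identical(dim(out$data), c(91L, 109L, 91L))
  same <- normalise_write(tpl, id, g4)
  expect_lt(max(abs(same$data - tpl$data)), 1e-6)

  # any warp leaves a uniform image uniform away from the volume edge
  ones <- vol_image(array(1, g4$dims), g4$affine)
  set.seed(21)
  C <- matrix(0, prod(c(7, 9, 7)), 3); C[2:10, ] <- runif(27, -3, 3)
  pw <- structure(list(affine = affine_params(), intensity_scale = 1,
                       warp = list(coef = C, orders = c(7L, 9L, 7L),
                                   bbox_min = g4$bbox_min,
                                   fov = g4$bbox_max - g4$bbox_min),
                       template_grid = NULL, source_grid = NULL,
                       converged = TRUE), class = "norm_params")
  w <- normalise_write(ones, pw, g4)
  core <- w$data[10:37, 10:46, 10:37]
  expect_equal(range(core), c(1, 1))
})

test_that("normalization parameters survive a JSON round trip", {
  g <- grid4()
  tpl <- make_matched_template(g)
  sub <- make_synthetic_subject(clean_subject_spec(
    misalignment = list(t = c(6, -4, 2), r = c(0.05, -0.03, 0.08),
                        z = c(1.04, 0.98, 1.02))), g)
  params <- normalise_estimate(sub$spect, tpl, reg_control(nl_iter = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_params(params, path)
  params2 <- read_norm_params(path)
  w1 <- normalise_write(sub$spect, params, g)
  w2 <- normalise_write(sub$spect, params2, g)
  expect_lt(max(abs(w1$data - w2$data)), 1e-6)
})

test_that("rigid coregistration: identity, recovery, metric improvement", {
  g <- grid4()
  sub <- make_synthetic_subject(subject_spec(
    misalignment = list(t = c(4, -6, 3), r = c(0.04, 0.02, -0.06),
                        z = c(1, 1, 1)),
    psf_fwhm_mm = 0, noise = noise_none()), g)

  id <- coregister_rigid(sub$t1, sub$t1)
  expect_lt(max(abs(as.numeric(id$params)[1:6])), 0.15)

  co <- coregister_rigid(sub$spect, sub$t1)
  truth <- as.numeric(sub$ground_truth$spect_t1_offset)
  expect_true(all(abs(as.numeric(co$params)[1:3] - truth[1:3]) < 1))
  expect_true(all(abs(as.numeric(co$params)[4:6] - truth[4:6]) < 0.01))

  # optimizer contract: NMI at the optimum is not worse than at identity
  nmi_at <- function(par) {
    wg <- datspect:::working_grid(sub$t1, 4)
    ref <- resample_trilinear(gaussian_smooth(sub$t1, 4), wg)
    msk <- as.vector(ref$data) > 0.05 * max(ref$data)
    xw <- datspect:::grid_world_coords(wg)[msk, ]
    src <- gaussian_smooth(sub$spect, 4)
    vox <- xw %*% t(solve(src$affine) %*% affine_matrix(par))
    sv <- datspect:::sample_vol(src, vox[, 1:3])[, 1]
    nmi_histogram(as.vector(ref$data)[msk], sv)
  }
  expect_gte(nmi_at(co$params), nmi_at(affine_params()) - 1e-9)
  expect_error(coregister_rigid(vol_image(array(1, c(8, 8, 8)), diag(4)),
                                sub$t1), "constant")
})
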