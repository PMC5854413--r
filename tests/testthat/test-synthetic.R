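test_that("synthetic atlas has nonempty, disjoint, reproducible regions", {
  atlas <- make_label_atlas(grid2())
  regions <- names(atlas$region_map)
  counts <- vapply(regions, function(r) sum(atlas_mask(atlas, r)), integer(1))
  expect_true(all(counts > 0))
  # labels partition: per-region masks sum to the nonzero voxel count
  expect_identical(sum(counts), sum(atlas$labels != 0L))
  expect_identical(make_label_atlas(grid2())$labels, atlas$labels)
  expect_error(make_label_atlas(grid_spec(c(0, 0, 0), c(10, 10, 10), 2)),
               "grid too small")
})

test_that("noiseless PSF-free phantom reproduces the closed-form ratios", {
  ph <- make_striatal_phantom(phantom_spec(), grid2())
  mns <- roi_means(ph$image, ph$truth,
                   c("caudate", "putamen_L", "putamen_R", "striatum",
                     "background"))
  B <- 1
  expect_equal(mns[["caudate"]], 3 * B, tolerance = 1e-12)
  expect_equal(compute_sur(mns[["caudate"]], mns[["background"]]), 2,
               tolerance = 1e-12)
  expect_equal(compute_sur(mns[["putamen_R"]], mns[["background"]]), 1,
               tolerance = 1e-12)
  expect_equal(compute_sur(mns[["putamen_L"]], mns[["background"]]), 0,
               tolerance = 1e-12)
  # equal compartment volumes -> striatum mean 2.25 B -> SUR 1.25
  cmp <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R")
  vols <- vapply(cmp, function(r) sum(atlas_mask(ph$truth, r)), integer(1))
  expect_true(all(vols == vols[1]))
  expect_equal(compute_sur(mns[["striatum"]], mns[["background"]]), 1.25,
               tolerance = 1e-12)
})

test_that("phantom respects background scaling and spec validation", {
  ph <- make_striatal_phantom(phantom_spec(background_level = 5), grid4())
  mns <- roi_means(ph$image, ph$truth, c("caudate", "background"))
  expect_equal(compute_sur(mns[["caudate"]], mns[["background"]]), 2,
               tolerance = 1e-12)
  expect_error(phantom_spec(ratio_caudate = 0), "> 0")
  expect_error(phantom_spec(background_level = -1), "> 0")
})

test_that("PSF blur monotonically depresses the truth-mask striatal SUR", {
  surs <- vapply(c(0, 4, 8, 12), function(fw) {
    ph <- make_striatal_phantom(phantom_spec(psf_fwhm_mm = fw), grid4())
    mns <- roi_means(ph$image, ph$truth, c("striatum", "background"))
    compute_sur(mns[["striatum"]], mns[["background"]])
  }, numeric(1))
  expect_true(all(diff(surs) < 0))
})

test_that("noise models preserve nonnegativity and determinism", {
  ph_p <- make_striatal_phantom(phantom_spec(noise = noise_poisson(50)),
                                grid8())
  expect_gte(min(ph_p$image$data), 0)
  ph_g <- make_striatal_phantom(phantom_spec(noise = noise_gaussian(0.5)),
                                grid8())
  expect_gte(min(ph_g$image$data), 0)
  ph_p2 <- make_striatal_phantom(phantom_spec(noise = noise_poisson(50)),
                                 grid8())
  expect_identical(ph_p$image$data, ph_p2$image$data)
})

test_that("defect severity strictly orders noiseless striatal SUR", {
  g <- grid4()
  sur_at <- function(sev) {
    sub <- make_synthetic_subject(clean_subject_spec(defect_severity = sev), g)
    mns <- roi_means(sub$spect, sub$truth, c("striatum", "background"))
    compute_sur(mns[["striatum"]], mns[["background"]])
  }
  expect_gt(sur_at(0), sur_at(0.5))
  expect_gt(sur_at(0.5), sur_at(1))
})

test_that("subject generation is seed-deterministic", {
  g <- grid8()
  sp <- subject_spec(defect_severity = 0.4, seed = 99)
  a <- make_synthetic_subject(sp, g)
  b <- make_synthetic_subject(sp, g)
  expect_identical(a$spect$data, b$spect$data)
  expect_identical(a$t1$data, b$t1$data)
})

test_that("the recorded ground-truth transform restores alignment", {
  g <- grid4()
  sp <- clean_subject_spec(
    misalignment = list(t = c(7, -5, 4), r = c(0.06, -0.04, 0.08),
                        z = c(1.03, 0.97, 1.02)))
  sub <- make_synthetic_subject(sp, g)
  restored <- resample_trilinear(sub$spect, g,
                                 transform = sub$ground_truth$spect_affine)
  aligned <- make_synthetic_subject(clean_subject_spec(), g)$spect
  # striatum (uptake > 2x brain background) overlap after inverse transform
  expect_gt(dice_coefficient(restored$data > 2, aligned$data > 2), 0.95)
})

test_that("perfusion-like template is cortex-dominant, nonnegative, fixed", {
  g <- grid4()
  tpl <- make_perfusion_like_template(g)
  atlas <- make_label_atlas(g)
  shell <- datspect:::geom_masks(g, datspect:::default_geometry(), "brain")$brain &
    !datspect:::ellipsoid_mask(datspect:::grid_world_coords(g),
                               c(0, -18, 10), c(64, 82, 68) * 0.78)
  cortical_mean <- mean(tpl$data[array(shell, g$dims)])
  striatal_mean <- mean(tpl$data[atlas_mask(atlas, "striatum")])
  expect_gt(cortical_mean, striatal_mean)
  expect_gte(min(tpl$data), 0)
  expect_identical(make_perfusion_like_template(g)$data, tpl$data)
})

test_that("cohort generation stratifies, reproduces, and orders uptake", {
  recs <- make_cohort(10, 0.5, seed = 42)
  expect_length(recs, 10)
  expect_identical(sum(vapply(recs, function(r) r$stratum == "healthy",
                              logical(1))), 5L)
  recs2 <- make_cohort(10, 0.5, seed = 42)
  expect_identical(recs, recs2)
  sev <- vapply(recs, function(r) r$defect_severity, numeric(1))
  expect_true(all(sev[6:10] >= 0.3 & sev[6:10] <= 0.9))
  mis <- t(vapply(recs, function(r) unlist(r$spec$misalignment), numeric(9)))
  expect_true(all(abs(mis[, 1:3]) <= 10) && all(abs(mis[, 4:6]) <= 0.1) &&
                all(mis[, 7:9] >= 0.95 & mis[, 7:9] <= 1.05))

  # noiseless truth-mask SUR is higher in the healthy stratum
  g <- grid8()
  base <- clean_subject_spec()
  recs <- make_cohort(6, 0.5, base_spec = base, seed = 7)
  surs <- vapply(recs, function(r) {
    sub <- make_synthetic_subject(r$spec, g)
    datspect:::subject_truth_sur(sub$spect, sub$truth,
                                 sub$ground_truth$spect_affine)
  }, numeric(1))
  expect_gt(mean(surs[1:3]), mean(surs[4:6]))
})
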