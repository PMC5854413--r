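## Synthetic data: digital striatal phantom, pseudo-T1/SPECT subject pairs,
## synthetic label atlas and a deliberately mismatched perfusion-like
## template.  All structures are ellipsoids at anatomically plausible MNI
## coordinates, grid-aligned (centres on the 2 mm lattice) so mirrored
## structures have identical voxel counts and the four striatal compartments
## have equal volumes.

# Default geometry (MNI mm): centre + semiaxes per structure.
default_geometry <- function() {
  list(
    head      = list(c = c(0, -18, 10),  s = c(72, 90, 75)),
    skull     = list(c = c(0, -18, 10),  s = c(68, 86, 71)),
    brain     = list(c = c(0, -18, 10),  s = c(64, 82, 68)),
    ventricle_L = list(c = c(-9, -20, 14), s = c(4, 18, 8)),
    ventricle_R = list(c = c(9, -20, 14),  s = c(4, 18, 8)),
    caudate_L = list(c = c(-14, 10, 8),  s = c(7, 11, 7)),
    caudate_R = list(c = c(14, 10, 8),   s = c(7, 11, 7)),
    putamen_L = list(c = c(-28, -2, 2),  s = c(7, 11, 7)),
    putamen_R = list(c = c(28, -2, 2),   s = c(7, 11, 7)),
    occipital_L = list(c = c(-22, -78, 2), s = c(12, 14, 14)),
    occipital_R = list(c = c(22, -78, 2),  s = c(12, 14, 14))
  )
}

ellipsoid_mask <- function(xw, centre, semi) {
  ((xw[, 1] - centre[1]) / semi[1])^2 +
    ((xw[, 2] - centre[2]) / semi[2])^2 +
    ((xw[, 3] - centre[3]) / semi[3])^2 <= 1
}

geom_masks <- function(grid, geometry, names_) {
  xw <- grid_world_coords(grid)
  out <- lapply(geometry[names_],
                function(g) ellipsoid_mask(xw, g$c, g$s))
  names(out) <- names_
  out
}

#' Noise model specifications
#'
#' `noise_none()` disables noise; `noise_gaussian(sigma_rel)` adds zero-mean
#' Gaussian noise with SD `sigma_rel` times the reference (background)
#' level, truncated at 0; `noise_poisson(scale)` draws
#' `Poisson(scale * value) / scale`, emulating count statistics with
#' `scale` expected counts per unit intensity.
#'
#' @param sigma_rel relative Gaussian SD.
#' @param scale expected counts per intensity unit.
#' @export
noise_none <- function() list(type = "none")

#' @rdname noise_none
#' @export
noise_gaussian <- function(sigma_rel = 0.05) {
  stopifnot(sigma_rel >= 0)
  list(type = "gaussian", sigma_rel = sigma_rel)
}

#' @rdname noise_none
#' @export
noise_poisson <- function(scale = 100) {
  stopifnot(scale > 0)
  list(type = "poisson", scale = scale)
}

apply_noise <- function(data, noise, ref_level, seed) {
  if (is.null(noise) || noise$type == "none") return(data)
  set.seed(seed)
  if (noise$type == "gaussian") {
    out <- data + rnorm(length(data), 0, noise$sigma_rel * ref_level)
    return(array(pmax(out, 0), dim(data)))
  }
  if (noise$type == "poisson") {
    out <- rpois(length(data), noise$scale * pmax(data, 0)) / noise$scale
    return(array(out, dim(data)))
  }
  stop("unknown noise type: ", noise$type)
}

#' Synthetic MNI label atlas
#'
#' Deterministic integer-label atlas with left/right caudate, putamen and
#' occipital regions as fixed ellipsoids at plausible MNI coordinates
#' (a synthetic stand-in for AAL-style atlases; real atlases load via
#' [read_label_atlas()]).
#'
#' @param grid a [grid_spec()] covering the MNI head region.
#' @param geometry structure geometry (see `default_geometry` in the
#'   package sources); override to deviate.
#' @return A [label_atlas()].
#' @export
make_label_atlas <- function(grid = grid_spec(), geometry = default_geometry()) {
  grid <- as_grid(grid)
  regions <- c(caudate_L = 1L, caudate_R = 2L, putamen_L = 3L,
               putamen_R = 4L, occipital_L = 5L, occipital_R = 6L)
  masks <- geom_masks(grid, geometry, names(regions))
  labels <- integer(prod(grid$dims))
  for (nm in names(regions)) {
    if (!any(masks[[nm]]))
      stop("grid too small: region '", nm, "' has no voxels")
    if (any(labels[masks[[nm]]] != 0L))
      stop("geometry produces overlapping regions at '", nm, "'")
    labels[masks[[nm]]] <- regions[[nm]]
  }
  label_atlas(array(labels, grid$dims), grid$affine, as.list(regions))
}

#' Digital striatal phantom specification
#'
#' Defaults encode the validation phantom: caudate at 3x background on both
#' sides, right putamen at 2x, left putamen at 1x (i.e. background), no PSF
#' blur and no noise.
#'
#' @param background_level background activity, arbitrary units (> 0).
#' @param ratio_caudate,ratio_putamen_right,ratio_putamen_left activity
#'   ratios relative to background (> 0).
#' @param psf_fwhm_mm Gaussian PSF blur applied after filling, mm FWHM.
#' @param noise a noise spec ([noise_none()], [noise_gaussian()],
#'   [noise_poisson()]).
#' @param geometry structure geometry.
#' @param seed integer RNG seed for the noise stage.
#' @export
phantom_spec <- function(background_level = 1, ratio_caudate = 3,
                         ratio_putamen_right = 2, ratio_putamen_left = 1,
                         psf_fwhm_mm = 0, noise = noise_none(),
                         geometry = default_geometry(), seed = 1L) {
  if (background_level <= 0) stop("background_level must be > 0")
  if (min(ratio_caudate, ratio_putamen_right, ratio_putamen_left) <= 0)
    stop("activity ratios must be > 0")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  structure(list(background_level = background_level,
                 ratio_caudate = ratio_caudate,
                 ratio_putamen_right = ratio_putamen_right,
                 ratio_putamen_left = ratio_putamen_left,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 geometry = geometry, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the digital striatal phantom
#'
#' Head-shaped uniform background with the four striatal compartments set
#' to their activity ratios, then PSF blur, then noise.  The truth atlas is
#' returned pre-blur; its occipital region doubles as the background
#' reference, which by construction sits at exactly the background level.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @return list with `image` ([vol_image()]) and `truth` ([label_atlas()]).
#' @export
make_striatal_phantom <- function(spec = phantom_spec(), grid = grid_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- as_grid(grid)
  g <- spec$geometry
  masks <- geom_masks(grid, g, c("head", "caudate_L", "caudate_R",
                                 "putamen_L", "putamen_R"))
  B <- spec$background_level
  x <- numeric(prod(grid$dims))
  x[masks$head] <- B
  x[masks$caudate_L] <- spec$ratio_caudate * B
  x[masks$caudate_R] <- spec$ratio_caudate * B
  x[masks$putamen_L] <- spec$ratio_putamen_left * B
  x[masks$putamen_R] <- spec$ratio_putamen_right * B
  img <- vol_image(array(x, grid$dims), grid$affine, "striatal phantom")
  if (spec$psf_fwhm_mm > 0) img <- gaussian_smooth(img, spec$psf_fwhm_mm)
  img$data <- apply_noise(img$data, spec$noise, B, spec$seed)
  list(image = img, truth = make_label_atlas(grid, g))
}

#' Synthetic subject specification
#'
#' Defines one synthetic subject: striatal defect severity in \[0, 1\]
#' (0 = healthy; putamen-dominant specific-binding loss with partial caudate
#' involvement), a global intensity scale, a small rigid/affine head
#' misalignment shared by the SPECT and pseudo-T1 channels, a further small
#' rigid SPECT-to-T1 offset (the coregistration ground truth), PSF blur and
#' count noise.
#'
#' @param defect_severity scalar in \[0, 1\].
#' @param global_scale global intensity scale (> 0).
#' @param misalignment list with `t` (mm), `r` (rad), `z` (zooms); applied
#'   as the normalization ground truth.
#' @param spect_t1_offset list with `t` (mm), `r` (rad): extra rigid offset
#'   of the SPECT channel relative to the T1 channel.
#' @param psf_fwhm_mm SPECT PSF blur, mm FWHM (the T1 channel gets a fixed
#'   light 2 mm blur).
#' @param noise noise spec for the SPECT channel.
#' @param geometry structure geometry.
#' @param seed integer RNG seed.
#' @export
subject_spec <- function(defect_severity = 0, global_scale = 1,
                         misalignment = list(t = c(0, 0, 0), r = c(0, 0, 0),
                                             z = c(1, 1, 1)),
                         spect_t1_offset = list(t = c(3, -2, 2),
                                                r = c(0.015, -0.01, 0.02)),
                         psf_fwhm_mm = 8, noise = noise_poisson(100),
                         geometry = default_geometry(), seed = 1L) {
  if (defect_severity < 0 || defect_severity > 1)
    stop("defect_severity must be in [0, 1]")
  if (global_scale <= 0) stop("global_scale must be > 0")
  structure(list(defect_severity = defect_severity,
                 global_scale = global_scale, misalignment = misalignment,
                 spect_t1_offset = spect_t1_offset,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 geometry = geometry, seed = as.integer(seed)),
            class = "subject_spec")
}

misalign_matrix <- function(mis) {
  affine_matrix(affine_params(mis$t[1], mis$t[2], mis$t[3],
                              mis$r[1], mis$r[2], mis$r[3],
                              mis$z[1], mis$z[2], mis$z[3]))
}

# Aligned (MNI-space) activity and pseudo-T1 maps for a given severity.
aligned_activity_map <- function(grid, geometry, defect_severity = 0,
                                 global_scale = 1) {
  m <- geom_masks(grid, geometry, c("head", "skull", "brain", "ventricle_L",
                                    "ventricle_R", "caudate_L", "caudate_R",
                                    "putamen_L", "putamen_R"))
  x <- numeric(prod(as_grid(grid)$dims))
  x[m$head] <- 1.2            # scalp / soft tissue uptake (outer bright ring)
  x[m$skull] <- 0.15          # photopenic skull / CSF gap
  x[m$brain] <- 1.0           # nonspecific brain background
  x[m$ventricle_L] <- 0.35    # CSF: low tracer uptake, adjacent to caudate
  x[m$ventricle_R] <- 0.35
  put <- 1 + 2 * (1 - defect_severity)
  cau <- 1 + 2 * (1 - 0.5 * defect_severity)
  x[m$caudate_L] <- cau; x[m$caudate_R] <- cau
  x[m$putamen_L] <- put; x[m$putamen_R] <- put
  vol_image(array(global_scale * x, as_grid(grid)$dims), as_grid(grid)$affine,
            "aligned activity map")
}

aligned_t1_map <- function(grid, geometry) {
  m <- geom_masks(grid, geometry,
                  c("head", "skull", "brain", "ventricle_L", "ventricle_R",
                    "caudate_L", "caudate_R", "putamen_L", "putamen_R"))
  x <- numeric(prod(as_grid(grid)$dims))
  x[m$head] <- 1.0            # scalp fat: bright on T1
  x[m$skull] <- 0.08          # cortical bone: dark
  x[m$brain] <- 0.7
  x[m$ventricle_L] <- 0.15; x[m$ventricle_R] <- 0.15
  for (nm in c("caudate_L", "caudate_R", "putamen_L", "putamen_R"))
    x[m[[nm]]] <- 0.55
  vol_image(array(x, as_grid(grid)$dims), as_grid(grid)$affine,
            "aligned pseudo-T1 map")
}

#' Generate a synthetic SPECT / pseudo-T1 subject pair
#'
#' Builds aligned MNI-space activity and pseudo-T1 maps, applies the known
#' misalignment to both (the SPECT channel additionally gets the small
#' SPECT-to-T1 rigid offset), then PSF blur and noise on the SPECT channel.
#' The truth atlas is returned in aligned (MNI) space together with the
#' ground-truth transforms for parameter-recovery tests.
#'
#' @param spec a [subject_spec()].
#' @param grid a [grid_spec()].
#' @return list with `spect`, `t1` ([vol_image()]s), `truth`
#'   ([label_atlas()] in aligned space) and `ground_truth`: `params`
#'   (misalignment [affine_params()]), `affine` (its matrix `M`; spatial
#'   normalization of the T1 recovers `M`), `spect_affine`
#'   (`offset %*% M`, recovered by normalizing the SPECT), and
#'   `spect_t1_offset` (rigid [affine_params()] recovered by
#'   [coregister_rigid()] of SPECT to T1).
#' @export
make_synthetic_subject <- function(spec = subject_spec(), grid = grid_spec()) {
  stopifnot(inherits(spec, "subject_spec"))
  grid <- as_grid(grid)
  mis <- spec$misalignment
  M <- misalign_matrix(mis)
  off <- rigid_params(spec$spect_t1_offset$t, spec$spect_t1_offset$r)
  M_off <- affine_matrix(off)
  M_spect <- M_off %*% M

  act <- aligned_activity_map(grid, spec$geometry, spec$defect_severity,
                              spec$global_scale)
  t1a <- aligned_t1_map(grid, spec$geometry)

  spect <- resample_trilinear(act, grid, transform = solve(M_spect))
  if (spec$psf_fwhm_mm > 0) spect <- gaussian_smooth(spect, spec$psf_fwhm_mm)
  spect$data <- apply_noise(spect$data, spec$noise,
                            spec$global_scale, spec$seed)
  spect$desc <- "synthetic SPECT"
  t1 <- resample_trilinear(t1a, grid, transform = solve(M))
  t1 <- gaussian_smooth(t1, 2)
  t1$desc <- "synthetic pseudo-T1"

  list(spect = spect, t1 = t1,
       truth = make_label_atlas(grid, spec$geometry),
       ground_truth = list(params = as_affine_params(
                             c(mis$t, mis$r, mis$z, 0, 0, 0)),
                           affine = M, spect_affine = M_spect,
                           spect_t1_offset = off))
}

#' Deterministic perfusion-like (cortex-dominant) template
#'
#' A smooth, brain-only template whose intensity is dominated by a cortical
#' shell rather than the striatum -- deliberately mismatched to
#' striatum-dominant tracer images.  Used to reproduce the failure mode of
#' normalizing DAT images to a cerebral blood-flow template.
#'
#' @param grid a [grid_spec()].
#' @param geometry structure geometry.
#' @export
make_perfusion_like_template <- function(grid = grid_spec(),
                                         geometry = default_geometry()) {
  grid <- as_grid(grid)
  m <- geom_masks(grid, geometry, c("brain", "ventricle_L", "ventricle_R"))
  inner <- geometry$brain
  inner$s <- inner$s * 0.78
  mi <- ellipsoid_mask(grid_world_coords(grid), inner$c, inner$s)
  x <- numeric(prod(grid$dims))
  x[m$brain] <- 1.0           # cortical shell dominates
  x[mi] <- 0.45               # deep grey / white interior
  x[m$ventricle_L] <- 0.2; x[m$ventricle_R] <- 0.2
  gaussian_smooth(vol_image(array(x, grid$dims), grid$affine,
                            "perfusion-like template"), 8)
}

#' Deterministic T1 template in MNI space
#'
#' The aligned pseudo-T1 map lightly smoothed: the normalization target for
#' the MRI-indirect template-building path.
#'
#' @inheritParams make_perfusion_like_template
#' @export
make_t1_template <- function(grid = grid_spec(), geometry = default_geometry()) {
  gaussian_smooth(aligned_t1_map(grid, geometry), 4)
}

#' Deterministic matched tracer template in MNI space
#'
#' The aligned healthy activity map smoothed at 8 mm: a reference
#' striatum-dominant template for tests that need a perfectly matched
#' normalization target.
#'
#' @inheritParams make_perfusion_like_template
#' @export
make_matched_template <- function(grid = grid_spec(),
                                  geometry = default_geometry()) {
  tpl <- gaussian_smooth(aligned_activity_map(grid, geometry), 8)
  tpl$desc <- "matched tracer template"
  tpl
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 100003 + 17 * i) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' `n` subject records with per-subject derived seeds.  The first
#' `round(n * healthy_fraction)` subjects are healthy (severity 0); patient
#' severities are drawn uniformly from \[0.3, 0.9\].  Misalignments are
#' drawn uniformly inside |t| <= 10 mm, |r| <= 0.1 rad, zoom in
#' \[0.95, 1.05\]; SPECT-to-T1 offsets inside |t| <= 4 mm, |r| <= 0.03 rad.
#'
#' @param n number of subjects (>= 1).
#' @param healthy_fraction fraction of healthy subjects in \[0, 1\].
#' @param base_spec template [subject_spec()] supplying PSF, noise, scale
#'   and geometry.
#' @param seed master seed; records are reproducible given the same seed.
#' @return list of records: `id`, `stratum`, `defect_severity`, `seed`,
#'   `spec` (a complete [subject_spec()]).
#' @export
make_cohort <- function(n, healthy_fraction = 0.5,
                        base_spec = subject_spec(), seed = 1L) {
  stopifnot(n >= 1)
  n_healthy <- round(n * healthy_fraction)
  set.seed(seed)
  sev <- c(rep(0, n_healthy), runif(n - n_healthy, 0.3, 0.9))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    mis <- list(t = runif(3, -10, 10), r = runif(3, -0.1, 0.1),
                z = runif(3, 0.95, 1.05))
    off <- list(t = runif(3, -4, 4), r = runif(3, -0.03, 0.03))
    sp <- base_spec
    sp$defect_severity <- sev[i]
    sp$misalignment <- mis
    sp$spect_t1_offset <- off
    sp$seed <- derive_seed(seed, i)
    recs[[i]] <- list(id = sprintf("sub%03d", i),
                      stratum = if (i <= n_healthy) "healthy" else "patient",
                      defect_severity = sev[i], seed = sp$seed, spec = sp)
  }
  recs
}
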