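## End-to-end orchestration: generation -> template building ->
## quantification -> agreement reporting, plus thin file-based entry points
## used by the command-line wrapper.

# FNV-1a hash of a config object (serialized to JSON) for provenance tags.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Subject-space region mask: the aligned atlas region carried through the
# subject's ground-truth transform.
subject_space_mask <- function(atlas, region, grid, gt_affine,
                               dilate_fwhm_mm = 0, thresh = 0.5) {
  m <- vol_image(array(as.numeric(atlas_mask(atlas, region)),
                       dim(atlas$labels)), atlas$affine, region)
  sm <- resample_trilinear(m, grid, transform = solve(gt_affine))
  if (dilate_fwhm_mm > 0) sm <- gaussian_smooth(sm, dilate_fwhm_mm)
  sm$data > thresh
}

# Ground-truth SUR of a subject image using its subject-space truth masks.
subject_truth_sur <- function(image, atlas, gt_affine) {
  grid <- as_grid(image)
  tm <- subject_space_mask(atlas, "striatum", grid, gt_affine)
  bm <- subject_space_mask(atlas, "background", grid, gt_affine)
  compute_sur(mean(image$data[tm]), mean(image$data[bm]))
}

#' Generate and write the striatal phantom
#'
#' Writes the phantom volume, its truth atlas (NIfTI labels + JSON region
#' map) and a manifest CSV recording ratios, seed and config hash.
#'
#' @param out_dir output directory (created if missing).
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @param seed overrides `spec$seed` when non-NULL.
#' @return (invisibly) named vector of written paths.
#' @export
run_phantom <- function(out_dir, spec = phantom_spec(), grid = grid_spec(),
                        seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- make_striatal_phantom(spec, grid)
  paths <- c(image = file.path(out_dir, "phantom.nii.gz"),
             atlas = file.path(out_dir, "phantom_truth.nii.gz"),
             regions = file.path(out_dir, "phantom_regions.json"),
             manifest = file.path(out_dir, "phantom_manifest.csv"))
  write_volume(ph$image, paths[["image"]])
  write_label_atlas(ph$truth, paths[["atlas"]], paths[["regions"]])
  manifest <- data.frame(
    background_level = spec$background_level,
    ratio_caudate = spec$ratio_caudate,
    ratio_putamen_right = spec$ratio_putamen_right,
    ratio_putamen_left = spec$ratio_putamen_left,
    psf_fwhm_mm = spec$psf_fwhm_mm, noise = spec$noise$type,
    seed = spec$seed,
    config_hash = config_hash(spec[setdiff(names(spec), "geometry")]))
  write.csv(manifest, paths[["manifest"]], row.names = FALSE)
  invisible(paths)
}

#' Generate and write a synthetic cohort
#'
#' Writes per-subject SPECT and pseudo-T1 volumes plus a manifest CSV
#' (id, stratum, severity, seed, file paths, config hash).
#'
#' @param out_dir output directory.
#' @param n,healthy_fraction,base_spec,seed passed to [make_cohort()].
#' @param grid a [grid_spec()].
#' @return (invisibly) the manifest data.frame.
#' @export
run_cohort <- function(out_dir, n = 8, healthy_fraction = 0.5,
                       base_spec = subject_spec(), grid = grid_spec(),
                       seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- make_cohort(n, healthy_fraction, base_spec, seed)
  rows <- lapply(recs, function(r) {
    sub <- make_synthetic_subject(r$spec, grid)
    sp <- file.path(out_dir, paste0(r$id, "_spect.nii.gz"))
    tp <- file.path(out_dir, paste0(r$id, "_t1.nii.gz"))
    write_volume(sub$spect, sp)
    write_volume(sub$t1, tp)
    data.frame(id = r$id, stratum = r$stratum,
               defect_severity = r$defect_severity, seed = r$seed,
               spect = sp, t1 = tp, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$config_hash <- config_hash(list(n = n, hf = healthy_fraction,
                                           seed = seed))
  write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Build a template from files
#'
#' File-based wrapper over [build_template_iterative()] /
#' [build_template_indirect()]: inputs come from a manifest CSV with a
#' `spect` column (and a `t1` column for the indirect mode).
#'
#' @param mode `"iterative"` or `"indirect"`.
#' @param manifest_path cohort manifest CSV.
#' @param seed_template_path seed (iterative) or T1 (indirect) template.
#' @param out_path output template NIfTI; a JSON report is written
#'   alongside it.
#' @param grid,ctrl,smooth_fwhm_mm,passes forwarded to the builder.
#' @return (invisibly) the builder's result list.
#' @export
run_template <- function(mode = c("iterative", "indirect"), manifest_path,
                         seed_template_path, out_path, grid = grid_spec(),
                         ctrl = reg_control(), smooth_fwhm_mm = 8,
                         passes = 2) {
  mode <- match.arg(mode)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  tpl0 <- read_volume(seed_template_path)
  res <- if (mode == "iterative") {
    build_template_iterative(lapply(man$spect, read_volume), tpl0,
                             smooth_fwhm_mm, passes, grid, ctrl)
  } else {
    if (!"t1" %in% names(man)) stop("indirect mode needs a 't1' column")
    pairs <- lapply(seq_len(nrow(man)), function(i)
      list(spect = read_volume(man$spect[i]), t1 = read_volume(man$t1[i])))
    build_template_indirect(pairs, tpl0, smooth_fwhm_mm, grid, ctrl)
  }
  write_volume(res$template, out_path)
  jsonlite::write_json(
    list(mode = res$report$mode, n_inputs = res$report$n_inputs,
         passes = res$report$passes,
         smooth_fwhm_mm = res$report$smooth_fwhm_mm,
         used = sum(vapply(res$report$subjects, function(s) isTRUE(s$ok),
                           logical(1)))),
    paste0(tools::file_path_sans_ext(out_path, compression = TRUE),
           "_report.json"),
    auto_unbox = TRUE)
  invisible(res)
}

#' Agreement report from a paired SUR table file
#'
#' @param table_path CSV or XLSX paired-SUR table.
#' @param method automatic method label (e.g. `"MBT"`).
#' @param out_json optional output path for the JSON report.
#' @param mapping optional column mapping for [read_sur_table()].
#' @return The [agreement_report()].
#' @export
run_agreement <- function(table_path, method, out_json = NULL,
                          mapping = NULL) {
  tab <- read_sur_table(table_path, mapping)
  rep <- agreement_report(tab, method)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(method = rep$method, n = rep$n, pearson_r = rep$pearson_r,
           variability_mean = rep$variability_mean,
           variability_sd = rep$variability_sd,
           mean_diff = rep$bland_altman$mean_diff,
           loa_low = rep$bland_altman$loa_low,
           loa_high = rep$bland_altman$loa_high,
           icc = rep$icc$icc, msbs = rep$icc$components$msbs,
           msws = rep$icc$components$msws),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' End-to-end synthetic pipeline
#'
#' Generates a synthetic cohort, builds the three templates (MRI-indirect
#' "MBT" from SPECT/T1 pairs of healthy subjects, iterative "HBT" seeded by
#' the mismatched perfusion-like template, and the mismatched "HMPAO"
#' template itself), quantifies every subject with every template
#' (automatic path) and with the manual slab emulation, and assembles the
#' per-template agreement statistics against the manual SURs plus the
#' Pearson correlation and striatal Dice against ground truth.
#'
#' @param n,healthy_fraction,base_spec,seed cohort settings
#'   (see [make_cohort()]).
#' @param grid working [grid_spec()] for templates, atlas and
#'   quantification.
#' @param ctrl a [reg_control()]; the default runs the full normalization
#'   (affine plus nonlinear warp), the configuration of the automatic
#'   method.  Disabling the warp (`nonlinear = FALSE`) speeds the pipeline
#'   up considerably but suppresses the intensity-driven distortion through
#'   which a mismatched template corrupts quantification.
#' @param n_mri_pairs SPECT/T1 pairs used for the MRI-indirect template
#'   (capped by the number of healthy subjects).
#' @param out_dir optional output directory for the summary and table CSVs.
#' @param verbose print progress.
#' @return An object of class `datspect_pipeline`: `table` (per-subject
#'   SURs and Dice), `reports` (per-template [agreement_report()]s),
#'   `summary` (one row per template).
#' @export
run_pipeline <- function(n = 8, healthy_fraction = 0.5,
                         base_spec = subject_spec(), grid = grid_spec(),
                         ctrl = reg_control(),
                         n_mri_pairs = 7, seed = 1L, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- as_grid(grid)
  atlas <- make_label_atlas(grid)
  recs <- make_cohort(n, healthy_fraction, base_spec, seed)
  say("generating %d subjects", length(recs))
  subs <- lapply(recs, function(r) make_synthetic_subject(r$spec, grid))

  healthy_idx <- which(vapply(recs, function(r) r$stratum == "healthy",
                              logical(1)))
  if (!length(healthy_idx)) stop("cohort has no healthy subjects")
  say("building templates")
  tpl_hmpao <- make_perfusion_like_template(grid)
  pairs <- lapply(subs[healthy_idx[seq_len(min(n_mri_pairs,
                                               length(healthy_idx)))]],
                  function(s) list(spect = s$spect, t1 = s$t1))
  tpl_mbt <- build_template_indirect(pairs, make_t1_template(grid),
                                     grid = grid, ctrl = ctrl)$template
  tpl_hbt <- build_template_iterative(lapply(subs[healthy_idx],
                                             function(s) s$spect),
                                      tpl_hmpao, passes = 2, grid = grid,
                                      ctrl = ctrl)$template
  templates <- list(MBT = tpl_mbt, HBT = tpl_hbt, HMPAO = tpl_hmpao)

  striatum_ref <- atlas_mask(atlas, "striatum")
  rows <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]; r <- recs[[i]]
    say("quantifying %s", r$id)
    gtM <- s$ground_truth$spect_affine
    tm <- subject_space_mask(atlas, "striatum", grid, gtM,
                             dilate_fwhm_mm = 6, thresh = 0.2)
    bm <- subject_space_mask(atlas, "background", grid, gtM,
                             dilate_fwhm_mm = 6, thresh = 0.2)
    manual <- manual_slab_quantify(s$spect, tm, bm, subject_id = r$id)
    row <- data.frame(subject_id = r$id, stratum = r$stratum,
                      defect_severity = r$defect_severity,
                      sur_truth = subject_truth_sur(s$spect, atlas, gtM),
                      sur_manual = manual$sur, stringsAsFactors = FALSE)
    strict_mask <- subject_space_mask(atlas, "striatum", grid, gtM)
    for (tn in names(templates)) {
      res <- auto_quantify(s$spect, templates[[tn]], atlas, ctrl,
                           subject_id = r$id,
                           method = paste0("auto:", tn))
      mvol <- vol_image(array(as.numeric(strict_mask), grid$dims),
                        grid$affine, "striatum mask")
      wm <- normalise_write(mvol, res$params, grid)
      row[[paste0("sur_", tn)]] <- res$sur
      row[[paste0("dice_", tn)]] <- dice_coefficient(wm$data > 0.5,
                                                     striatum_ref)
    }
    rows[[i]] <- row
  }
  table <- do.call(rbind, rows)

  reports <- lapply(names(templates), function(tn)
    agreement_report(table, tn))
  names(reports) <- names(templates)
  summary <- do.call(rbind, lapply(names(templates), function(tn) {
    rp <- reports[[tn]]
    data.frame(method = tn,
               pearson_manual = rp$pearson_r,
               pearson_truth = pearson(table$sur_truth,
                                       table[[paste0("sur_", tn)]]),
               variability_mean = rp$variability_mean,
               variability_sd = rp$variability_sd,
               mean_diff = rp$bland_altman$mean_diff,
               icc = rp$icc$icc,
               mean_dice = mean(table[[paste0("dice_", tn)]]),
               min_sur = min(table[[paste0("sur_", tn)]]),
               stringsAsFactors = FALSE)
  }))

  out <- structure(list(table = table, reports = reports, summary = summary,
                        templates = templates, atlas = atlas,
                        seed = seed, n = n,
                        config_hash = config_hash(list(n = n, seed = seed,
                                                       grid = grid$dims))),
                   class = "datspect_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(table, file.path(out_dir, "sur_table.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "agreement_summary.csv"),
              row.names = FALSE)
  }
  out
}

#' @export
print.datspect_pipeline <- function(x, ...) {
  cat(sprintf("<datspect_pipeline> n = %d subjects, seed %s, config %s\n",
              x$n, x$seed, x$config_hash))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
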