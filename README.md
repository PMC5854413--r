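# datspect

Automated semiquantitative analysis of dopamine-transporter (DAT) brain
SPECT in R.

DAT tracers such as ^99m^Tc-TRODAT-1 concentrate in the striatum; the
clinical endpoint is the **specific uptake ratio**

```
SUR = (Target − Background) / Background
```

with the striatum (caudate + putamen) as target and the occipital cortex as
background.  Manual ROI drawing is slow and observer-dependent.  The
automatic alternative spatially normalizes every scan to a tracer template
in MNI space and applies fixed atlas ROIs — which makes the **choice of
template** the dominant error source: normalizing a striatum-dominant DAT
image to a mismatched cerebral-blood-flow template misplaces the ROIs and
corrupts the SUR.

`datspect` implements the full workflow and everything needed to validate
it without any clinical scan:

* **Spatial normalization** — 12-parameter affine estimated by damped
  Gauss–Newton on the mean squared difference with a profiled global
  intensity scale, followed by a regularized 7×9×7 discrete-cosine
  deformation (25 mm cutoff, 16 iterations, regularization 1); trilinear
  reslicing onto the MNI bounding box `[-90 -126 -72; 90 90 108]` at 2 mm
  (the 91×109×91 grid); no intensity modulation.
* **Rigid multimodal coregistration** — normalized mutual information over
  a 64×64 joint histogram (SPECT → T1).
* **Template construction** — (a) *iterative*: normalize all scans to a
  seed template, average, re-normalize to the preliminary average, average
  again, smooth at 8 mm FWHM; (b) *MRI-indirect*: coregister each SPECT to
  its T1, normalize the T1 to a T1 template, transfer those parameters to
  the SPECT, average, smooth.
* **Quantification** — atlas-ROI SUR (automatic path) and a manual-method
  emulation (sum of the three hottest transverse slices + 2D masks).
* **Agreement statistics** — percent error, per-subject variability
  (mean ± SD), Pearson correlation, Bland–Altman bias and limits of
  agreement, one-way ICC `(MSBS − MSWS)/(MSBS + (k−1)·MSWS)` with k = 2
  (negative values returned unclamped), pooled two-sample t test.
* **Synthetic data** — a digital striatal phantom (caudate 3× background,
  right putamen 2×, left putamen 1×), a synthetic SPECT/pseudo-T1 cohort
  with known misalignments, striatal defects, PSF blur and Poisson noise,
  a synthetic MNI label atlas, and a deliberately mismatched
  cortex-dominant ("perfusion-like") template.

## Worked example

```r
library(datspect)

## the digital phantom: closed-form ground truth
ph  <- make_striatal_phantom(phantom_spec(), grid_spec())
mns <- roi_means(ph$image, ph$truth, c("caudate", "putamen_R", "putamen_L",
                                       "striatum", "background"))
compute_sur(mns[["caudate"]],  mns[["background"]])   # 2
compute_sur(mns[["putamen_R"]], mns[["background"]])  # 1
compute_sur(mns[["putamen_L"]], mns[["background"]])  # 0
compute_sur(mns[["striatum"]], mns[["background"]])   # 1.25

## end-to-end synthetic study (4 mm working grid for speed)
pl <- run_pipeline(n = 8, grid = grid_spec(voxel_size = 4), seed = 1)
pl
```

The pipeline prints one agreement row per template, e.g.

```
 method pearson_manual pearson_truth variability_mean variability_sd mean_diff
    MBT          0.989         0.995            0.235         0.0678    -0.152
    HBT          0.944         0.953            0.192         0.1561     0.124
  HMPAO          0.635         0.685            1.212         0.2500     0.455
    icc mean_dice min_sur
  0.763     0.809  0.3945
  0.556     0.486  0.2909
 -0.550     0.157  0.0419
```

Read it as: the MRI-indirect template (`MBT`) tracks ground truth almost
perfectly (Pearson vs truth 0.995, striatal ROI Dice 0.81) and carries the
highest manual-method agreement (ICC 0.76); the iteratively built template
(`HBT`) is intermediate; the mismatched perfusion-like template (`HMPAO`)
collapses quantification (Dice 0.16, negative ICC, SUR driven toward
zero).  The automatic SURs from the matched template run slightly above
the manual-emulation SURs (negative mean difference), because the 2D slab
emulation dilutes the striatal signal through-plane.

A thin command-line wrapper ships in `inst/cli/datspect`
(`phantom`, `cohort`, `template`, `quantify`, `agree`, `pipeline`
subcommands).

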