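# trabmorph

Trabecular bone morphometry from micro-CT and dental CBCT volumes, with the
preprocessing ladder that makes chairside CBCT usable for ranking bone
quality — and a fully synthetic, ground-truthed test world so the whole
pipeline is verifiable without any scanner data.

## Who this is for

Researchers comparing trabecular microarchitecture across imaging modalities
(dental CBCT vs micro-CT), and anyone who needs an **exact**, oracle-tested
implementation of model-independent local thickness on binary volumes.

## What it computes

For a binary bone mask the four standard microarchitectural parameters:

- **BV/TV** (%) — bone volume fraction, voxel counting;
- **TbTh** (mm) — mean over bone voxels of the diameter of the largest
  sphere fully contained in bone covering that voxel
  (Hildebrand–Rüegsegger, exact digital implementation: distance ridge +
  sphere propagation, bit-identical to a brute-force oracle);
- **TbSp** (mm) — the same thickness measure on the marrow phase;
- **TbN** (1/mm) — the ratio convention (BV/TV)/TbTh.

For a CBCT volume, the cumulative preprocessing ladder applied before
binarization:

| Group | Steps |
|-------|-------|
| G0 | micro-CT reference, global isodata threshold |
| G1 | raw CBCT, global isodata threshold |
| G2 | + 3×3 sharpen and 3×3 median despeckle (per slice) |
| G3 | + per-slice isodata threshold (cancels axial shading exactly) |
| G4 | + removal of voxels at/below the zero-BMD grayscale from the hydroxyapatite-phantom calibration |

And for a cohort: per-group summaries (mean ± SD, range) plus paired
t-tests and Pearson correlations of every CBCT group against the micro-CT
reference.

The synthetic-data module generates cancellous-bone phantoms (thresholded
Gaussian random fields with exactly realised BV/TV, drained-pore air
pockets, a composite-resin anchor ball for ROI alignment) and degrades them
to CBCT quality (axial shading → Gaussian PSF → ×5 block-average
downsampling to 0.1 mm voxels → noise). Volume I/O covers TIFF slice stacks
(micro-CT dialect) and DICOM series (CBCT dialect).

## Worked example

```r
library(trabmorph)

ph <- generate_trabecular_phantom(
  phantom_spec(shape_mm = c(3, 3, 6), target_bvtv = 0.25, seed = 42))
micro <- embed_anchor_ball(ph$gray)                       # resin ball on top
cbct  <- degrade_to_cbct(micro, degradation_spec(seed = 43))
print(cbct)

roi <- roi_spec(extent_mm = c(2, 2, 5))                   # implant-sized ROI
roi_micro <- extract_roi(micro, locate_anchor(micro), roi)
roi_cbct  <- extract_roi(cbct,  locate_anchor(cbct),  roi)

calib <- fit_calibration(generate_calibration_scan())     # HA phantom
for (g in c("G0", "G1", "G3", "G4")) {
  input <- if (g == "G0") roi_micro else roi_cbct
  print(compute_morphometry(run_group(input, g, calib),
                            specimen_id = "S42", group = g,
                            params = c("bv_tv", "tb_th", "tb_n")))
}
cat("ground-truth BV/TV:", round(100 * ph$realized_bvtv, 2), "%\n")
```

prints

```
<gray_volume> 71 x 30 x 30 (z,y,x), voxel 0.1 mm, cbct, range [0, 230.2]
<morphometry> S42 G0: BV/TV 22.99%, TbTh 0.195 mm, TbN 1.182 /mm, TbSp NA mm
<morphometry> S42 G1: BV/TV 37.84%, TbTh 0.263 mm, TbN 1.441 /mm, TbSp NA mm
<morphometry> S42 G3: BV/TV 38.90%, TbTh 0.232 mm, TbN 1.675 /mm, TbSp NA mm
<morphometry> S42 G4: BV/TV 38.90%, TbTh 0.232 mm, TbN 1.675 /mm, TbSp NA mm
ground-truth BV/TV: 25 %
```

Reading it: the micro-CT reference (G0) recovers the 25 % ground truth and a
TbTh of ~0.2 mm; the raw CBCT (G1) overestimates both — the partial-volume
effect at 0.1 mm voxels. TbSp prints `NA` because the example skips the
expensive marrow-phase transform via `params`. G4 differs from G3 only on
specimens where a per-slice threshold drops to the air–tissue split, so the
air-removal rule has something to delete; at cohort level it is what
restores the BV/TV correlation with the reference (run
`run_experiment(default_config())` for the full 30-specimen analog, ~4 min).

## Cohort experiment

```r
out <- run_experiment(default_config(n = 30, seed = 1, out_dir = "run1"))
out$summary      # mean ± SD and range per group and parameter
out$comparison   # Pearson r and paired t against G0, 16 rows
```

Rerunning the same configuration is byte-identical. A command-line front end
is installed at `inst/scripts/trabmorph` with subcommands `simulate`, `roi`,
`preprocess`, `morphometry`, `run`.

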