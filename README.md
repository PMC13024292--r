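# spinetrack

Quantitative motion analysis of the cervical spine from per-frame vertebra
segmentation masks of dynamic X-ray recordings.

Dynamic lateral radiographs of a flexion–extension sweep (typically
1024 × 1024 px at 15 fps, ~10 s) can be segmented frame by frame into
per-vertebra label masks (C0–C7), by hand or by a segmentation model.
`spinetrack` is for the people who then have to turn those masks into
kinematics: clinical-motion researchers validating automated pipelines,
and methods developers who need a controlled test bed with known ground
truth. The package never trains or runs a segmentation model — masks in,
kinematics and reports out.

## What it computes

For each vertebra *C*, a rigid per-recording **mean shape** is built by
iterative aligned averaging of all frames, then fitted to every frame
(translation to the mask centroid, rotation maximising overlap within
±90° of the previous frame's angle) to give an absolute angle trace
θ_C(t). From these:

* per-frame deltas dθ_C(t) = θ_C(t) − θ_C(t−1), with dθ_C(0) = 0;
* segmental relative rotation dθ_R(t) = dθ_Ck(t) − dθ_Cl(t) for adjacent
  pairs (motion segments), Gaussian-smoothed with σ = 3 frames;
* segmental range of motion (sROM): max − min of the cumulative smoothed
  series, with a 4° sensitivity filter for low-motion segments;
* motion-pattern curves (per-segment rotation vs. cumulative C4–C7
  rotation) and the sequence of segmental contribution (SSC);
* segmentation quality: Dice (DSC = 2|A∩B|/(|A|+|B|)), Jaccard
  (IoU = |A∩B|/|A∪B|), and the symmetric 95th-percentile Hausdorff
  distance (HD95) with per-vertebra mean ± SD and acceptability flags
  (DSC ≥ 0.8, IoU ≥ 0.7, HD95 < 16 mm);
* reliability of predicted vs. reference kinematics: ICC(3,1) — two-way
  mixed-effects, consistency, single rater,
  (MS_R − MS_E)/(MS_R + MS_E) for two raters — with F-based 95% CIs,
  sensitivity filters, and Pearson correlations of ICC against
  segmentation-metric summaries.

A seeded synthetic phantom (an articulated chain of rounded rectangles
with analytic raised-cosine segment kinematics, plus boundary jitter /
occlusion / dropout degradations) provides ground truth for every stage.

## Worked example

```r
library(spinetrack)

cfg <- phantom_config(n_frames = 60, image_size = c(384L, 384L), seed = 42)
rec <- generate_phantom(cfg)
rec
#> <phantom_recording> 60 frames 384x384, sweep 40 deg over 7 segments, seed 42

shapes <- lapply(c(C4 = "C4", C5 = "C5", C6 = "C6", C7 = "C7"),
                 function(v) build_mean_shape(rec$masks, v))
shapes$C5
#> <mean_shape> C5: 1111 px template from 60 frames, converged after 3 iteration(s)

tracks <- lapply(shapes, function(s) track_vertebra(rec$masks, s))
segs <- list(relative_rotation(tracks$C4, tracks$C5),
             relative_rotation(tracks$C5, tracks$C6),
             relative_rotation(tracks$C6, tracks$C7))
segs[[2]]
#> <segment_trace> C5-C6: 60 frames, sROM 8.50 deg (sigma 3)

build_pattern(segs)
#> <motion_pattern> frames 1-60, cumulative C4-C7 excursion 24.08 deg
#>   SSC: C6-C7 -> C5-C6 -> C4-C5

icc_3_1(segs[[2]]$dtheta_rel_smoothed_deg,
        smooth_trace(rec$truth_segment[["C5-C6"]]$dtheta_rel, 3))
#> <icc_result> ICC(3,1) consistency: 0.992 (95% CI 0.987-0.995), n = 60
```

Reading the numbers: the phantom programs an 8° excursion on C5–C6 (the
estimated sROM of 8.50° includes smoothing and rasterization effects at
this reduced 384-px scale; at the full 1024-px default the error is
within ±0.1°), the C4–C7 segments are programmed to peak at 0.2/0.5/0.8
of the sweep — exactly the recovered SSC order — and the tracked C5–C6
series agrees with the analytic truth at ICC 0.992.

The same stages are available from the command line
(`exec/spinetrack` after installation):

```sh
spinetrack simulate --config phantom.yaml -o sim/
spinetrack metrics --pred pred.tif --gt gt.tif --spacing-mm 0.2 -o metrics.tsv
spinetrack pipeline --config pipeline.yaml
```

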