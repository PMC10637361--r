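# tfusplan

Automatic target planning for transcranial MR-guided focused ultrasound
(tcMRgFUS) thalamotomy in essential tremor, as an R package. The ablation
target — the ventral intermediate nucleus (VIM) of the thalamus — is not
visible on routine MRI, so planning combines two surrogates:

1. **A geometric standard coordinate** derived from the anterior and
   posterior commissures (AC, PC): anterior to the PC by 25 % of the AC-PC
   distance, 1 mm superior to the AC-PC plane, 14 mm lateral toward the
   treated side.
2. **Deterministic diffusion-tensor tractography** of the treatment-relevant
   bundles: the cerebellothalamic (CTT) and pallidothalamic (PTT) tracts as
   targets, and the corticospinal tract (CST) and medial lemniscus (ML) as
   no-go structures.

The package implements the full planning chain: NIfTI/bval/bvec I/O and
voxel↔world geometry; AC-PC reorientation; rigid multilevel registration
with a normalized-gradient-fields (NGF) distance; DWI preprocessing
(Lanczos-3 isotropic supersampling, Gaussian smoothing, Stejskal–Tanner
tensor fitting with per-voxel log-linear least squares); atlas-adaptive
streamline tracking with seed/include/exclude ROI filtering and a
minimum-fiber (≥ 100) / maximum-iteration (500, CTT 2500) retry loop;
tract probability maps scaled to [0, 1] and thresholded (0.2 for
CTT/PTT/CST, 0.5 for ML; 0.1 for FSL-style maps); and the evaluation
statistics

```
dev(j)  = (1/K) Σᵢ ‖p(i,j) − stdCoord(j)‖          (mean deviation, mm)
xdev(j) = (1/K) Σᵢ | |pₓ(i,j)| − 14 |               (lateral deviation, mm)
```

with conditional cohort means, bundle-border distances, lesion centroids
and Dice overlaps. A synthetic phantom generator (`make_phantom()`)
produces complete, self-consistent planning datasets — tensor tubes with
known geometry, forward-simulated DWI at b = 1200 s/mm² with 56
directions, ROIs, atlas labels, landmarks, lesion and treatment log — so
every stage is testable without patient data.

## Worked example

```r
library(tfusplan)

# the standard target for a 24 mm AC-PC distance, left-side treatment
lm <- landmark_pair(ac = c(0, 24, 0), pc = c(0, 0, 0))
standard_coordinate(lm, side = "left")
#> <standard coordinate> (14, 6, 1) mm, side left

# a synthetic planning dataset and a full pipeline run
ph  <- make_phantom(phantom_spec(shape = "straight", noise = "none"))
dir <- tempfile(); write_phantom_dataset(ph, dir)
cfg <- plan_config(t1 = file.path(dir, "t1.nii.gz"),
                   dwi = file.path(dir, "dwi.nii.gz"),
                   bval = file.path(dir, "dwi.bval"),
                   bvec = file.path(dir, "dwi.bvec"),
                   landmarks = file.path(dir, "landmarks.json"),
                   rois = file.path(dir, "rois/manifest.json"),
                   bundles = file.path(dir, "bundles.json"),
                   atlas = file.path(dir, "atlas.nii.gz"),
                   treatment = file.path(dir, "treatment.csv"),
                   lesion = file.path(dir, "lesion.nii.gz"),
                   side = "left", seed = 42, out_dir = tempfile())
rep <- plan(cfg)
rep$standard_coordinate
#> [1] 14  6  1
rep$bundles$CTT$accepted        # ≥ 100 accepted streamlines
#> [1] 100
```

The run writes the standard coordinate JSON, one TrackVis `.trk` file and
one thresholded probability-map NIfTI per bundle, an evaluation JSON with
per-bundle distances to the lesion centre / mean treatment point /
standard coordinate, and a stage-timed run report. `(14, 6, 1)` is the
25 % / +1 mm / +14 mm rule applied to the phantom's 24 mm AC-PC distance;
the accepted-streamline count reflects the ≥ 100-fiber contract of the
tracking loop on a clear corridor.

A thin CLI wrapper (`inst/cli/tfusplan.R`) exposes `plan`, `make-phantom`
and `acpc` subcommands for shell use.

## Scope

Landmark detection and ROI segmentation (deep-learning components in a
clinical deployment) are inputs here, not products; deformable atlas
registration, crossing-fiber models, probabilistic tractography and DICOM
ingestion are out of scope. See `vignettes/planning-methods.Rmd` for the
model, parameter and design discussion.
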