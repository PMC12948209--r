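# vox3dmsi

Voxel-based 3D reconstruction and statistical analysis of serial-section
MALDI mass spectrometry imaging (MSI) data from micron-scale 3D cell
cultures — spheroids and cystic organoids.

A spheroid of ~600 µm diameter is cryosectioned exhaustively at 20 µm,
each section imaged at a 20 µm raster and exported as one centroid imzML
file. Because every section is mounted independently, consecutive ion
images are rigidly displaced. `vox3dmsi`:

1. **reads** the section series onto a common m/z feature axis
   (centroid imzML 1.1 in, NRRD volumes out);
2. **reconstructs** the 3D volume: per-pixel RMS normalization, then
   rigid registration of consecutive sections on a morphology-defining
   landmark ion image (m/z 863.57 by convention) by maximizing
   normalized cross-correlation over a multi-resolution pyramid, with a
   consistency-graph solve over redundant pairwise registrations that
   suppresses chain drift; inter-slice correlation before/after
   registration is the QC readout;
3. **segments** voxels by bisecting k-means with correlation distance
   (1 − Pearson r to the leaf centroid), after optional weak de-noising
   (3×3 median), with config-driven leaf→region assignment;
4. **picks voxel objects**: 3D connected components of a region mask
   (26-connectivity by default), classified by size — V1 < 10 vx,
   10 ≤ V2 ≤ 100 vx, V3 > 100 vx, one 20×20×20 µm voxel = 8000 µm³ —
   with surface/volume geometry validated against voxelated spheres;
5. **tests** object groups feature-by-feature: per-object mean profiles
   (objects, never voxels, are the replicates), two-sided Welch t-tests,
   Benjamini–Hochberg adjustment, log2 fold changes of group means, and
   volcano tables; a feature is significant when `p_adj < α` and
   `|log2FC| >` the threshold. Cohen's d marker concordance covers the
   2D workflow.

A synthetic phantom generator (`phantomSpec()` / `generatePhantom()`)
produces serial-section datasets with complete ground truth — applied
per-section transforms, voxel region labels, embedded-object catalog,
planted log2 fold changes — so every stage is testable without
instrument data. See the vignette in `vignettes/` for the model and its
design decisions.

## Worked example

```r
library(vox3dmsi)

ph <- generatePhantom(phantomSpec(seed = 2))
ph$dataset
#> SerialSectionDataset 'biculture_spheroid': 30 sections, 12 features

vol <- stackDataset(ph$dataset, landmarkMz = 863.57)
round(c(before = intersliceCorrelation(assembleVolume(ph$dataset), 863.57)$mean,
        after  = intersliceCorrelation(vol, 863.57)$mean), 3)
#> before  after
#> -0.134  0.760
```

Registration lifts the mean adjacent-slice landmark correlation from
about zero (sections perturbed by up to 5 px and 10°) to ~0.76, the
geometric ceiling for this phantom's noise. Voxel-object analysis on the
fibroblast region (here the ground-truth mask of an unperturbed
replicate; `runPipeline()` derives it by segmentation):

```r
still <- generatePhantom(phantomSpec(seed = 2, maxTransPx = 0, maxRotDeg = 0))
svol <- assembleVolume(still$dataset)
objects <- objectGeometry(classifySize(
  pickObjects(still$truth@regionVolume == 2, connectivity = 26,
              voxelUm = voxelUm(svol))))
attr(objects, "classCounts")
#> V1 V2 V3
#>  0  9  5

head(objectStats(objects), 3)
#>   object_id voxel_count centroid_z centroid_y centroid_x size_class volume_um3 surface_area_um2
#> 1         1         177   22.58757   22.11864   27.92090         V3    1416000            90400
#> 2         2         176   15.26705   21.30114   17.18750         V3    1408000            90400
#> 3         3         136   15.74265   32.44118   31.25735         V3    1088000            76000

prof <- objectProfiles(objects, svol)
cls <- objectStats(objects)$size_class
res <- differentialTest(prof[cls == "V2", ], prof[cls == "V3", ],
                        mz = as.numeric(colnames(prof)),
                        alpha = 0.01, lfcThreshold = 1)
head(volcanoTable(res), 5)
#>       mz    log2_fc      p_value        p_adj significant
#> 1 650.20 -2.4022038 2.472273e-05 0.0002966728        TRUE
#> 2 700.10  2.4790492 6.933863e-04 0.0041603176        TRUE
#> 3 600.30  1.6487378 2.019856e-03 0.0080794242        TRUE
#> 4 550.40  0.5346887 1.428663e-01 0.3590082643       FALSE
#> 5 885.55  0.3353853 1.495868e-01 0.3590082643       FALSE
```

The three significant features are exactly the three planted V2-vs-V3
fold changes (+2, −2, +1.5 in log2), recovered with the correct signs;
the remaining channels (cell-type markers and nulls) are correctly not
selected. Volumes and labels export to NRRD with `writeVolumeNrrd()`
for 3D rendering; `runPipeline()` orchestrates the whole flow from a
single declarative YAML config (see
`inst/extdata/example_run.yaml`), and `inst/cli/vox3dmsi.R` wraps the
same functions for shell use.

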