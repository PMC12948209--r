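# Example pipeline configuration: simulate a biculture spheroid phantom and
# run reconstruction -> segmentation -> voxel objects -> differential stats.
# All unset fields take the documented defaults (see ?readRunConfig).
simulate:
  seed: 3
landmark_mz: 863.57
registration:
  max_iters: 400
  reference: graph
segmentation:
  n_leaves: 8
  seed: 7
  denoise: true
  region_markers:
    cancer: 778.51
    fibroblast: 792.55
  target_region: fibroblast
objects:
  connectivity: 26
  lower: 10
  upper: 100
  exclude_classes: [V1]
stats:
  group_by: size_class
  group_a: V2
  group_b: V3
  alpha: 0.01
  lfc: 1
  test: welch
output_dir: vox3dmsi_run
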