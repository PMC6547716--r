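# Example configuration for run_pipeline(): a reduced human-like study.
seed: 1
out_dir: amynet_run
stages:
  simulate: true
  preprocess: true
  voxelwise: true
  connectivity: true
  interaction: true
  sem: true
synthetic:
  n_subjects:
    CN_pos: 53
    MCI_pos: 170
correction:
  method: permutation_maxT
  alpha: 0.05
  n_perm: 500
seed_rois:
  - precuneus
  - posterior_cingulate
write_volumes: false
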