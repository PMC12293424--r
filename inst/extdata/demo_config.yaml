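# Demo configuration for the synthetic ALPS pipeline.
seed: 20260929
phantom:
  dim: [48, 48, 12]
  voxel_mm: 2
  lambda_radial: 0.000699
  lambda_axial: 0.0017
  pvs_dx: 0.000301
  background_d: 0.0008
  S0: 1000
  snr: 30
scheme:
  n_dirs_per_shell: 30
  shell_bvals: [800, 2800]
  n_b0: 8
cohort:
  n_subjects: 9
  between_subject_cv: 0.03
fit:
  b_target: 800
  tol: 50
  method: wls
rois: standard
stats:
  alpha: 0.05
  adjust: BH
output:
  dir: alps_out
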