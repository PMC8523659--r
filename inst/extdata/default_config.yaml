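# Default cdrflex pipeline configuration: analyze the vhh_contrast
# synthetic preset end to end. All keys override defaults of
# cdrflex::default_config(); paths are relative to the working directory.
seed: 1
output_dir: cdrflex_out
generator:
  preset: vhh_contrast
regions:
  scheme: imgt
q_params:
  beta: 5.0            # 1/Angstrom, logistic steepness
  lambda: 1.8          # formed-contact fluctuation tolerance (all-atom)
  contact_cutoff: 4.5  # Angstrom, native heavy-atom pair cutoff
  min_seq_separation: 3
burn_in_fraction: 0.5454545454545454   # 6/11: drop 600 of 1100 ns worth
convergence:
  std_threshold: 1.0       # Angstrom, post-burn-in global RMSD stability
  overlap_threshold: 0.5   # half-split histogram overlap coefficient
  outlier_k: 3             # MAD multiplier for outlier-run flagging
  outlier_min_abs: 0.5     # Angstrom, absolute floor for the outlier rule
  split_after_burn_in: true
  exclude_outliers: false  # advisory by default: report, do not drop
exclude_runs: []
kde:
  grid_points: 512
  rmsd_region: CDR1
write_plots: false
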