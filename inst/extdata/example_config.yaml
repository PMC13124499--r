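# Example pipeline configuration for `proteomut run --config ...`.
# Top-level keys mirror pipeline_config(); the sim block mirrors sim_config().
seed: 1
fdr: 0.01
precursor_tol_ppm: 10
frag_tol: 0.6
flank: 25
lead: 24
spike_amount: 10
sim:
  seed: 1
  n_proteins: 20
  n_missense: 10
  n_frameshift: 2
  n_negatives_per_clause: 2
  depth_mean: 100
  vaf_min: 0.15
  vaf_max: 0.6
  dropout: 0.1
  n_noise_peaks: 5
  mz_jitter_sd: 0.05
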