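# Example pipeline configuration. Paths are relative to where you run the
# CLI; generate the phantom inputs first with the `simulate` subcommand.
labeled_imzml: out/phantom_labeled.imzML
unlabeled_imzml: out/phantom_unlabeled.imzML
target_list: targets_brain_dnl.tsv
out_dir: out
tol_ppm: 10
blur_sigma: 0          # set to 1 to enable the 3x3 Gaussian blur
normalization: none    # none | tic
p13: 0.0107
interference_threshold: 0.02
segmentation:
  n_components: 5
  seed: 1
sisa:
  target: palmitate
  model: sisa          # sisa | elongation
  t_hours: 48
  min_intensity: 0
errorprop:
  model: sisa
  sigma_levels: [0.001, 0.002, 0.005, 0.01, 0.02, 0.05]
  n_reps: 200
  seed: 1
  target: palmitate
phantom:
  width: 60
  height: 40
  seed: 1
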