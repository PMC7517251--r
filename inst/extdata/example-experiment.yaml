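# Minimal end-to-end experiment: Ising patches at one temperature, a small
# hidden-size family, enumerate-mode thermodynamics. Intended as a template;
# scale n_samples / n_patches / hidden_sizes up for production runs.
data:
  source: ising
  L: 8
  temperature: 2.5
  n_samples: 200
  burn_in: 200
  thin: 10
  method: swendsen-wang
  pixel_count: 5
  n_patches: 1000
  heldout_fraction: 0.2
  seed: 11
model:
  hidden_sizes: [3, 6]
  schedule: [0.2, 0.1, 0.05]
  epochs_per_stage: 2
  minibatch: 16
  seed: 12
analysis:
  n_bins: 6
  mode: enumerate
  gibbs_n_keep: 4000
  gibbs_n_chains: 100
  gibbs_thin: 2
  gibbs_burn_in: 100
  seed: 13
output:
  dir: example-output
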