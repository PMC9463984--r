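# Pipeline defaults: one documented home for every parameter the method
# leaves open. Override with --config; --seed overrides `seed`.
schema: 1
seed: 1

data:                 # synthetic dataset geometry (desk scale)
  n_subjects: 8
  v: 100              # TRs per subject
  grid: [12, 12, 12]
  k1: 8               # primitive networks
  k3: 4               # composite (deep-layer analogue) maps
  alpha: 0.2          # subject-specific mixing ratio
  noise_sd: 0.1

nas:                  # particle-swarm architecture search
  n_particles: 10     # full-scale default is 30; reduced for desk runs
  n_iterations: 10    # 40 at full scale
  w: 0.1
  w_schedule: null    # e.g. [0.9, 0.1] for linearly decreasing inertia
  c1: 2
  c2: 2
  layer_range: [2, 4]     # full-scale search range is [2, 10]
  node_range: [8, 32]     # full-scale search range is [100, 800]
  eval_budget: 5      # training epochs per fitness evaluation

train:                # group-stage vsDBN
  arch: [16, 16, 16]  # used when the nas stage has not been run
  epochs: 30
  batch_size: 64
  sparsity_target: 0.1
  sparsity_weight: 1

fine_tune:            # subject stage
  epochs: 20
  lr_scale: 0.1

metrics:
  overlap_cutoff: 1.96   # z threshold for binarizing maps

dfc:
  rect_width: 22      # TRs
  gauss_sigma: 3      # TRs
  gauss_halfwidth: 11 # TRs; effective window length = 22 + 2*11 = 44
  step: 2             # TRs
  k: 4                # connectivity states
  kmeans_restarts: 20
  atoms: null         # top-layer atom indices; null = all atoms
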