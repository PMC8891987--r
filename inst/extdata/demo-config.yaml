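# Demo configuration: full synthetic run at small problem sizes.
seed: 42
out_dir: demo-run
stages: [beads, migration, afm, fa, stats]
beads:
  n: 60
  pixel_size: 0.3
  noise_sd: 0.02
migration:
  n_tracks: 20
  n_steps: 72
  dt: 5
afm:
  E_Pa: [500, 1000, 2000]
  n_cells: 2
  n_curves: 15
fa:
  n_cells: 2
  pixel_size: 0.1
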