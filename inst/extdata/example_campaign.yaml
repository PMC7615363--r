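# Example pipeline configuration: simulate a short campaign from a synthetic
# poly-A seed and run every analysis stage with the engine-free defaults.
seed:
  name: T5
  fwd_primer: GCTAGACGTTCCATG
  core: AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
  rev_primer: CATGGTTGCAGACTC
campaign:
  n_rounds: 4
  molecules_per_round: 1000
  rng_seed: 1
  selection:
    binding_score: loop
    capture_scale: 1
    background_capture: 0.02
stages: [diversity, mutation, motifs, structure, embedding]
motif: GGNAGANNNTG
fold_engine: fallback
pad_len: 90
rng_seed: 1
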