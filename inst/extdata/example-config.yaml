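# Desk-scale monosynaptic STS experiment on the single-pathway aDFP
# network with uncorrelated background drive. Unspecified fields fall back
# to the reference defaults (see ?load_config).
background:
  rate: 0.8
  n_trains: 200
  c_back: 0
network:
  n_hidden_paths: 1
  n_background_removed_from_O: 0
durations:
  equilibrate: 20000
  base: 2000
  peri: 10000
  post: 2000
intervention:
  type: sts
  source: I1_1
  target: O
  t_delay: 20
  w_stim_max: 50000
n_trials: 5
seed: 1
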