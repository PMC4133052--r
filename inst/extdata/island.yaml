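# One large population coupled to six small valley-crossing islands.
landscape:
  delta: 0.2
  s: 0.3
  mu: 3.0e-4
deme:
  K: 27
  g: 0.1
metapop:
  D: 7
  m: 0
  topology: hub-and-spoke
  N_large: 100
  C: 6
  N_island: 24
  m_total_island: 1.0e-3
run:
  command: island
  replicates: 50
  seed: 1
  t_max: 1.0e7
  grid:
    axis: m_over_mu
    from: 0.2
    to: 110
    n: 7
  out: out/island
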