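{
  "landscape": { "delta": 0.05, "s": 0.1, "mu": 1e-05 },
  "deme": { "K": 111, "g": 0.1 },
  "metapop": { "D": 10, "m": 7e-07 },
  "run": {
    "command": "theory",
    "replicates": 100,
    "seed": 1,
    "t_max": 1e9,
    "grid": { "axis": "m_over_mu", "from": 0.002, "to": 3, "n": 9 },
    "out": "out/deep_valley"
  }
}
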