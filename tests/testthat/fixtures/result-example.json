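{
  "schema": "qsgwst-result-v1",
  "qp_energies_eV": [-542.1, -33.2, -17.19, -14.85, -12.31, 5.12, 9.4],
  "IP_eV": 12.31,
  "EA_eV": -5.12,
  "iterations": 9,
  "nf_trace": [0.005, 0.0004, 2.1e-05, 1.3e-06, 8.2e-08, 3.1e-09],
  "converged": true,
  "mode": "B",
  "guess": "PBE0",
  "basis": "et-min",
  "n_occ": 5,
  "config": {
    "mode": "B", "eps_scf": 1e-07, "max_iter": 30, "n0": 10,
    "mixing": "diis", "alpha": 0.35, "noise_cut": 1e-06,
    "n_grid": 16, "eta": 0.001
  }
}
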