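{
  "carbon": {
    "radiation_type": "carbon",
    "intercept": 0.646,
    "coefficients": {
      "tiRNA-Glu-TTC-003": -0.149,
      "tRF-Val-AAC-024": 0.022,
      "tRF-Gln-CTG-018": -0.093,
      "tRF-Lys-CTT-008": 0.139,
      "tRF-Lys-TTT-019": -0.206
    }
  },
  "xray": {
    "radiation_type": "xray",
    "intercept": 0.943,
    "coefficients": {
      "tRF-Val-AAC-024": -0.05,
      "tRF-Gln-CTG-018": -0.053,
      "tRF-Lys-CTT-008": -0.013,
      "tRF-Lys-TTT-019": 0.023
    }
  },
  "proton": {
    "radiation_type": "proton",
    "intercept": 0.521,
    "coefficients": {
      "tiRNA-Glu-TTC-003": -0.081,
      "tRF-Val-AAC-024": 0.788,
      "tRF-Gln-CTG-018": -0.077,
      "tRF-Lys-CTT-008": -0.646,
      "tRF-Lys-TTT-019": -0.077
    }
  }
}
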