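{
  "version": 1,
  "engine": "layered",
  "name": "sfdi-perpendicular",
  "n_packets": 100000,
  "geometry": {
    "layers": [
      {
        "n": 1
      },
      {
        "mua": {
          "value": 2.5,
          "unit": "1/cm"
        },
        "mus": {
          "value": 300,
          "unit": "1/cm"
        },
        "n": 1.337,
        "thickness": "Inf",
        "phase_function": {
          "family": "HG",
          "g": 0.9
        }
      },
      {
        "n": 1.337
      }
    ]
  },
  "source": {
    "kind": "pencil"
  },
  "detectors": {
    "radial_top": {
      "r_max": {
        "value": 150,
        "unit": "mm"
      },
      "n_bins": 2000,
      "log": true,
      "r_min": {
        "value": 10,
        "unit": "um"
      },
      "cos_min": 0.984807753012208
    }
  }
}
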