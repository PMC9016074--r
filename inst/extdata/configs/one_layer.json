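{
  "version": 1,
  "engine": "layered",
  "name": "one-layer-1-mm",
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
        "thickness": {
          "value": 1,
          "unit": "mm"
        },
        "phase_function": {
          "family": "HG",
          "g": 0.9
        }
      },
      {
        "n": 1
      }
    ]
  },
  "source": {
    "kind": "pencil"
  },
  "detectors": {
    "radial_top": {
      "r_max": {
        "value": 5,
        "unit": "mm"
      },
      "n_bins": 100,
      "na": 1
    },
    "radial_bottom": {
      "r_max": {
        "value": 5,
        "unit": "mm"
      },
      "n_bins": 100,
      "na": 1
    }
  },
  "fluence": {
    "xlim": [
      {
        "value": -2.5,
        "unit": "mm"
      },
      {
        "value": 2.5,
        "unit": "mm"
      }
    ],
    "ylim": [
      {
        "value": -2.5,
        "unit": "mm"
      },
      {
        "value": 2.5,
        "unit": "mm"
      }
    ],
    "zlim": [
      {
        "value": 0,
        "unit": "mm"
      },
      {
        "value": 1,
        "unit": "mm"
      }
    ],
    "nx": 20,
    "ny": 20,
    "nz": 25
  }
}
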