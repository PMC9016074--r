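{
  "version": 1,
  "engine": "voxel",
  "name": "voxel-two-layer",
  "n_packets": 100000,
  "stepping": "mbl",
  "geometry": {
    "shape": [1, 1, 22],
    "voxel_size": [
      2,
      2,
      5e-05
    ],
    "labels": [1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2],
    "origin": [
      -1,
      -1
    ],
    "n_above": 1,
    "n_below": 1,
    "materials": [
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
        "phase_function": {
          "family": "HG",
          "g": 0.9
        }
      },
      {
        "mua": {
          "value": 1,
          "unit": "1/cm"
        },
        "mus": {
          "value": 100,
          "unit": "1/cm"
        },
        "n": 1.337,
        "phase_function": {
          "family": "HG",
          "g": 0.9
        }
      }
    ]
  },
  "source": {
    "kind": "pencil"
  },
  "fluence": {
    "xlim": [
      -0.002,
      0.002
    ],
    "ylim": [
      -0.002,
      0.002
    ],
    "zlim": [
      0,
      0.0011
    ],
    "nx": 8,
    "ny": 8,
    "nz": 22
  }
}
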