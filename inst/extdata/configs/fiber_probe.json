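{
  "version": 1,
  "engine": "layered",
  "name": "six-around-one-probe",
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
    "kind": "fiber",
    "core_diameter": {
      "value": 200,
      "unit": "um"
    },
    "cladding_diameter": {
      "value": 220,
      "unit": "um"
    },
    "na": 0.22,
    "n_core": {
      "material": "fused_silica",
      "wavelength": {
        "value": 500,
        "unit": "nm"
      }
    }
  },
  "layout": {
    "kind": "six_around_one",
    "core_diameter": {
      "value": 200,
      "unit": "um"
    },
    "cladding_diameter": {
      "value": 220,
      "unit": "um"
    },
    "na": 0.22,
    "n_core": 1.462,
    "tip_radius": {
      "value": 1.5,
      "unit": "mm"
    },
    "reflectivity": 0.6
  },
  "detectors": {
    "fiber_top": {
      "fiber_x": [
        0,
        0.00022,
        0.00011,
        -0.00011,
        -0.00022,
        -0.00011,
        0.00011
      ],
      "fiber_y": [
        0,
        0,
        0.00019053,
        0.00019053,
        0,
        -0.00019053,
        -0.00019053
      ],
      "core_diameter": {
        "value": 200,
        "unit": "um"
      },
      "na": 0.22
    }
  }
}
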