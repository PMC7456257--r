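{
  "form": "power_exp_full",
  "coefficient_order": ["a1", "a2", "a3", "a4", "a5"],
  "shelterwood_cut": {
    "selected": "q0.88",
    "fits": {
      "ols":   {"estimates": [0.3848, 0.6002, 1.3131, -0.4378, -1.6558],
                "std":       [0.0706, 0.0339, 0.1529,  0.1675,  0.1680]},
      "q0.75": {"estimates": [0.3543, 0.5363, 1.2589, -0.5247, -1.1415],
                "std":       [0.0623, 0.0342, 0.1050,  0.1146,  0.1459]},
      "q0.85": {"estimates": [0.3881, 0.4892, 1.2204, -0.5747, -0.9509],
                "std":       [0.0484, 0.0247, 0.1021,  0.1109,  0.1195]},
      "q0.95": {"estimates": [0.5648, 0.3607, 1.0896, -0.5414, -0.7556],
                "std":       [0.1194, 0.0508, 0.1046,  0.1388,  0.1468]},
      "q0.99": {"estimates": [0.6379, 0.2500, 0.8087, -0.4039, -0.3635],
                "std":       [0.1532, 0.0382, 0.1199,  0.1313,  0.2319]},
      "q0.88": {"estimates": [0.4030, 0.4751, 1.1811, -0.5538, -0.9125],
                "std":       [0.0574, 0.0241, 0.1160,  0.1306,  0.1426]}
    }
  },
  "uncut": {
    "selected": "q0.92",
    "fits": {
      "ols":   {"estimates": [1.1287, 0.5288, 1.4591, -0.0522, -2.3823],
                "std":       [0.3423, 0.0458, 0.1673,  0.0750,  0.3096]},
      "q0.75": {"estimates": [0.6884, 0.5346, 1.1902, -0.0289, -1.6889],
                "std":       [0.1478, 0.0442, 0.0916,  0.0592,  0.1804]},
      "q0.85": {"estimates": [0.8041, 0.4941, 1.1184,  0.0141, -1.6638],
                "std":       [0.1992, 0.0462, 0.1466,  0.1139,  0.2086]},
      "q0.95": {"estimates": [1.2189, 0.2915, 1.0042, -0.0639, -1.3446],
                "std":       [0.6316, 0.0723, 0.2289,  0.2042,  0.4596]},
      "q0.99": {"estimates": [0.9989, 0.3235, 0.8906, -0.0947, -0.9920],
                "std":       [0.6651, 0.0852, 0.2951,  0.2252,  0.4998]},
      "q0.92": {"estimates": [1.2834, 0.3950, 1.2543, -0.1097, -1.8092],
                "std":       [0.3302, 0.0550, 0.1456,  0.1245,  0.2696]}
    }
  }
}
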