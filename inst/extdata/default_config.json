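{
  "seed": [1],
  "band_length": [500],
  "step_spacing": [48.8, 14.9],
  "step_spacing_min": [15],
  "vesicle_diameter": [50, 60],
  "row_offset": [40],
  "row_jitter": [2],
  "length": {
    "beam": [75.1, 13.1],
    "step": [28.4, 7.6],
    "mast": [31.5, 4.5],
    "rib": [27.9, 7.7],
    "pin": [8.6, 3.5],
    "spar": [17.6, 6.5],
    "boom": [16, 4.8],
    "topmast": [24.6, 9.4]
  },
  "diameter": {
    "beam": [10.7, 0.7],
    "step": [21.8, 5.8],
    "mast": [22, 3],
    "rib": [9.4, 1.4],
    "pin": [5, 1],
    "spar": [7.1, 1.2],
    "boom": [6.5, 1.3],
    "topmast": [6.9, 2.1],
    "non_azm": [7, 1.5]
  },
  "step_diameter_vertical": [13.9, 2.7],
  "mast_strands": [4, 9],
  "counts": {
    "ribs_per_vesicle": [3.9, 0.6],
    "spars_per_vesicle": [2.2, 0.5],
    "booms_per_mast": [10.6, 1.8],
    "pins_per_vesicle": [4.1, 0.7],
    "pins_range": [3, 5],
    "topmasts_per_mast": [1, 2],
    "non_azm_per_vesicle": [10]
  },
  "depth": {
    "rib_site": [7.7, 3.3],
    "rib_site_max": [15],
    "spar_offset": [10.3, 4.4],
    "boom_offset": [24.2, 6.6],
    "boom_origin": [39, 7.7],
    "pin_site_max": [15]
  },
  "angle": {
    "rib": [10.6, 6.2],
    "spar": [23.3, 13.1],
    "boom": [30, 14.7]
  },
  "azimuth_halfwidth": [80],
  "activated": {
    "vacated_fraction": [0.5],
    "distance_range": [4, 42],
    "pins_within": [15],
    "undocked_pins_per_vesicle": [3.8, 0.5],
    "undocked_pin_length": [16.5, 6.5],
    "fused_omega": [true]
  },
  "bin_rules": {
    "lo": [29, 17, 4],
    "hi": [42, 24, 16],
    "boom_mean": [4.8, 5.6, 5.6],
    "boom_sd": [0.8, 1, 1],
    "spar_mean": [0.3, 1.7, 1.9],
    "spar_sd": [0.5, 0.6, 0.4],
    "rib_mean": [0, 1.3, 3.6],
    "rib_sd": [0, 0.6, 0.5],
    "pins": [false, false, true]
  },
  "compression_ratio": [0.805],
  "schema_version": [1]
}
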