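{
  "seed": 7,
  "f_wm": 1.0,
  "f_gm": 0.05,
  "thresholds": [4, 8],
  "phantom": {
    "grid_shape": [48, 48, 48],
    "voxel_size": [0.4, 0.4, 0.4],
    "n_areas": 6,
    "cortex_thickness": 2.0,
    "decay_length": 3.0,
    "intrinsic_weight": 2.0,
    "cells_per_injection": 1000,
    "exclusion_radius_range": [0.1, 1.1]
  },
  "primary_areas": [2, 3]
}
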