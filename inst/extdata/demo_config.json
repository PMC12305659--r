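{
  "seed": 1,
  "n_features": 60,
  "n_cells": 150,
  "n_treatments": 8,
  "n_active": 4,
  "n_vehicle_wells": 8,
  "n_ms_features": 60,
  "features_per_class": 4,
  "heatmap": false
}
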