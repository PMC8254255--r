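{
  "format": "emsloc-region/1",
  "spec": {
    "n_municipalities": 3,
    "urban_fraction": 0.3333,
    "age_structure_params": {
      "share_0_14": [0.1, 0.2],
      "share_65plus": [0.08, 0.25]
    },
    "n_hospitals": 1,
    "n_current_stations": 3,
    "als_fraction": 0.3333,
    "grid_resolution": 2,
    "network_style": "grid",
    "max_stations_per_town": 3,
    "seed": 1
  }
}
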