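{
  "card_size_mm": [60, 72],
  "dpi": 150,
  "fiducials": [
    [6, 6],
    [54, 6],
    [6, 64],
    [52, 58]
  ],
  "fiducial_radius_mm": 1.6,
  "zones": [
    {
      "zone_id": "std_0",
      "role": "standard",
      "center": [15, 20],
      "radius": 5,
      "standard_conc": 0
    },
    {
      "zone_id": "std_100",
      "role": "standard",
      "center": [30, 20],
      "radius": 5,
      "standard_conc": 100
    },
    {
      "zone_id": "std_300",
      "role": "standard",
      "center": [45, 20],
      "radius": 5,
      "standard_conc": 300
    },
    {
      "zone_id": "sample_1",
      "role": "sample",
      "center": [15, 32],
      "radius": 5
    },
    {
      "zone_id": "sample_2",
      "role": "sample",
      "center": [30, 32],
      "radius": 5
    },
    {
      "zone_id": "sample_3",
      "role": "sample",
      "center": [45, 32],
      "radius": 5
    },
    {
      "zone_id": "sample_4",
      "role": "sample",
      "center": [15, 44],
      "radius": 5
    },
    {
      "zone_id": "sample_5",
      "role": "sample",
      "center": [30, 44],
      "radius": 5
    },
    {
      "zone_id": "sample_6",
      "role": "sample",
      "center": [45, 44],
      "radius": 5
    }
  ],
  "color_patches": [
    {
      "center": [22, 67],
      "half_size": 2.5,
      "rgb": [220, 220, 220]
    },
    {
      "center": [30, 67],
      "half_size": 2.5,
      "rgb": [160, 160, 160]
    },
    {
      "center": [38, 67],
      "half_size": 2.5,
      "rgb": [100, 100, 100]
    }
  ]
}
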