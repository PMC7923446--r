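{
  "metadata": {
    "seed": 7,
    "config": "reference rig"
  },
  "range_stats": [
    {
      "bin_low": 0,
      "bin_high": 50,
      "flight_time": 32,
      "detection_time": 29,
      "efficiency": 91
    },
    {
      "bin_low": 50,
      "bin_high": 100,
      "flight_time": 85,
      "detection_time": 80,
      "efficiency": 94
    }
  ],
  "scenario_stats": [
    {
      "mean_D_ref": 46.4,
      "sd_D_ref": 0.100000000000001,
      "mean_H_ref": 26.7,
      "sd_H_ref": 0.0999999999999996,
      "N": 2,
      "mean_D_sys": 45.6,
      "sd_D_sys": 0.100000000000001,
      "mean_H_sys": 26.9,
      "sd_H_sys": 0.0999999999999996,
      "dD_abs": 0.799999999999997,
      "dH_abs": 0.199999999999996,
      "dD_rel": 1.72413793103448,
      "dH_rel": 0.749063670411969
    }
  ],
  "confusion": {
    "counts": [
      {
        "true": "small",
        "small": 3,
        "medium": 1,
        "large": 0,
        "_row": "small"
      },
      {
        "true": "medium",
        "small": 0,
        "medium": 0,
        "large": 0,
        "_row": "medium"
      },
      {
        "true": "large",
        "small": 0,
        "medium": 0,
        "large": 0,
        "_row": "large"
      }
    ],
    "reliability": {
      "small": 75,
      "medium": null,
      "large": null
    }
  }
}
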