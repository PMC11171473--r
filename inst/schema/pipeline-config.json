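{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "forcedosc pipeline configuration",
  "type": "object",
  "properties": {
    "study": {
      "type": "object",
      "properties": {
        "n_sham": {"type": "integer", "minimum": 0},
        "n_pin": {"type": "integer", "minimum": 0},
        "stages": {
          "type": "array",
          "items": {"enum": ["control", "Fe-9", "Fe-8", "Fe-7", "Fe-6",
                             "washout30", "nal10", "Fe-9+Nal", "Fe-8+Nal",
                             "Fe-7+Nal", "Fe-6+Nal"]},
          "description": "ordered subset of the protocol stage vocabulary"
        },
        "ring_masses": {
          "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
          "minItems": 4, "maxItems": 4,
          "description": "strictly increasing suspended masses, kg"
        },
        "mask_mass": {"type": "number", "exclusiveMinimum": 0},
        "geometry": {
          "type": "object",
          "properties": {
            "L0": {"type": "number", "exclusiveMinimum": 0},
            "width": {"type": "number", "exclusiveMinimum": 0},
            "thickness": {"type": "number", "exclusiveMinimum": 0},
            "vessel_radius": {"type": "number", "exclusiveMinimum": 0}
          }
        },
        "effect_model": {
          "type": "object",
          "description": "columns group, stage, f0_intercept (Hz), f0_slope (Hz/mmHg)"
        },
        "zeta": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "subject_sd": {"type": "number", "minimum": 0},
        "f0_noise_sd": {"type": "number", "minimum": 0},
        "noise_sigma": {"type": "number", "minimum": 0},
        "sweep": {
          "type": "object",
          "properties": {
            "r_lo": {"type": "number", "exclusiveMinimum": 0},
            "r_hi": {"type": "number", "exclusiveMinimum": 0},
            "rate_factor": {"type": "number", "exclusiveMinimum": 0},
            "settle_time": {"type": "number", "minimum": 0},
            "oversample": {"type": "number", "exclusiveMinimum": 10}
          }
        },
        "seed": {"type": "integer"}
      }
    },
    "analysis": {
      "type": "object",
      "properties": {
        "n_points": {"type": "integer", "minimum": 20},
        "window_cycles": {"type": "number", "exclusiveMinimum": 0},
        "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "adjust": {"enum": ["none", "holm"]},
        "contrast_plan": {
          "type": "object",
          "description": "columns type (between|within), groupA, stageA, groupB, stageB"
        }
      }
    }
  }
}
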