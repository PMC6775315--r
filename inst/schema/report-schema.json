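{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cgmfractal period report",
  "type": "object",
  "required": ["label", "n", "dt", "config", "increments", "spectral", "mse", "mfdfa"],
  "properties": {
    "label": {"type": "string"},
    "n": {"type": "integer", "minimum": 2},
    "dt": {"type": "number", "exclusiveMinimum": 0},
    "config": {"type": "object"},
    "increments": {
      "type": "object",
      "required": ["positive", "negative"],
      "properties": {
        "positive": {"$ref": "#/definitions/fit_comparison"},
        "negative": {"$ref": "#/definitions/fit_comparison"}
      }
    },
    "spectral": {
      "type": "object",
      "properties": {
        "beta": {"type": "number"},
        "intercept": {"type": "number"},
        "fit_band": {"type": "array", "items": {"type": "number"}},
        "n_freqs_used": {"type": "integer"},
        "signal_class": {"enum": ["fGn", "fBm", "ambiguous"]},
        "hurst": {"type": ["number", "null"]}
      }
    },
    "mse": {
      "type": "object",
      "properties": {
        "scales": {"type": "array", "items": {"type": "integer"}},
        "entropies": {"type": "array", "items": {"type": ["number", "null"]}},
        "undefined": {"type": "array", "items": {"type": "boolean"}},
        "m": {"type": "integer"},
        "r_fraction": {"type": "number"},
        "r_absolute": {"type": "number"},
        "sd_reference": {"type": "number"}
      }
    },
    "mfdfa": {
      "type": "object",
      "properties": {
        "q_grid": {"type": "array", "items": {"type": "number"}},
        "scales": {"type": "array", "items": {"type": "integer"}},
        "hq": {"type": "array", "items": {"type": ["number", "null"]}},
        "tau": {"type": "array", "items": {"type": ["number", "null"]}},
        "spectrum": {"type": "object"},
        "delta_h": {"type": "number"},
        "detrend_order": {"type": "integer"}
      }
    },
    "bootstrap": {"type": ["object", "null"]}
  },
  "definitions": {
    "fit_comparison": {
      "type": "object",
      "properties": {
        "stable": {"type": "object"},
        "gaussian": {"type": "object"},
        "loglik_stable": {"type": "number"},
        "loglik_gaussian": {"type": "number"},
        "better": {"enum": ["stable", "gaussian"]},
        "n": {"type": "integer"},
        "error": {"type": "string"}
      }
    }
  }
}
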