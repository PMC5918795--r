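{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fearmotion pipeline report",
  "type": "object",
  "required": ["provenance", "descriptives", "phase_tests"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["config_hash", "seed", "package_version", "n_subjects"]
    }
  },
  "table_columns": {
    "descriptives": ["variable", "phase", "n", "min", "max", "mean", "sd"],
    "phase_tests": ["variable", "comparison", "n", "t", "p"],
    "modality_correlations": ["variable", "phase", "n", "r", "p"],
    "symptom_correlations": ["variable", "phase", "scale", "n", "r", "p"],
    "covariate_screen": ["variable", "phase", "covariate", "n", "rho", "p"],
    "diagnosis_tests": ["variable", "phase", "n_none", "n_dx", "t", "p", "cohen_d"]
  }
}
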