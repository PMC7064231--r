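{
  "comment": "SYNTHETIC example of the user-supplied registry schema for above-ground (AGB) equations. The published AGB coefficient sets live in supplementary material that is not reprinted here; fill in real values from that source. Coefficients are decimal strings (preserved exactly); cf is the log-space correction factor applied multiplicatively at prediction time.",
  "entries": [
    {
      "scope": "C1",
      "compartment": "AGB",
      "form": "POWER",
      "predictors": ["D"],
      "coefficients": ["0.25", "2.0"],
      "cf": 1.02,
      "units": {"D": "cm", "response": "kg"},
      "provenance": "synthetic placeholder illustrating the schema"
    }
  ]
}
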