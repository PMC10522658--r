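# Illustrative ICD-9-CM code-block grouping for the six analysis causes.
# Patterns are dot-insensitive prefixes: "304.3" covers 304.30-304.39.
# This example mirrors the granularity of standard grouper software but
# is NOT a certified reproduction of any licensed crosswalk.
causes:
  alcohol: ["291", "303", "305.0"]
  substance: ["292", "304", "305.2", "305.3", "305.4", "305.5",
              "305.6", "305.7", "305.8", "305.9"]
  cannabis: ["304.3", "305.2"]
  cocaine: ["304.2", "305.6"]
  opioids: ["304.0", "304.7", "305.5"]
  sedatives: ["304.1", "305.4"]
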