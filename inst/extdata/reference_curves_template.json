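[
  {
    "name": "swimming_crawl",
    "comment": "Front-crawl swimming cost of transport vs speed. Fill in quadratic coefficients (descending powers, J/kg/m) from the source equation; the declared range is where the equation was derived — evaluation outside it warns.",
    "coefficients": [null, null, null],
    "speed_range": [0.96, 1.6]
  },
  {
    "name": "dryland_walking",
    "comment": "Dry-land walking cost of transport vs speed; quadratic coefficients from the source equation.",
    "coefficients": [null, null, null],
    "speed_range": [0.2, 2.0]
  }
]
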