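{
  "doses": [400, 600, 800, 1000],
  "variants": ["base", "low20", "high20"],
  "serum": { "slope": "table5" },
  "anchors": {
    "dose": [400, 800, 2000],
    "rrr": [0.11, 0.15, 0.17]
  },
  "cost": {
    "unit_ingredient_cost": 0.11,
    "loss_fraction": 0.41,
    "component_shares": {
      "ingredient": 0.80,
      "marketing": 0.08,
      "monitoring": 0.07,
      "other": 0.05
    },
    "cost_overrides": { "400": 15166, "600": 17493, "800": 19819, "1000": 22146 },
    "cost_per_death": 40000,
    "loss_convention": "divide"
  },
  "burden": {
    "total_deaths": 229827,
    "seed": 1
  }
}
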