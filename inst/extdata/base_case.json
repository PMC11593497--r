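{
  "strategies": [
    {"name": "INT", "mean_cost": 317.73, "mean_effect": 0.23},
    {"name": "CON", "mean_cost": 293.93, "mean_effect": 0.20}
  ],
  "cost_items": [
    {"resource_label": "IMT device", "n_units": 1, "unit_cost": 1200, "currency": "USD", "source": "market price", "period": "1 unit"},
    {"resource_label": "Treadmill", "n_units": 1, "unit_cost": 1150, "currency": "USD", "source": "market price", "period": "1 unit"},
    {"resource_label": "Resistance exercise station", "n_units": 1, "unit_cost": 1132, "currency": "USD", "source": "market price", "period": "2 units"},
    {"resource_label": "Oxygen supplier device", "n_units": 1, "unit_cost": 960, "currency": "USD", "source": "market price", "period": "2 units"},
    {"resource_label": "Rehabilitation team salaries", "n_units": 1, "unit_cost": 2347, "currency": "USD", "source": "Health Secretary", "period": "per month"},
    {"resource_label": "Supplies (cleaners, nose catheter, PPE)", "n_units": 1, "unit_cost": 1345, "currency": "USD", "source": "SIGTAP", "period": "200 units"}
  ],
  "utilities": [
    {"label": "post-ward", "utility": 0.724, "disutility": -0.061, "setting": "ward"},
    {"label": "post-ICU", "utility": 0.693, "disutility": -0.155, "setting": "ICU"}
  ],
  "horizon": {"weeks": 12, "weeks_per_year": 52},
  "exchange": {"brl_per_usd": 5.10},
  "correction": {"factor": 2.8, "applies_to": ["SIGTAP"]},
  "threshold": {"value": 40000, "currency": "BRL"},
  "psa": {"n_draws": 1000, "se_pct": 0.15},
  "owsa": {"variation": 0.15}
}
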