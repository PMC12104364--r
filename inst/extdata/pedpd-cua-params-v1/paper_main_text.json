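{
  "schema": "pedpd-cua-params-v1",
  "notes": "Values printed in the article main text. PD direct medical costs are the published annual per-patient dialysis costs; no separate first-year value is printed, so the same value is used for both cost components. CI bounds on main-text rows are synthetic conveniences for sensitivity analyses (the main text prints point values only).",
  "utilities": [
    {
      "state": "PD",
      "arm": "APD",
      "u": 0.94,
      "low": 0.9,
      "high": 0.98,
      "source": "main_text"
    },
    {
      "state": "PD",
      "arm": "CAPD",
      "u": 0.89,
      "low": 0.85,
      "high": 0.93,
      "source": "main_text"
    }
  ],
  "costs": [
    {
      "state": "PD",
      "arm": "APD",
      "component": "dmc_y1",
      "value": 496836,
      "low": 422310.6,
      "high": 571361.4,
      "source": "main_text"
    },
    {
      "state": "PD",
      "arm": "APD",
      "component": "dmc_y2plus",
      "value": 496836,
      "low": 422310.6,
      "high": 571361.4,
      "source": "main_text"
    },
    {
      "state": "PD",
      "arm": "CAPD",
      "component": "dmc_y1",
      "value": 433641,
      "low": 368594.85,
      "high": 498687.15,
      "source": "main_text"
    },
    {
      "state": "PD",
      "arm": "CAPD",
      "component": "dmc_y2plus",
      "value": 433641,
      "low": 368594.85,
      "high": 498687.15,
      "source": "main_text"
    }
  ],
  "discounting": {
    "costs": 0.03,
    "outcomes": 0.03
  },
  "settings": {
    "start_age": 1,
    "max_age": 100,
    "wtp": 160000
  },
  "budget_impact": {
    "cost_capd": 433641,
    "cost_apd": 496836,
    "p_kt": 0.079,
    "p_hd": 0.031,
    "p_death": 0.023,
    "proportion_pediatric": 0.004,
    "proportion_pd": 0.76,
    "incident_cases": 61,
    "uptake": 1,
    "years": [2023, 2032],
    "patient_counts": [618, 671, 724, 778, 831, 884, 937, 990, 1043, 1051]
  }
}
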