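{
  "factors": [
    {"name": "pH", "low": 2.5, "high": 3.5, "units": ""},
    {"name": "ACN", "low": 50, "high": 70, "units": "percent"},
    {"name": "Temperature", "low": 25, "high": 35, "units": "degC"}
  ],
  "cmas": ["RS1", "RS2", "RT_CMN", "RT_DMCMN", "RT_BDMCMN",
           "TP_CMN", "TP_DMCMN", "TP_BDMCMN"],
  "goals": [
    {"cma": "RS1", "goal": "at_least", "lower": 1.2, "upper": 2.12},
    {"cma": "RS2", "goal": "at_least", "lower": 1.2, "upper": 2.04},
    {"cma": "RT_CMN", "goal": "maximize", "lower": 2.38, "upper": 6.51},
    {"cma": "RT_DMCMN", "goal": "in_range", "lower": 2.51, "upper": 7.18},
    {"cma": "RT_BDMCMN", "goal": "minimize", "lower": 2.66, "upper": 7.9},
    {"cma": "TP_CMN", "goal": "at_least", "lower": 2000, "upper": 5800},
    {"cma": "TP_DMCMN", "goal": "at_least", "lower": 2000, "upper": 4644},
    {"cma": "TP_BDMCMN", "goal": "at_least", "lower": 2000, "upper": 3699}
  ],
  "windows": [
    {"cma": "RS1", "lsl": 1.2, "usl": 12},
    {"cma": "RS2", "lsl": 1.2, "usl": 12},
    {"cma": "RT_CMN", "lsl": 2, "usl": 7},
    {"cma": "RT_DMCMN", "lsl": 2, "usl": 7},
    {"cma": "RT_BDMCMN", "lsl": 2, "usl": 7},
    {"cma": "TP_CMN", "lsl": 2000, "usl": null},
    {"cma": "TP_DMCMN", "lsl": 2000, "usl": null},
    {"cma": "TP_BDMCMN", "lsl": 2000, "usl": null}
  ],
  "monte_carlo": {"n_draws": 100000, "seed": 1},
  "robustness": {"alpha": 0.05, "method": "regression_residual"}
}
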