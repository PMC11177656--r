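{
  "analytes": [
    {"analyte_name": "TT4", "units": "nmol/L", "cvg": 11.8, "cvi": 6.4},
    {"analyte_name": "AMH", "units": "ng/mL", "cvi": 19.2},
    {"analyte_name": "ALT", "units": "U/L", "cvg": 29.3, "cvi": 10.1},
    {"analyte_name": "TC", "units": "mmol/L", "cvg": 16.7, "cvi": 5.3},
    {"analyte_name": "UREA", "units": "mmol/L", "cvg": 21.0, "cvi": 13.9},
    {"analyte_name": "ALB", "units": "g/L", "cvg": 4.9, "cvi": 2.5,
     "lambda_grid": [0.02, 0.03, 0.05],
     "truncation_method": "biological_variation",
     "truncation_params": {"k_bv": 2}}
  ]
}
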