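# Trial evidence: baseline event rates and pooled relative risks for
# misoprostol 600 ug oral vs placebo and vs injectable oxytocin 10 iU.
# Rates are proportions; point estimates averaged across trials, low/high
# from the trials with the lowest/highest estimates. Relative-risk low/high
# are 95% confidence limits.
source_label: tuncalp2012
baseline_rates:
  placebo:
    pph:                    {point: 0.160, low: 0.120, high: 0.273}
    severe_pph:             {point: 0.030, low: 0.007, high: 0.097}
    additional_uterotonics: {point: 0.072, low: 0.007, high: 0.387}
    blood_transfusion:      {point: 0.008, low: 0.005, high: 0.009}
    shivering:              {point: 0.108, low: 0.000, high: 0.173}
    fever:                  {point: 0.016, low: 0.000, high: 0.043}
  oxytocin:
    pph:                    {point: 0.124, low: 0.004, high: 0.173}
    severe_pph:             {point: 0.027, low: 0.000, high: 0.065}
    additional_uterotonics: {point: 0.111, low: 0.044, high: 0.140}
    blood_transfusion:      {point: 0.011, low: 0.000, high: 0.016}
    shivering:              {point: 0.060, low: 0.000, high: 0.404}
    fever:                  {point: 0.010, low: 0.000, high: 0.070}
relative_risks:
  misoprostol_vs_oxytocin:
    pph:                    {point: 1.43, low: 1.34, high: 1.52}
    severe_pph:             {point: 1.36, low: 1.17, high: 1.58}
    additional_uterotonics: {point: 1.35, low: 1.10, high: 1.66}
    blood_transfusion:      {point: 0.77, low: 0.59, high: 1.02}
    shivering:              {point: 2.94, low: 2.35, high: 3.67}
    fever:                  {point: 6.77, low: 5.55, high: 8.27}
  misoprostol_vs_placebo:
    pph:                    {point: 0.77, low: 0.60, high: 0.99}
    severe_pph:             {point: 0.91, low: 0.51, high: 1.63}
    additional_uterotonics: {point: 0.86, low: 0.66, high: 1.13}
    blood_transfusion:      {point: 0.24, low: 0.06, high: 0.94}
    shivering:              {point: 3.01, low: 2.68, high: 3.39}
    fever:                  {point: 5.39, low: 3.78, high: 7.69}
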