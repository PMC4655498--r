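# Alternative evidence for the home-birth setting: placebo baseline rates
# and misoprostol-vs-placebo relative risks only (no oxytocin arm was
# reviewed in that setting). Rate bounds were not calculated (null -> NA).
source_label: hundley2013
baseline_rates:
  placebo:
    pph:                    {point: 0.122, low: null, high: null}
    severe_pph:             {point: 0.012, low: null, high: null}
    additional_uterotonics: {point: 0.054, low: null, high: null}
    blood_transfusion:      {point: 0.029, low: null, high: null}
    shivering:              {point: 0.178, low: null, high: null}
    fever:                  {point: 0.138, low: null, high: null}
relative_risks:
  misoprostol_vs_placebo:
    pph:                    {point: 0.58, low: 0.38, high: 0.87}
    severe_pph:             {point: 0.20, low: 0.04, high: 0.91}
    additional_uterotonics: {point: 0.34, low: 0.16, high: 0.73}
    blood_transfusion:      {point: 0.16, low: 0.07, high: 0.38}
    shivering:              {point: 2.18, low: 1.00, high: 4.72}
    fever:                  {point: 1.40, low: 0.16, high: 12.09}
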