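# Scalar literature constants used across the package.
pgp_expression_in_vivo: 19.4   # fmol/ug total protein, rat brain microvascular endothelium (mean across sources)
observed_kpuu_bbb:             # literature unbound brain/plasma partition coefficients
  risperidone: 0.147
  morphine: 0.23
body_weight_kg: 0.25           # typical rat, used for mg/kg dose conversion
loading_dose_duration_min: 1   # loading doses delivered as a zero-order infusion over this time (~bolus)
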