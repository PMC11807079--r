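# Drug physicochemical properties. fup and pKa are literature-typical rat
# values; they parameterize plasma protein binding and the Henderson-
# Hasselbalch unionized fraction (brain-cell partitioning). Membrane
# partitioning clearances default to 0 (membrane compartment disabled) and can
# be supplied per drug. observed_kpuu_bbb is used only for the Kp_uu-scaled
# comparison profiles.
acetaminophen:
  fup: 0.85
  pka: 9.38
  species: acid
raclopride:
  fup: 0.35
  pka: 8.9
  species: base
morphine:
  fup: 0.65
  pka: 8.21
  species: base
  observed_kpuu_bbb: 0.23
paliperidone:
  fup: 0.26
  pka: 8.76
  species: base
quinidine:
  fup: 0.25
  pka: 8.56
  species: base
risperidone:
  fup: 0.10
  pka: 8.24
  species: base
  observed_kpuu_bbb: 0.147
verapamil:
  fup: 0.10
  pka: 8.92
  species: base
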