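# Default rat CNS physiology. sa_bbb and trans_fraction are fixed literature
# values for the rat blood-brain barrier; the remaining entries are standard
# rat CNS physiological constants and are user-overridable (they are config
# data, not hard-coded model constants).
sa_bbb: 155            # BBB surface area, cm^2
trans_fraction: 0.998  # fraction of sa_bbb available transcellularly (-> 154.69 cm^2)
v_mv: 0.06             # brain microvascular volume, mL
v_ecf: 0.29            # brain extracellular fluid volume, mL
v_bc: 0.007            # brain-cell-membrane compartment volume, mL
q_cbf: 1.2             # cerebral blood flow, mL/min
q_ecf: 0.0003          # brainECF bulk flow, mL/min
ph_ecf: 7.3            # brainECF pH
body_weight: 0.25      # kg, typical rat
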