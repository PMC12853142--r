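# Bundled example drug: "risdiplam-like" oral low-hepatic-extraction
# compound eliminated by hepatic FMO3 (75%), hepatic CYP3A (20%) and renal
# excretion (5%) in adults, with high bioavailability and age-independent
# plasma protein binding. Parameters are representative and synthetic; the
# adult pathway intrinsic clearances are back-calculated from the adult
# fraction-metabolised targets and the packaged adult physiology.

name: risdiplam_like
FaFg: 0.95              # fraction absorbed x gut availability
ka: 0.7                 # 1/h first-order absorption
V_ref: 256              # L at the adult reference body weight
vol_allometric_exponent: 1.0
fu: 0.11                # unbound fraction in plasma, age-independent
BP: 1.0                 # blood-to-plasma ratio
age_independent_binding: true
adult_CL_total: 2.6     # L/h total (hepatic + renal) adult clearance
fe_renal: 0.05          # adult fraction excreted renally
renal_ontogeny: GFR_maturation
pathways:
  FMO3:
    fm_adult: 0.75
    ontogeny: risdiplam_case
  CYP3A:
    fm_adult: 0.20
    ontogeny: CYP3A_profile1
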