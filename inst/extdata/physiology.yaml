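# Age-dependent system (anatomy/physiology) constants.
#
# Editable, versioned constants file: all age functions used to scale adult
# drug parameters to children live here so that the assumptions can be kept
# consistent with a whole-body PBPK platform by swapping this one file.
# Sources are representative published forms: growth curves fitted to
# standard median weight/height-for-age tables, liver weight allometric in
# body weight, microsomal protein per gram liver (MPPGL) as the cubic
# log10-age polynomial of Barter et al. (2008, Drug Metab Dispos), body
# surface area by Haycock, hepatic blood flow scaled by BSA, and the
# GFR_maturation profile from ontogeny_profiles.yaml.

version: 1
adult_reference_age: 35

weight_for_age:   # kg; base + infancy saturating term + pubertal sigmoid
  base: 3.778
  infancy_gain: 22.525
  infancy_age50: 2.830
  puberty_gain: 48.277
  puberty_hill: 5.147
  puberty_age50: 12.931

height_for_age:   # cm; same functional form
  base: 50.953
  infancy_gain: 82.832
  infancy_age50: 2.421
  puberty_gain: 48.090
  puberty_hill: 4.631
  puberty_age50: 10.288

liver_weight:     # g = coef * body_weight_kg ^ exponent
  coef: 45.5
  exponent: 0.86

mppgl:            # mg microsomal protein / g liver
  log10_intercept: 1.407
  age_linear: 0.0158
  age_quadratic: -0.00038
  age_cubic: 0.0000024

bsa:              # m^2, Haycock: coef * WT^wt_exp * HT^ht_exp
  coef: 0.024265
  wt_exp: 0.5378
  ht_exp: 0.3964

hepatic_blood_flow:   # L/h; adult value scaled by BSA ratio
  adult_LPH: 90

gfr:
  profile: GFR_maturation   # normalised to 1 at the adult reference age
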