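# Fixed (non-estimable) ontogeny profiles used as system inputs.
#
# These are editable constants with provenance notes; they are inputs to the
# structural model, never estimands. The two hepatic CYP3A profiles are
# deliberately different in infancy, reflecting the disagreement between
# published maturation functions for the same enzyme; swap or edit entries
# to match the whole-body PBPK platform in use.

CYP3A_profile1:
  family: eq4b
  parameters:
    F_birth: 0.11
    Age_up50: 0.64
    gamma_u: 1.91
    FRD: 0.0
    Age_down50: 10.0
    gamma_d: 2.0
    AGECAP: 25.0
  note: >
    Hepatic CYP3A maturation, fast-maturing sigmoid in the style of
    Salem et al. (2014, Clin Pharmacokinet 53:625-636): ~50% of adult
    activity around 0.64 years, capped at 1 from 25 years.

CYP3A_profile2:
  family: eq4b
  parameters:
    F_birth: 0.20
    Age_up50: 1.0
    gamma_u: 0.8
    FRD: 0.0
    Age_down50: 10.0
    gamma_d: 2.0
    AGECAP: 25.0
  note: >
    Hepatic CYP3A maturation, slower shallow sigmoid in the style of
    Upreti & Wahlstrom (2016, J Clin Pharmacol 56:266-283, as modified in
    later platform releases); disagrees with profile 1 through infancy.

GFR_maturation:
  family: eq1_sigmoid_up
  parameters:
    F_birth: 0.35
    F_max: 1.0
    Age_up50: 0.4
    gamma_u: 1.2
  note: >
    Glomerular filtration rate maturation expressed as fraction of adult
    GFR: ~35% of adult at term birth, adult capacity reached during early
    childhood (sigmoid in postnatal age, in the spirit of Rhodin et al.
    2009, Pediatr Nephrol 24:67-76 recast on a postnatal-age axis).

risdiplam_case:
  family: eq4a
  parameters:
    F_birth: 0.20
    Age_up50: 0.2797
    gamma_u: 1.6
    FRD: 0.68414
    Age_down50: 4.8517
    gamma_d: 4.3344
  note: >
    Bell-shaped example truth bundled with the synthetic case study:
    hepatic FMO3-like activity rising from 20% of adult at birth to a
    maximum of ~3x adult at 2 years of age, then declining to the adult
    level. Calibrated in-package; synthetic, not the proprietary risdiplam
    estimate.
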