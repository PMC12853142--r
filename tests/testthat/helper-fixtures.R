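# Shared fixtures: all built in code at test time.

# Small wide-age-range sparse design for fast estimation tests.
small_design <- function(n_per_arm = 40, bsv = c(CL_int = 0.3, V = 0.2),
                         residual = c(prop = 0.15, add = 0.1),
                         visits_days = c(14, 112),
                         samples_per_visit = c(2, 3)) {
  trial_design(
    arms = list(
      list(age_range = c(1 / 6, 2), n = n_per_arm,
           dose = list(type = "mg_per_kg", value = 0.2),
           age_dist = "log_uniform"),
      list(age_range = c(2, 18), n = n_per_arm,
           dose = list(type = "mg_per_kg", value = 0.25, cap_mg = 5)),
      list(age_range = c(18, 61), n = n_per_arm,
           dose = list(type = "fixed_mg", value = 5))),
    visits_days = visits_days, samples_per_visit = samples_per_visit,
    bsv = bsv, residual = residual, name = "small")
}

# Drug identical to the bundled one but with a flat (no-maturation) target
# pathway: data generated from it carry no ontogeny signal.
flat_target_drug <- function() {
  fo <- flat_ontogeny()
  set_pathway_ontogeny(load_drug_config(), "FMO3", fo$model, fo$params)
}

# A one-subject dataset with a steady-state dose and a few observations.
one_subject_dataset <- function(dv = c(50, 40, 30), tads = c(2, 8, 20),
                                age = 35, wt = 70, amt = 5) {
  data.frame(ID = 1, TIME = c(0, tads), AMT = c(amt, rep(0, length(tads))),
             EVID = c(1, rep(0, length(tads))),
             MDV = c(1, rep(0, length(tads))),
             DV = c(0, dv), AGE = age, WT = wt,
             SS = c(1, rep(0, length(tads))), II = c(24, rep(0, length(tads))))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
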