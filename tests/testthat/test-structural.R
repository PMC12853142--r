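drug <- load_drug_config()

test_that("well-stirred liver model matches closed-form hand values", {
  ws <- well_stirred(CL_int = 10, Q_H = 90, fu_B = 1)
  expect_equal(ws$CL_H, 9)
  expect_equal(ws$F_H, 0.9)
  ws0 <- well_stirred(0, 90, 0.5)
  expect_identical(ws0$CL_H, 0)
  expect_identical(ws0$F_H, 1)
  wsf <- well_stirred(1e9, 90, 1)
  expect_equal(wsf$CL_H, 90, tolerance = 1e-6)
  expect_lt(wsf$F_H, 1e-6)
  expect_true(all(well_stirred(c(1, 10, 100), 90, 0.5)$CL_H < 90))
  expect_error(well_stirred(10, 0, 1), "Q_H")
  expect_error(well_stirred(10, 90, 1.5), "fu_B")
})

test_that("adult whole-liver intrinsic clearance matches the hand back-calculation", {
  adult <- adult_reference_profile()
  cl_h <- (1 - 0.05) * 2.6           # config: CL_total 2.6, fe 0.05
  fu_b <- 0.11 / 1.0
  clint_hand <- adult$Q_H * cl_h / (fu_b * (adult$Q_H - cl_h))
  expect_equal(drug$CLint_adult_total, clint_hand, tolerance = 1e-10)
  # per-mg values scale back to whole-liver clearances exactly
  scaling <- adult$MPPGL * adult$liver_weight * 60 / 1e6
  expect_equal(unname(drug$CLint_per_mg * scaling),
               unname(drug$CLint_pathway), tolerance = 1e-12)
  # evaluated at the adult age with the bundled ontogenies
  cli <- hepatic_intrinsic_clearance(drug, adult, adult_reference_age())
  expect_equal(cli$total, clint_hand, tolerance = 1e-3)
  # zero intrinsic clearance everywhere gives zero total
  d0 <- drug
  d0$CLint_per_mg[] <- 0
  expect_identical(hepatic_intrinsic_clearance(d0, adult, 35)$total, 0)
})

test_that("ontogeny scales pathway intrinsic clearance linearly", {
  flat3 <- ontogeny_parameters(F_birth = 3, F_max = 3, Age_up50 = 1,
                               gamma_u = 1)
  fo <- flat_ontogeny()
  base <- set_pathway_ontogeny(drug, "FMO3", fo$model, fo$params)
  trip <- set_pathway_ontogeny(drug, "FMO3", ontogeny_model("eq1_sigmoid_up"),
                               flat3)
  adult <- adult_reference_profile()
  c1 <- hepatic_intrinsic_clearance(base, adult, 35)$per_pathway
  c3 <- hepatic_intrinsic_clearance(trip, adult, 35)$per_pathway
  expect_equal(c3[, "FMO3"], 3 * c1[, "FMO3"])
  expect_equal(c3[, "CYP3A"], c1[, "CYP3A"])
})

test_that("adult pathway partition reproduces the configured 75/20/5", {
  fm <- fraction_metabolized(drug, age = adult_reference_age())
  expect_equal(unname(fm["FMO3"]), 0.75, tolerance = 1e-3)
  expect_equal(unname(fm["CYP3A"]), 0.20, tolerance = 1e-3)
  expect_equal(unname(fm["renal"]), 0.05, tolerance = 1e-3)
  expect_equal(sum(fm), 1, tolerance = 1e-12)
})

test_that("tripled FMO3 activity shifts the partition as the hand arithmetic says", {
  # equal system scalars (adult age), FMO3 activity x3: in the
  # low-extraction limit fm_FMO3 = 0.75*3 / (0.75*3 + 0.20 + 0.05) = 0.90
  flat3 <- ontogeny_parameters(F_birth = 3, F_max = 3, Age_up50 = 1,
                               gamma_u = 1)
  d3 <- set_pathway_ontogeny(drug, "FMO3", ontogeny_model("eq1_sigmoid_up"),
                             flat3)
  fm <- fraction_metabolized(d3, age = adult_reference_age())
  expect_lt(abs(unname(fm["FMO3"]) - 0.90), 0.005)
  expect_lt(abs(unname(fm["CYP3A"]) - 0.08), 0.005)
  expect_lt(abs(unname(fm["renal"]) - 0.02), 0.005)
})

test_that("single hepatic pathway with no renal elimination has fm = 1", {
  cfg <- yaml::read_yaml(example_drug_path())
  cfg$fe_renal <- 0
  cfg$pathways <- list(FMO3 = list(fm_adult = 1.0,
                                   ontogeny = "risdiplam_case"))
  d1 <- load_drug_config(cfg)
  fm <- fraction_metabolized(d1, age = 5)
  expect_equal(unname(fm["FMO3"]), 1)
})

test_that("random effects enter the intrinsic clearance before the well-stirred transform", {
  adult <- adult_reference_profile()
  base <- individual_parameters(drug, adult, 35)
  up <- individual_parameters(drug, adult, 35, eta = list(CL_int = log(2)))
  expect_equal(up$CL_int_total, 2 * base$CL_int_total)
  # hepatic clearance must equal the well-stirred transform of the doubled
  # CL_int, not double the transformed clearance
  ws <- well_stirred(2 * base$CL_int_total, adult$Q_H, drug$fu_B)
  expect_equal(up$CL_H, ws$CL_H, tolerance = 1e-12)
  expect_lt(up$CL_H, 2 * base$CL_H)
  # volume halves when weight halves (allometric exponent 1)
  half <- profile_for_age(35, body_weight = adult$body_weight / 2)
  vh <- individual_parameters(drug, half, 35)
  expect_equal(vh$V, base$V / 2)
})

test_that("closed-form concentrations agree with the ODE integrator", {
  params <- individual_parameters(drug, age = 35)
  params <- lapply(params, `[`, 1)
  dosing <- data.frame(time = c(0, 24, 48), amt = c(5, 5, 5))
  times <- c(0, seq(0.5, 70, by = 3.5))
  ca <- predict_concentration(params, dosing, times, backend = "analytic")
  co <- predict_concentration(params, dosing, times, backend = "ode")
  expect_identical(ca[1], 0)
  expect_lt(max(abs(ca[-1] - co[-1]) / pmax(co[-1], 1e-12)), 1e-6)
  # steady-state records agree with the expanded-dose ODE solution
  ss_dose <- data.frame(time = 0, amt = 5, ss = 1, ii = 24)
  tss <- seq(0.5, 23.5, by = 1.5)
  cs <- predict_concentration(params, ss_dose, tss)
  cso <- predict_concentration(params, ss_dose, tss, backend = "ode")
  expect_lt(max(abs(cs - cso) / cso), 1e-5)
})

test_that("AUC identities hold under linear PK", {
  expect_equal(auc_ss(list(F = 1, CL = 10), 100), 10 * 1000)
  expect_equal(auc_ss(list(F = 0.5, CL = 20), 100),
               auc_ss(list(F = 0.5, CL = 10), 100) / 2)
  params <- individual_parameters(drug, age = 35)
  params <- lapply(params, `[`, 1)
  # numeric integral of the single-dose curve vs Dose*F/CL
  f <- function(t) predict_concentration(params, data.frame(time = 0,
                                                            amt = 5), t)
  auc_num <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
  expect_rel(auc_num, auc_ss(params, 5), 1e-3)
  expect_error(auc_ss(list(F = 1, CL = 0), 5), "CL")
})

test_that("mass-balance simulation recovers the clearance-level partition", {
  mb <- mass_balance_fractions(drug, age = adult_reference_age())
  expect_equal(sum(mb), 1, tolerance = 1e-9)
  expect_lt(abs(mb[["FMO3"]] - 0.75), 0.005)
  expect_lt(abs(mb[["CYP3A"]] - 0.20), 0.005)
  expect_lt(abs(mb[["renal"]] - 0.05), 0.005)
  # and at a paediatric age the simulated and analytic partitions agree
  fm2 <- fraction_metabolized(drug, age = 2)
  mb2 <- mass_balance_fractions(drug, age = 2, dose = 3)
  expect_lt(max(abs(mb2 - fm2[names(mb2)])), 0.005)
})

test_that("the bundled drug stays in the low-extraction regime at all ages", {
  ages <- c(1 / 12, 0.25, 0.5, 1, 2, 5, 10, 18, 35, 60)
  physio <- profile_for_age(ages)
  ip <- individual_parameters(drug, physio, ages)
  expect_true(all(ip$CL_H / physio$Q_H < 0.3))
  expect_true(all(ip$CL_H < physio$Q_H))
  # fm_CYP3A decreases as FMO3 activity rises with everything else fixed
  fo <- flat_ontogeny()
  d_cflat <- set_pathway_ontogeny(drug, "CYP3A", fo$model, fo$params)
  fm <- fraction_metabolized(d_cflat, age = c(0.25, 2))
  act <- evaluate_ontogeny(drug$pathway_ontogeny$FMO3$model,
                           drug$pathway_ontogeny$FMO3$params, c(0.25, 2))
  expect_gt(act[2], act[1])
  expect_lt(fm[2, "CYP3A"] / sum(fm[2, c("CYP3A", "FMO3")]),
            fm[1, "CYP3A"] / sum(fm[1, c("CYP3A", "FMO3")]))
})
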