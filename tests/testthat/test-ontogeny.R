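test_that("registry exposes the expected families and free-parameter counts", {
  reg <- ontogeny_registry()
  expect_setequal(names(reg),
                  c("eq1_sigmoid_up", "eq2_gompertz_up", "eq3a_sigmoid_down",
                    "eq3b_exp_down", "eq4a", "eq4b", "eq4c", "eq4d", "eq4e",
                    "eq4f", "eq4g_double_sigmoid"))
  bells <- paste0("eq4", letters[1:6])
  counts <- vapply(reg[bells], `[[`, 0L, "n_free")
  expect_true(all(counts %in% c(6L, 7L)))
  expect_lte(max(counts), 7L)
  expect_identical(reg$eq4g_double_sigmoid$n_free, 9L)
  for (m in reg) {
    expect_true(all(m$roster %in% c("F_birth", "F_max", "F_min", "Age_up50",
                                    "gamma_u", "Age_down50", "gamma_d",
                                    "FRD", "K", "AGECAP")))
  }
  expect_error(ontogeny_model("eq99"), "unknown ontogeny family")
})

test_that("sigmoid rising limb hits its Hill midpoint at Age_up50", {
  p <- ontogeny_parameters(F_birth = 0, F_max = 2.4, Age_up50 = 0.7,
                           gamma_u = 1.8)
  expect_equal(evaluate_ontogeny("eq1_sigmoid_up", p, 0.7), 2.4 / 2)
  # with a nonzero floor the limb is halfway through its total rise
  p2 <- ontogeny_parameters(F_birth = 0.3, F_max = 1.9, Age_up50 = 0.5,
                            gamma_u = 2.2)
  expect_equal(evaluate_ontogeny("eq1_sigmoid_up", p2, 0.5),
               0.3 + (1.9 - 0.3) / 2)
})

test_that("capped families return exactly 1 at and beyond AGECAP", {
  p <- ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.4, gamma_u = 2,
                           FRD = 0.5, Age_down50 = 3, gamma_d = 4,
                           AGECAP = 12)
  expect_identical(evaluate_ontogeny("eq4b", p, c(12, 22, 40)),
                   c(1, 1, 1))
  pg <- ontogeny_parameters(F_birth = 0.1, K = 1.5, F_max = 2,
                            gamma_u = 1.5, Age_up50 = 0.5, FRD = 0.4,
                            gamma_d = 3, Age_down50 = 4, AGECAP = 18)
  expect_identical(evaluate_ontogeny("eq4g_double_sigmoid", pg, 28), 1)
})

test_that("bell-shaped product evaluates to the frozen hand calculation", {
  # U(2) = 0.1 + 3.9 * 4/(0.09 + 4); D(2) = 1 - 0.75 * 8/(512 + 8);
  # product worked out by hand before implementation
  p <- ontogeny_parameters(F_birth = 0.1, F_max = 4.0, gamma_u = 2,
                           Age_up50 = 0.3, FRD = 0.75, gamma_d = 3,
                           Age_down50 = 8.0)
  expect_equal(evaluate_ontogeny("eq4a", p, 2.0), 3.8690173,
               tolerance = 1e-7)
})

test_that("bundled risdiplam_case profile peaks near 3x adult at 2 years", {
  prof <- fixed_profile("risdiplam_case")
  grid <- seq(0, 18, by = 0.01)
  f <- evaluate_ontogeny(prof$model, prof$params, grid)
  expect_equal(max(f), 3.0, tolerance = 0.02)
  expect_equal(grid[which.max(f)], 2.0, tolerance = 0.3)
  expect_equal(evaluate_ontogeny(prof$model, prof$params, 35), 1,
               tolerance = 0.01)
  expect_equal(f[1], 0.2, tolerance = 1e-8)
})

test_that("monotone families are monotone and bells exceed 1 inside", {
  grid <- seq(0, 30, by = 0.05)
  up1 <- evaluate_ontogeny("eq1_sigmoid_up",
                           ontogeny_parameters(F_birth = 0.1, F_max = 1,
                                               Age_up50 = 0.5,
                                               gamma_u = 1.4), grid)
  up2 <- evaluate_ontogeny("eq2_gompertz_up",
                           ontogeny_parameters(F_birth = 0.05, F_max = 1,
                                               K = 0.8), grid)
  expect_true(all(diff(up1) >= 0))
  expect_true(all(diff(up2) >= 0))
  dn1 <- evaluate_ontogeny("eq3a_sigmoid_down",
                           ontogeny_parameters(F_birth = 3, F_min = 1,
                                               Age_down50 = 2,
                                               gamma_d = 2.5), grid)
  dn2 <- evaluate_ontogeny("eq3b_exp_down",
                           ontogeny_parameters(F_birth = 2.5, F_min = 1,
                                               K = 0.9), grid)
  expect_true(all(diff(dn1) <= 0))
  expect_true(all(diff(dn2) <= 0))

  bells <- list(
    eq4a = ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2,
                               FRD = 0.6, Age_down50 = 4, gamma_d = 3),
    eq4b = ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2,
                               FRD = 0.6, Age_down50 = 4, gamma_d = 3,
                               AGECAP = 25),
    eq4c = ontogeny_parameters(F_birth = 0.2, K = 2, gamma_u = 1,
                               FRD = 0.6, Age_down50 = 4, gamma_d = 3),
    eq4d = ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2,
                               FRD = 0.6, K = 0.4, gamma_d = 2),
    eq4e = ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2,
                               FRD = 0.6, Age_down50 = 4, gamma_d = 3),
    eq4f = ontogeny_parameters(F_birth = 0.2, K = 2, gamma_u = 1,
                               FRD = 0.6, Age_down50 = 4, gamma_d = 3))
  for (fam in names(bells)) {
    f <- evaluate_ontogeny(fam, bells[[fam]], grid)
    expect_equal(f[1], 0.2, tolerance = 1e-10,
                 label = sprintf("%s F(0)", fam))
    expect_gt(max(f[grid > 0 & grid < 20]), 1)
  }
})

test_that("admissible saturated parameter sets normalise to 1 at the adult age", {
  a_ref <- adult_reference_age()
  sets <- list(
    list("eq1_sigmoid_up",
         ontogeny_parameters(F_birth = 0.2, F_max = 1, Age_up50 = 0.3,
                             gamma_u = 3.5)),
    list("eq2_gompertz_up",
         ontogeny_parameters(F_birth = 0.2, F_max = 1, K = 1)),
    list("eq3a_sigmoid_down",
         ontogeny_parameters(F_birth = 3, F_min = 1, Age_down50 = 1,
                             gamma_d = 6)),
    list("eq3b_exp_down",
         ontogeny_parameters(F_birth = 2.5, F_min = 1, K = 1)),
    list("eq4a",
         ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 3.5,
                             FRD = 0.5, Age_down50 = 2, gamma_d = 7)),
    list("eq4c",
         ontogeny_parameters(F_birth = 0.2, K = 2, gamma_u = 1, FRD = 0.5,
                             Age_down50 = 2, gamma_d = 7)),
    list("eq4d",
         ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 3.5,
                             FRD = 0.5, K = 0.5, gamma_d = 2)),
    list("eq4e",
         ontogeny_parameters(F_birth = 0.2, Age_up50 = 0.3, gamma_u = 3.5,
                             FRD = 0.5, Age_down50 = 2, gamma_d = 7)),
    list("eq4f",
         ontogeny_parameters(F_birth = 0.2, K = 2, gamma_u = 1, FRD = 0.5,
                             Age_down50 = 2, gamma_d = 7)))
  for (s in sets) {
    expect_lt(abs(evaluate_ontogeny(s[[1]], s[[2]], a_ref) - 1), 1e-6,
              label = s[[1]])
  }
  # capped families are exactly 1 there by construction
  expect_identical(
    evaluate_ontogeny("eq4b", ontogeny_parameters(
      F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2, FRD = 0.6,
      Age_down50 = 4, gamma_d = 3, AGECAP = 25), a_ref), 1)
})

test_that("parameter validation reports violations and passes valid sets", {
  m <- ontogeny_model("eq4a")
  rep1 <- validate_ontogeny_parameters(m, ontogeny_parameters(
    F_birth = 0.2, Age_up50 = 0.3, gamma_u = 2, FRD = 1.2,
    Age_down50 = 4, gamma_d = 3))
  expect_true(any(grepl("FRD", rep1)))
  rep2 <- validate_ontogeny_parameters(
    ontogeny_model("eq1_sigmoid_up"),
    ontogeny_parameters(F_birth = 0.2, F_max = 1, Age_up50 = 0.3,
                        gamma_u = 0))
  expect_true(any(grepl("gamma_u", rep2)))
  rep3 <- validate_ontogeny_parameters(
    ontogeny_model("eq1_sigmoid_up"),
    ontogeny_parameters(F_birth = 0.2, F_max = 1, Age_up50 = 0.3,
                        gamma_u = 2))
  expect_length(rep3, 0)
  # missing roster parameter is reported, and evaluation refuses it
  rep4 <- validate_ontogeny_parameters(m, ontogeny_parameters(F_birth = 0.2))
  expect_true(any(grepl("missing", rep4)))
  expect_error(evaluate_ontogeny(m, ontogeny_parameters(F_birth = 0.2), 1),
               "invalid parameters")
  # inconsistent F_max for a bell family is flagged
  rep5 <- validate_ontogeny_parameters(m, ontogeny_parameters(
    F_birth = 0.2, F_max = 9, Age_up50 = 0.3, gamma_u = 2, FRD = 0.5,
    Age_down50 = 4, gamma_d = 3))
  expect_true(any(grepl("F_max", rep5)))
  expect_error(evaluate_ontogeny(m, ontogeny_parameters(F_birth = 0.2,
                                                        Age_up50 = 0.3,
                                                        gamma_u = 2,
                                                        FRD = 0.5,
                                                        Age_down50 = 4,
                                                        gamma_d = 3),
                                 -1), "ages must be")
})

test_that("fixed profiles load, disagree in infancy, and normalise", {
  p1 <- fixed_profile("CYP3A_profile1")
  p2 <- fixed_profile("CYP3A_profile2")
  expect_identical(
    evaluate_ontogeny(p1$model, p1$params, adult_reference_age()), 1)
  v1 <- evaluate_ontogeny(p1$model, p1$params, 1)
  v2 <- evaluate_ontogeny(p2$model, p2$params, 1)
  expect_gt(abs(v1 - v2), 0.05)
  g <- fixed_profile("GFR_maturation")
  g0 <- evaluate_ontogeny(g$model, g$params, 0)
  expect_gt(g0, 0)
  expect_lt(g0, 1)
  expect_error(fixed_profile("no_such_profile"), "unknown fixed profile")
})

test_that("ontogeny config serialisation round-trips losslessly", {
  prof <- fixed_profile("risdiplam_case")
  cfg <- ontogeny_to_config(prof$model, prof$params)
  back <- ontogeny_from_config(cfg)
  expect_identical(back$model$family_id, prof$model$family_id)
  expect_equal(as.numeric(back$params), as.numeric(prof$params))
  expect_identical(names(back$params), names(prof$params))
  ages <- c(0, 0.5, 2, 10, 35)
  expect_identical(evaluate_ontogeny(back$model, back$params, ages),
                   evaluate_ontogeny(prof$model, prof$params, ages))
})
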