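drug <- load_drug_config()

test_that("Laplace equals the closed-form linear-Gaussian marginal OFV", {
  set.seed(21)
  subjects <- lapply(1:6, function(i) {
    n <- 3 + i %% 3
    a <- 5 + runif(n, 0, 2)
    b <- runif(n, 0.5, 2)
    eta_true <- rnorm(1, 0, 0.4)
    list(a = a, b = b, y = a + b * eta_true + rnorm(n, 0, 0.3))
  })
  omega2 <- 0.16
  sig <- 0.3
  pkg <- laplace_ofv_general(
    lapply(subjects, function(s) {
      force(s)
      list(y = s$y, f = function(eta) s$a + s$b * eta[1])
    }),
    omega = matrix(omega2, 1, 1), sigma = c(prop = 0, add = sig))
  oracle <- oracle_ofv_lingauss(subjects, omega2, sig)
  expect_lt(abs(as.numeric(pkg) - oracle), 1e-8)
})

test_that("Laplace agrees with 21-node adaptive Gauss-Hermite on small nonlinear cases", {
  skip_if_not_installed("pracma")
  make_case <- function(seed, f_builder, omega, sigma, n_sub = 3,
                        n_obs = 3) {
    set.seed(seed)
    q <- nrow(omega)
    lapply(seq_len(n_sub), function(i) {
      t <- sort(runif(n_obs, 0.5, 12))
      eta <- as.numeric(chol(omega) %*% rnorm(q))
      f <- f_builder(t)
      mu <- f(eta)
      y <- pmax(mu * (1 + sigma[["prop"]] * rnorm(n_obs)) +
                  sigma[["add"]] * rnorm(n_obs), 1e-3)
      list(y = y, f = f)
    })
  }
  cases <- list(
    list(omega = matrix(0.09, 1, 1), sigma = c(prop = 0, add = 0.5),
         f = function(t) function(eta) 10 * exp(-0.3 * exp(eta[1]) * t)),
    list(omega = matrix(0.16, 1, 1), sigma = c(prop = 0.15, add = 0.05),
         f = function(t) function(eta) 20 * exp(eta[1]) * exp(-0.2 * t)),
    list(omega = matrix(0.04, 1, 1), sigma = c(prop = 0.1, add = 0.1),
         f = function(t) function(eta) {
           8 * exp(eta[1]) * t / (1.5 + t)
         }),
    list(omega = diag(c(0.09, 0.04)), sigma = c(prop = 0, add = 0.4),
         f = function(t) function(eta) {
           12 * exp(eta[1]) * exp(-0.25 * exp(eta[2]) * t)
         }),
    list(omega = diag(c(0.12, 0.05)), sigma = c(prop = 0.12, add = 0.02),
         f = function(t) function(eta) {
           15 * exp(eta[1]) * (exp(-0.1 * t) - exp(-exp(eta[2]) * t))
         }))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    subjects <- make_case(100 + k, cs$f, cs$omega, cs$sigma)
    lap <- as.numeric(laplace_ofv_general(subjects, cs$omega, cs$sigma))
    agh <- oracle_ofv_agh(subjects, cs$omega, cs$sigma, n_nodes = 21)
    expect_lt(abs(lap - agh), 0.1, label = sprintf("case %d", k))
  }
})

test_that("the PK-model Laplace OFV matches quadrature on a 3-subject case", {
  skip_if_not_installed("pracma")
  drug_f <- flat_target_drug()   # spec below forces the target flat too
  des <- small_design(n_per_arm = 1, visits_days = 14,
                      samples_per_visit = c(2, 2))
  dat <- simulate_trial(des, drug_f, seed = 31)
  spec <- popmodel_spec(drug_f, family = NULL, eta_on = "CL_int",
                        omega_init = c(CL_int = 0.09))
  lap <- laplace_ofv(spec, dat)
  # oracle: same structural model through exported pieces, integrated by
  # adaptive Gauss-Hermite instead of Laplace
  ids <- unique(dat$ID)
  subjects <- lapply(ids, function(id) {
    rows <- dat[dat$ID == id, ]
    obs <- rows[rows$EVID == 0, ]
    dose <- rows[rows$EVID == 1, ][1, ]
    age <- obs$AGE[1]; wt <- obs$WT[1]
    physio <- profile_for_age(age, body_weight = wt)
    f <- function(eta) {
      ip <- individual_parameters(spec$drug, physio, age,
                                  eta = list(CL_int = eta[1]))
      ip1 <- lapply(ip, `[`, 1)
      predict_concentration(
        ip1, data.frame(time = dose$TIME, amt = dose$AMT, ss = 1, ii = 24),
        obs$TIME)
    }
    list(y = obs$DV, f = f)
  })
  agh <- oracle_ofv_agh(subjects, matrix(0.09, 1, 1),
                        c(prop = spec$sigma[["prop"]],
                          add = spec$sigma[["add"]]), n_nodes = 21)
  expect_lt(abs(as.numeric(lap) - agh), 0.1)
})

test_that("compiled and reference backends agree", {
  dat <- simulate_trial(small_design(n_per_arm = 5), drug, seed = 8)
  spec <- popmodel_spec(drug, family = "eq4a")
  oc <- laplace_ofv(spec, dat, backend = "cpp")
  or <- laplace_ofv(spec, dat, backend = "r")
  expect_lt(abs(as.numeric(oc) - as.numeric(or)), 1e-3)
})

test_that("omega -> 0 degenerates to the fixed-effect weighted deviance", {
  drug_f <- flat_target_drug()
  dat <- one_subject_dataset()
  spec <- popmodel_spec(drug_f, family = NULL)
  ofv0 <- laplace_ofv(spec, dat, omega = c(CL_int = 0, V = 0))
  # hand-computed weighted deviance at eta = 0
  physio <- profile_for_age(35, body_weight = 70)
  ip <- individual_parameters(drug_f, physio, 35)
  ip1 <- lapply(ip, `[`, 1)
  f <- predict_concentration(ip1, data.frame(time = 0, amt = 5, ss = 1,
                                             ii = 24), c(2, 8, 20))
  g2 <- (spec$sigma[["prop"]] * f)^2 + spec$sigma[["add"]]^2
  dev_hand <- sum((c(50, 40, 30) - f)^2 / g2 + log(2 * pi * g2))
  expect_equal(as.numeric(ofv0), dev_hand, tolerance = 1e-8)
})

test_that("noise-free rich data returns the generating fixed effects", {
  des <- small_design(n_per_arm = 12, bsv = c(CL_int = 0, V = 0),
                      residual = c(prop = 1e-3, add = 1e-6),
                      samples_per_visit = c(3, 3))
  dat <- simulate_trial(des, drug, seed = 9)
  truth <- fixed_profile("risdiplam_case")
  spec <- popmodel_spec(
    drug, family = "eq4a",
    ontogeny_init = truth$params[ontogeny_model("eq4a")$roster],
    eta_on = "CL_int", omega_init = c(CL_int = 1e-4),
    sigma_init = c(prop = 1e-3, add = 1e-6),
    fixed = c(names(truth$params[ontogeny_model("eq4a")$roster]),
              "omega_CL_int", "sigma_prop", "sigma_add"))
  fit <- fit_population_model(
    spec, dat,
    inits = list(CLint_adult = drug$CLint_adult_total * 1.3,
                 V_ref = drug$V_ref * 0.8, ka = drug$ka * 1.2),
    n_starts = 1, compute_se = FALSE)
  expect_rel(fit$theta[["CLint_adult"]], drug$CLint_adult_total, 0.005)
  expect_rel(fit$theta[["V_ref"]], drug$V_ref, 0.005)
  expect_rel(fit$theta[["ka"]], drug$ka, 0.005)
})

test_that("an all-fixed fit evaluates the OFV without iterating", {
  dat <- simulate_trial(small_design(n_per_arm = 3), drug, seed = 10)
  spec <- popmodel_spec(drug, family = NULL,
                        fixed = c("CLint_adult", "V_ref", "ka",
                                  "omega_CL_int", "omega_V", "sigma_prop",
                                  "sigma_add"))
  fit <- fit_population_model(spec, dat)
  expect_identical(fit$n_iter, 0L)
  expect_equal(fit$ofv, as.numeric(laplace_ofv(spec, dat)), tolerance = 1e-8)
})

test_that("empirical Bayes estimates behave at the degenerate prior and recover true effects", {
  des <- small_design(n_per_arm = 10, residual = c(prop = 0.02, add = 1e-3),
                      samples_per_visit = c(4, 4),
                      visits_days = c(14, 112, 365))
  dat <- simulate_trial(des, drug, seed = 12)
  truth <- fixed_profile("risdiplam_case")
  all_names <- c("CLint_adult", "V_ref", "ka",
                 ontogeny_model("eq4a")$roster)
  spec <- popmodel_spec(
    drug, family = "eq4a",
    ontogeny_init = truth$params[ontogeny_model("eq4a")$roster],
    sigma_init = c(prop = 0.02, add = 1e-3),
    fixed = c(all_names, "omega_CL_int", "omega_V", "sigma_prop",
              "sigma_add"))
  fit <- fit_population_model(spec, dat)
  ebe <- empirical_bayes(fit, dat)
  eta_true <- attr(dat, "eta")
  # rich, nearly noise-free data: individual clearance effects recovered
  expect_lt(median(abs(exp(ebe$eta_CL_int) / exp(eta_true[, "CL_int"]) - 1)),
            0.05)
  expect_error(empirical_bayes(fit, dat, id = "absent"), "unknown subject")
  # omega -> 0 shrinks every eta to the prior mode
  spec0 <- popmodel_spec(drug, family = NULL,
                         omega_init = c(CL_int = 1e-8, V = 1e-8),
                         fixed = c("CLint_adult", "V_ref", "ka",
                                   "omega_CL_int", "omega_V", "sigma_prop",
                                   "sigma_add"))
  fit0 <- fit_population_model(spec0, dat)
  ebe0 <- empirical_bayes(fit0, dat)
  expect_lt(max(abs(ebe0$eta_CL_int)), 1e-3)
})

test_that("the OFV is invariant to subject ordering", {
  dat <- simulate_trial(small_design(n_per_arm = 5), drug, seed = 13)
  spec <- popmodel_spec(drug, family = "eq4a")
  o1 <- as.numeric(laplace_ofv(spec, dat))
  shuffled <- do.call(rbind, lapply(rev(unique(dat$ID)), function(id) {
    dat[dat$ID == id, ]
  }))
  o2 <- as.numeric(laplace_ofv(spec, shuffled))
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("estimates are invariant to DV/dose rescaling under proportional error", {
  des <- small_design(n_per_arm = 6, residual = c(prop = 0.15, add = 0))
  dat <- simulate_trial(des, drug, seed = 14)
  scaled <- dat
  scaled$DV <- dat$DV * 100
  scaled$AMT <- dat$AMT * 100
  mk <- function() popmodel_spec(
    drug, family = NULL, eta_on = "CL_int", omega_init = c(CL_int = 0.09),
    sigma_init = c(prop = 0.15, add = 1e-9),
    fixed = c("ka", "sigma_add"))
  f1 <- fit_population_model(mk(), dat, n_starts = 1, compute_se = FALSE)
  f2 <- fit_population_model(mk(), scaled, n_starts = 1, compute_se = FALSE)
  expect_rel(f2$theta[["CLint_adult"]], f1$theta[["CLint_adult"]], 1e-3)
  expect_rel(f2$theta[["V_ref"]], f1$theta[["V_ref"]], 1e-3)
  expect_rel(f2$omega[["CL_int"]], f1$omega[["CL_int"]], 0.01)
})

test_that("freeing a superfluous parameter never increases the optimum OFV", {
  dat <- simulate_trial(small_design(n_per_arm = 6), drug, seed = 15)
  base_fix <- c("ka", "V_ref", "omega_V", "sigma_add")
  spec <- popmodel_spec(drug, family = NULL, fixed = base_fix)
  f1 <- fit_population_model(spec, dat, n_starts = 1, compute_se = FALSE)
  inits <- c(as.list(f1$theta),
             setNames(as.list(f1$omega), paste0("omega_", names(f1$omega))),
             sigma_prop = unname(f1$sigma[["prop"]]))
  spec2 <- popmodel_spec(drug, family = NULL,
                         fixed = setdiff(base_fix, "ka"))
  f2 <- fit_population_model(spec2, dat, inits = inits, n_starts = 1,
                             compute_se = FALSE)
  expect_lte(f2$ofv, f1$ofv + 1e-6)
})
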