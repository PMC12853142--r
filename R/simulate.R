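# Synthetic sparse-trial simulator. Emulates the case-study structure:
# wide age range, weight-based once-daily oral dosing, steady-state visits
# with 2-4 samples each, log-normal between-subject variability and
# combined proportional + additive residual error.

#' Construct a trial design
#'
#' @param arms List of arms; each arm is a list with `age_range` (years),
#'   `n`, `dose` (list: `type` `"mg_per_kg"` or `"fixed_mg"`, `value`,
#'   optional `cap_mg`) and optional `age_dist` (`"uniform"` or
#'   `"log_uniform"`).
#' @param visits_days Visit days (dosing is continuous; visits are sampled
#'   at steady state).
#' @param samples_per_visit Length-2 integer range of samples per visit.
#' @param sampling_window_h Length-2 window (h after the visit dose).
#' @param interval_h Dosing interval, h.
#' @param bsv Named log-normal between-subject SDs (of log), e.g.
#'   `c(CL_int = 0.3, V = 0.2)`.
#' @param residual `c(prop = , add = )` residual magnitudes for generation.
#' @param weight_cv CV of body weight around the typical curve.
#' @param name Design label.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(arms, visits_days = c(14, 112, 365),
                         samples_per_visit = c(2, 4),
                         sampling_window_h = c(0.5, 24), interval_h = 24,
                         bsv = c(CL_int = 0.3, V = 0.2),
                         residual = c(prop = 0.15, add = 0.1),
                         weight_cv = 0.15, name = "design") {
  for (a in arms) {
    if (is.null(a$n) || a$n < 1) stopf("each arm needs n >= 1")
    if (length(a$age_range) != 2L) stopf("each arm needs age_range")
    win <- sampling_window_h
    if (win[1] < 0 || win[2] > interval_h) {
      stopf("sampling window must lie within the dosing interval")
    }
  }
  structure(list(arms = arms, visits_days = visits_days,
                 samples_per_visit = samples_per_visit,
                 sampling_window_h = sampling_window_h,
                 interval_h = interval_h, bsv = bsv, residual = residual,
                 weight_cv = weight_cv, name = name),
            class = "trial_design")
}

#' Load a trial design from a YAML block
#' @param path YAML file (see the packaged `design_risdiplam_like.yaml`).
#' @return A [trial_design()] object.
#' @export
load_trial_design <- function(path = example_design_path()) {
  cfg <- yaml::read_yaml(path)
  arms <- lapply(cfg$arms, function(a) {
    # YAML 1.1 parses a bare key "n" as a boolean, hence "n_subjects"
    if (is.null(a$n)) a$n <- a$n_subjects
    a
  })
  trial_design(
    arms = arms,
    visits_days = unlist(cfg$visits_days),
    samples_per_visit = unlist(cfg$samples_per_visit),
    sampling_window_h = unlist(cfg$sampling_window_h),
    interval_h = cfg$regimen$interval_h %||% 24,
    bsv = unlist(cfg$bsv),
    residual = unlist(cfg$residual),
    weight_cv = cfg$weight_cv %||% 0.15,
    name = cfg$name %||% "design")
}

#' Path to the bundled case-study-like trial design
#' @return File path.
#' @export
example_design_path <- function() onto_extdata("design_risdiplam_like.yaml")

.arm_dose <- function(dose_rule, wt) {
  amt <- switch(dose_rule$type,
                mg_per_kg = dose_rule$value * wt,
                fixed_mg = rep(dose_rule$value, length(wt)),
                stopf("unknown dose rule '%s'", dose_rule$type))
  if (!is.null(dose_rule$cap_mg)) amt <- pmin(amt, dose_rule$cap_mg)
  amt
}

#' Simulate a sparse PK trial
#'
#' Demographics per arm via [sample_demographics()], individual parameters
#' via the structural model with `eta ~ N(0, diag(bsv^2))`, observations
#' `DV = pred * (1 + prop * e1) + add * e2` truncated at 0. Deterministic
#' under `seed`.
#'
#' @param design A [trial_design()].
#' @param truth A `drug_parameters` object carrying the true ontogeny
#'   bindings, or a [popmodel_spec()] (its drug is used).
#' @param seed Integer seed.
#' @return A NONMEM-style dataset (data.frame) with columns `ID`, `TIME`,
#'   `AMT`, `EVID`, `MDV`, `DV`, `AGE`, `WT`, `SS`, `II`; the matrix of
#'   simulated random effects is attached as attribute `"eta"`.
#' @export
simulate_trial <- function(design, truth = load_drug_config(), seed = 1) {
  drug <- if (inherits(truth, "popmodel_spec")) truth$drug else truth
  if (!inherits(drug, "drug_parameters")) {
    stopf("truth must be drug_parameters or popmodel_spec")
  }
  set.seed(seed)
  bsv <- design$bsv
  resid <- design$residual
  rows <- list()
  etas <- list()
  id0 <- 0L
  for (a in design$arms) {
    dem <- sample_demographics(unlist(a$age_range), a$n,
                               weight_cv = design$weight_cv,
                               age_dist = a$age_dist %||% "uniform")
    amt <- .arm_dose(a$dose, dem$body_weight)
    physio <- profile_for_age(dem$age, body_weight = dem$body_weight)
    eta <- matrix(0, a$n, length(bsv), dimnames = list(NULL, names(bsv)))
    for (nm in names(bsv)) eta[, nm] <- rnorm(a$n, 0, bsv[[nm]])
    ip <- individual_parameters(drug, physio, dem$age,
                                eta = as.list(as.data.frame(eta)))
    for (i in seq_len(a$n)) {
      id0 <- id0 + 1L
      n_per <- sample(seq(design$samples_per_visit[1],
                          design$samples_per_visit[2]), 1)
      subj_rows <- list()
      for (v in design$visits_days) {
        t_v <- v * 24
        tads <- sort(runif(n_per, design$sampling_window_h[1],
                           design$sampling_window_h[2]))
        pred <- .conc_1cmt_oral(amt[i], ip$F[i], ip$V[i], ip$CL[i],
                                ip$ka[i], tads, ss = TRUE,
                                ii = design$interval_h)
        dv <- pmax(pred * (1 + resid[["prop"]] * rnorm(n_per)) +
                     resid[["add"]] * rnorm(n_per), 0)
        subj_rows[[length(subj_rows) + 1L]] <- rbind(
          data.frame(TIME = t_v, AMT = amt[i], EVID = 1, MDV = 1, DV = NA,
                     SS = 1, II = design$interval_h),
          data.frame(TIME = t_v + tads, AMT = 0, EVID = 0, MDV = 0,
                     DV = dv, SS = 0, II = 0))
      }
      sr <- do.call(rbind, subj_rows)
      sr <- cbind(ID = id0, sr, AGE = dem$age[i], WT = dem$body_weight[i])
      rows[[id0]] <- sr
    }
    etas[[length(etas) + 1L]] <- eta
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  out$DV[is.na(out$DV)] <- 0
  out <- out[, c("ID", "TIME", "AMT", "EVID", "MDV", "DV", "AGE", "WT",
                 "SS", "II")]
  attr(out, "eta") <- do.call(rbind, etas)
  validate_dataset(out)
  out
}

#' Re-simulate observations under an existing dataset's design
#'
#' Keeps every subject's dosing and sampling structure and draws new
#' random effects and residuals from the given model parameters; the
#' workhorse of the visual predictive check.
#'
#' @param spec A [popmodel_spec()].
#' @param data The observed dataset (its design is reused).
#' @param theta,omega,sigma Parameters (defaults from `spec`).
#' @param seed Integer seed.
#' @return The dataset with `DV` replaced by simulated values.
#' @export
simulate_from_dataset <- function(spec, data, theta = NULL, omega = NULL,
                                  sigma = NULL, seed = 1) {
  theta <- theta %||% spec$theta
  omega <- omega %||% spec$omega
  sigma <- sigma %||% spec$sigma
  set.seed(seed)
  ctx <- .build_ctx(spec, data)
  n <- ctx$n_sub
  eta <- matrix(0, n, length(omega), dimnames = list(NULL, names(omega)))
  for (nm in names(omega)) eta[, nm] <- rnorm(n, 0, sqrt(omega[[nm]]))
  pred <- .predict_obs(ctx, theta, names(omega), eta)
  n_obs <- length(pred)
  dv <- pmax(pred * (1 + sigma[["prop"]] * rnorm(n_obs)) +
               sigma[["add"]] * rnorm(n_obs), 0)
  out <- data
  out$DV[ctx$prep$obs$row] <- dv
  out
}

#' Single-arm neonate extrapolation design
#'
#' @param age_days Age in days (e.g. 16).
#' @param dose_mg_per_kg Weight-based dose, mg/kg.
#' @param n Number of subjects.
#' @return A [trial_design()] with one arm at the given age.
#' @export
neonate_design <- function(age_days = 16, dose_mg_per_kg = 0.15, n = 100) {
  if (age_days < 0) stopf("age_days must be >= 0")
  if (n < 1) stopf("n must be >= 1")
  age_y <- age_days / 365.25
  trial_design(
    arms = list(list(age_range = c(age_y, age_y), n = n,
                     dose = list(type = "mg_per_kg",
                                 value = dose_mg_per_kg))),
    visits_days = 14, name = sprintf("neonate_%gd", age_days))
}
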