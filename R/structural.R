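# Reduced PBPK structural model: well-stirred hepatic clearance with
# ontogeny-scaled, pathway-partitioned intrinsic clearance; GFR-scaled renal
# clearance; empirical first-order absorption and one-compartment
# disposition. Units: doses mg, times h, volumes L, clearances L/h, ages
# years, concentrations ng/mL.

#' Well-stirred liver model
#'
#' @param CL_int Whole-liver unbound intrinsic clearance, L/h (`>= 0`).
#' @param Q_H Hepatic blood flow, L/h (`> 0`).
#' @param fu_B Unbound fraction in blood (`fu / BP`, in `(0, 1]`).
#' @return A list with `CL_H` (hepatic blood clearance, always `< Q_H`) and
#'   `F_H` (hepatic availability).
#' @export
#' @examples
#' well_stirred(CL_int = 10, Q_H = 90, fu_B = 1)  # CL_H = 9, F_H = 0.9
well_stirred <- function(CL_int, Q_H, fu_B) {
  if (any(Q_H <= 0)) stopf("Q_H must be > 0")
  if (any(CL_int < 0)) stopf("CL_int must be >= 0")
  if (any(fu_B <= 0 | fu_B > 1)) stopf("fu_B must lie in (0, 1]")
  denom <- Q_H + fu_B * CL_int
  list(CL_H = Q_H * fu_B * CL_int / denom, F_H = Q_H / denom)
}

# F_activity of each pathway at the given ages, as a named list of vectors.
.pathway_activity <- function(drug, age) {
  lapply(drug$pathway_ontogeny, function(b) {
    evaluate_ontogeny(b$model, b$params, age)
  })
}

#' Ontogeny-scaled whole-liver intrinsic clearance
#'
#' Per pathway: `CL_int_p(age) = CLint_per_mg[p] * MPPGL(age) *
#' liver_weight(age) * F_activity_p(age)`, converted to L/h.
#'
#' @param drug A [load_drug_config()] object.
#' @param physio A [profile_for_age()] row (or rows) matching `age`.
#' @param age Ages in years.
#' @return List with `total` (L/h) and `per_pathway` (matrix, one column per
#'   pathway).
#' @export
hepatic_intrinsic_clearance <- function(drug, physio, age) {
  act <- .pathway_activity(drug, age)
  scaling <- physio$MPPGL * physio$liver_weight * UL_MIN_TO_L_H
  per <- vapply(names(drug$CLint_per_mg), function(p) {
    drug$CLint_per_mg[[p]] * scaling * act[[p]]
  }, numeric(length(age)))
  per <- matrix(per, nrow = length(age),
                dimnames = list(NULL, names(drug$CLint_per_mg)))
  list(total = rowSums(per), per_pathway = per)
}

#' Individual structural PK parameters at a given age
#'
#' Combines the ontogeny-scaled intrinsic clearance (well-stirred liver),
#' GFR-scaled renal clearance, allometric volume and first-order
#' absorption. Log-normal random effects enter multiplicatively as
#' `exp(eta)`; the clearance effect is applied to the intrinsic clearance
#' *before* the well-stirred transform so that hepatic availability stays
#' consistent with the individual's clearance.
#'
#' @param drug A [load_drug_config()] object.
#' @param physio Optional [profile_for_age()] rows; computed from `age` (and
#'   `physio$body_weight` when supplied) if missing.
#' @param age Ages in years.
#' @param eta Named list/vector of random effects; recognised names are
#'   `CL_int`, `V`, `ka` (each scalar or length of `age`).
#' @return A list of class `individual_pk_params` with vectors `CL_H`,
#'   `CL_R`, `CL` (total), `F`, `V`, `ka`, `CL_int_total` and the matrix
#'   `CL_int_pathway`.
#' @export
individual_parameters <- function(drug, physio = NULL, age,
                                  eta = list()) {
  if (is.null(physio)) physio <- profile_for_age(age)
  eta_of <- function(nm) {
    v <- eta[[nm]] %||% 0
    rep_len(v, length(age))
  }
  cli <- hepatic_intrinsic_clearance(drug, physio, age)
  clint_ind <- cli$total * exp(eta_of("CL_int"))
  ws <- well_stirred(clint_ind, physio$Q_H, drug$fu_B)
  wt_ref <- drug$adult_profile$body_weight
  renal_act <- evaluate_ontogeny(drug$renal_ontogeny$model,
                                 drug$renal_ontogeny$params, age) /
    evaluate_ontogeny(drug$renal_ontogeny$model, drug$renal_ontogeny$params,
                      adult_reference_age())
  # renal clearance scales with absolute GFR: maturation x size (BSA)
  cl_r <- drug$CLR_adult * renal_act * physio$bsa / drug$adult_profile$bsa
  structure(list(
    CL_H = ws$CL_H,
    CL_R = cl_r,
    CL = ws$CL_H + cl_r,
    F = drug$FaFg * ws$F_H,
    V = drug$V_ref *
      (physio$body_weight / wt_ref)^drug$vol_allometric_exponent *
      exp(eta_of("V")),
    ka = drug$ka * exp(eta_of("ka")),
    CL_int_total = clint_ind,
    CL_int_pathway = cli$per_pathway * exp(eta_of("CL_int"))
  ), class = "individual_pk_params")
}

#' Fraction metabolised / excreted by pathway at a given age
#'
#' Apportioned at the clearance level: hepatic pathways share the
#' well-stirred hepatic clearance in proportion to their intrinsic
#' clearances (competing pathways see the same unbound liver exposure), and
#' the renal route takes `CL_R / (CL_H + CL_R)`.
#'
#' @inheritParams individual_parameters
#' @return A named numeric vector per age row: one entry per hepatic
#'   pathway plus `renal`; entries sum to 1. For vector `age` a matrix.
#' @export
#' @examples
#' drug <- load_drug_config()
#' fraction_metabolized(drug, age = 35)  # adult partition 0.75/0.20/0.05
fraction_metabolized <- function(drug, physio = NULL, age) {
  if (is.null(physio)) physio <- profile_for_age(age)
  ip <- individual_parameters(drug, physio, age)
  total <- ip$CL
  if (any(total <= 0)) stopf("total clearance must be > 0")
  shares <- ip$CL_int_pathway / ip$CL_int_total
  fm <- shares * (ip$CL_H / total)
  out <- cbind(fm, renal = ip$CL_R / total)
  if (length(age) == 1L) out[1, ] else out
}

# Closed-form one-compartment first-order-absorption concentration at
# time-after-dose tad for a single dose (ss = FALSE) or at steady state of
# interval ii (ss = TRUE). Vectorised over everything. The exact ka == ke
# degeneracy is handled by nudging ka (documented numerical tie-break).
.conc_1cmt_oral <- function(dose, F, V, CL, ka, tad, ss = FALSE, ii = 24) {
  ke <- CL / V
  ka <- ifelse(abs(ka - ke) < 1e-8 * ke, ka * (1 + 1e-6), ka)
  coefpk <- MGL_TO_NGML * F * dose * ka / (V * (ka - ke))
  tad <- pmax(tad, 0)
  if (ss) {
    coefpk * (exp(-ke * tad) / (1 - exp(-ke * ii)) -
                exp(-ka * tad) / (1 - exp(-ka * ii)))
  } else {
    coefpk * (exp(-ke * tad) - exp(-ka * tad))
  }
}

#' Predict plasma concentrations for a dosing history
#'
#' Default backend is the closed-form one-compartment superposition
#' (steady-state dose records use the closed-form accumulation over the
#' dosing interval); an ODE backend (`deSolve`) is available as a
#' cross-check and agrees within numerical integration tolerance.
#'
#' @param params An [individual_parameters()] object (scalar entries).
#' @param dosing data.frame with columns `time` (h), `amt` (mg) and
#'   optionally `ss` (0/1) and `ii` (h).
#' @param times Observation times, h.
#' @param backend `"analytic"` or `"ode"`.
#' @return Numeric vector of concentrations, ng/mL.
#' @export
predict_concentration <- function(params, dosing, times,
                                  backend = c("analytic", "ode")) {
  backend <- match.arg(backend)
  if (any(times < 0)) stopf("times must be >= 0")
  if (is.null(dosing$ss)) dosing$ss <- 0
  if (is.null(dosing$ii)) dosing$ii <- 24
  if (backend == "analytic") {
    conc <- numeric(length(times))
    for (i in seq_len(nrow(dosing))) {
      d <- dosing[i, ]
      contrib <- .conc_1cmt_oral(d$amt, params$F, params$V, params$CL,
                                 params$ka, times - d$time,
                                 ss = d$ss > 0, ii = d$ii)
      contrib[times < d$time] <- 0
      conc <- conc + contrib
    }
    return(pmax(conc, 0))
  }
  # ODE backend: expand steady-state records into enough preceding doses
  expand <- do.call(rbind, lapply(seq_len(nrow(dosing)), function(i) {
    d <- dosing[i, ]
    if (d$ss > 0) {
      ke <- params$CL / params$V
      n_pre <- ceiling(log(1e9) / (min(ke, params$ka) * d$ii))
      data.frame(time = d$time - (n_pre:0) * d$ii, amt = d$amt)
    } else data.frame(time = d$time, amt = d$amt)
  }))
  t0 <- min(expand$time, 0)
  rhs <- function(t, y, p) {
    list(c(-params$ka * y[1], params$ka * y[1] - params$CL / params$V * y[2]))
  }
  ev <- data.frame(var = 1, time = expand$time, value = expand$amt * params$F,
                   method = "add")
  tt <- sort(unique(c(t0, expand$time, times)))
  sol <- deSolve::lsoda(c(gut = 0, central = 0), times = tt, func = rhs,
                        parms = NULL, events = list(data = ev),
                        rtol = 1e-10, atol = 1e-10)
  idx <- match(times, sol[, "time"])
  pmax(MGL_TO_NGML * sol[idx, "central"] / params$V, 0)
}

#' Steady-state (or total) area under the concentration-time curve
#'
#' Under linear PK the steady-state AUC over one dosing interval equals the
#' single-dose AUC from zero to infinity: `Dose * F / CL`.
#'
#' @param params An [individual_parameters()] object.
#' @param dose Dose amount, mg.
#' @return AUC in ng.h/mL.
#' @export
auc_ss <- function(params, dose) {
  if (any(params$CL <= 0)) stopf("CL must be > 0")
  MGL_TO_NGML * dose * params$F / params$CL
}

#' Forward mass-balance simulation with pathway-flux bookkeeping
#'
#' Administers a single oral dose and integrates the amount eliminated
#' through every hepatic pathway (including the first-pass extraction,
#' split by intrinsic-clearance share) and the renal route until the dose
#' is fully accounted for. The returned fractions are the simulated
#' counterpart of [fraction_metabolized()].
#'
#' @param drug A [load_drug_config()] object.
#' @param age Age in years.
#' @param dose Dose in mg.
#' @param horizon Integration horizon in multiples of the elimination
#'   half-life.
#' @return Named vector of eliminated fractions (pathways plus `renal`),
#'   summing to 1.
#' @export
mass_balance_fractions <- function(drug, age = adult_reference_age(),
                                   dose = 5, horizon = 40) {
  physio <- profile_for_age(age)
  ip <- individual_parameters(drug, physio, age)
  shares <- drug$CLint_per_mg *
    vapply(.pathway_activity(drug, age), identity, numeric(1))
  shares <- shares / sum(shares)
  f_h <- ip$F / drug$FaFg              # hepatic availability
  npath <- length(shares)
  ke <- ip$CL / ip$V
  rhs <- function(t, y, p) {
    gut <- y[1]; central <- y[2]
    absorbed <- ip$ka * gut            # reaches the liver, mg/h
    conc <- central / ip$V
    hep <- ip$CL_H * conc
    ren <- ip$CL_R * conc
    d_elim <- shares * (absorbed * (1 - f_h) + hep)
    list(c(-absorbed, absorbed * f_h - hep - ren, d_elim, ren))
  }
  t_end <- horizon * log(2) / min(ke, ip$ka)
  y0 <- c(gut = dose * drug$FaFg, central = 0,
          setNames(numeric(npath), names(shares)), renal = 0)
  sol <- deSolve::lsoda(y0, times = c(0, t_end), func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  elim <- sol[nrow(sol), 3 + seq_len(npath + 1)]
  out <- elim / sum(elim)
  setNames(as.numeric(out), c(names(shares), "renal"))
}
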