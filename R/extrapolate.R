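# Extrapolation with estimated ontogeny models: age-dependent pathway
# partition, static CYP3A DDI AUC ratios, and neonate exposure ranges
# across retained ontogeny models.

#' Static drug-drug-interaction AUC ratio at a given age
#'
#' The inhibited state divides the perpetrated pathway's intrinsic
#' clearance by `IR` and rebuilds the well-stirred hepatic clearance *and*
#' bioavailability, so hepatic availability stays consistent with the
#' reduced clearance. `IR = Inf` is complete inhibition. In the
#' low-extraction limit the result approaches the textbook static ratio
#' `1 / (1 - fm + fm / IR)` (see [ddi_auc_ratio_shortcut()]).
#'
#' @param drug A [load_drug_config()] object.
#' @param age Age in years.
#' @param pathway Inhibited pathway (default `"CYP3A"`).
#' @param IR Fold-reduction of the pathway intrinsic clearance (`>= 1`).
#' @return The AUC ratio (inhibited / baseline), `>= 1`.
#' @export
#' @examples
#' drug <- load_drug_config()
#' ddi_auc_ratio(drug, age = 35, IR = Inf)   # adult, complete inhibition
ddi_auc_ratio <- function(drug, age, pathway = "CYP3A", IR = Inf) {
  if (IR < 1) stopf("IR must be >= 1 (fold reduction)")
  if (!pathway %in% names(drug$CLint_per_mg)) {
    stopf("pathway '%s' not in drug config", pathway)
  }
  physio <- profile_for_age(age)
  base <- individual_parameters(drug, physio, age)
  er <- base$CL_H / physio$Q_H
  if (er > 0.3) warnf("hepatic extraction ratio %.2f: low-extraction static model questionable", er)
  inh_drug <- drug
  inh_drug$CLint_per_mg[[pathway]] <- drug$CLint_per_mg[[pathway]] /
    (if (is.infinite(IR)) Inf else IR)
  if (is.infinite(IR)) inh_drug$CLint_per_mg[[pathway]] <- 0
  inh <- individual_parameters(inh_drug, physio, age)
  (inh$F / inh$CL) / (base$F / base$CL)
}

#' Textbook static AUC-ratio shortcut
#'
#' `AUCR = 1 / (1 - fm + fm / IR)`, valid for low-extraction drugs with
#' unchanged absorption; retained as a cross-check for [ddi_auc_ratio()].
#'
#' @param fm Fraction of total clearance through the inhibited pathway.
#' @param IR Fold reduction (`>= 1`; `Inf` = complete inhibition).
#' @return The AUC ratio.
#' @export
ddi_auc_ratio_shortcut <- function(fm, IR = Inf) {
  if (IR < 1) stopf("IR must be >= 1")
  1 / (1 - fm + if (is.infinite(IR)) 0 else fm / IR)
}

#' Typical-subject exposure range across retained ontogeny models
#'
#' Replaces the target pathway's ontogeny with each retained model,
#' computes the typical steady-state AUC at the given age and dose, and
#' summarises the range against a reference exposure interval.
#'
#' @param drug A [load_drug_config()] object.
#' @param age Age in years.
#' @param dose_mg_per_kg Weight-based dose (typical weight-for-age is
#'   used), or give `dose_mg` for a fixed dose.
#' @param models Named list of retained ontogeny models, each a list with
#'   `model` and `params` (e.g. from [fixed_profile()] or fitted scans).
#' @param reference_interval Optional length-2 exposure interval
#'   (ng.h/mL) to flag each model's prediction against.
#' @param target_pathway Pathway to rebind.
#' @param dose_mg Optional fixed dose overriding `dose_mg_per_kg`.
#' @return A list of class `exposure_range`: per-model AUC table,
#'   `min`/`median`/`max`, and inside-interval flags.
#' @export
extrapolate_exposure <- function(drug, age, dose_mg_per_kg = 0.15,
                                 models, reference_interval = NULL,
                                 target_pathway = "FMO3", dose_mg = NULL) {
  if (length(models) < 1L) stopf("need at least one retained model")
  physio <- profile_for_age(age)
  dose <- dose_mg %||% (dose_mg_per_kg * physio$body_weight)
  aucs <- vapply(models, function(m) {
    d <- set_pathway_ontogeny(drug, target_pathway, m$model, m$params)
    ip <- individual_parameters(d, physio, age)
    auc_ss(ip, dose)
  }, 0)
  inside <- if (!is.null(reference_interval)) {
    aucs >= reference_interval[1] & aucs <= reference_interval[2]
  } else rep(NA, length(aucs))
  tab <- data.frame(model = names(models) %||% seq_along(models),
                    auc = aucs, inside_reference = inside)
  structure(list(table = tab, age = age, dose = dose,
                 min = min(aucs), median = median(aucs), max = max(aucs),
                 reference_interval = reference_interval),
            class = "exposure_range")
}

#' @export
print.exposure_range <- function(x, ...) {
  cat(sprintf("<exposure range at age %.3g y, dose %.3g mg: AUC %.4g / %.4g / %.4g ng.h/mL (min/median/max)>\n",
              x$age, x$dose, x$min, x$median, x$max))
  if (!is.null(x$reference_interval)) {
    cat(sprintf("  reference interval [%.4g, %.4g]: %d/%d models inside\n",
                x$reference_interval[1], x$reference_interval[2],
                sum(x$table$inside_reference), nrow(x$table)))
  }
  invisible(x)
}

#' Pathway partition (fm / fe) across age
#'
#' @param drug A [load_drug_config()] object.
#' @param age_grid Ages in years.
#' @return data.frame with `age` and one fraction column per pathway plus
#'   `renal`; rows sum to 1.
#' @export
#' @examples
#' fm_vs_age(load_drug_config(), c(0.3, 2, 35))
fm_vs_age <- function(drug, age_grid) {
  fm <- fraction_metabolized(drug, age = age_grid)
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1,
                                     dimnames = list(NULL, names(fm)))
  cbind(data.frame(age = age_grid), as.data.frame(fm))
}

#' Reference exposure interval from a simulated paediatric population
#'
#' Simulates steady-state AUCs (with between-subject variability on the
#' intrinsic clearance) for subjects in a reference age range on a
#' reference dosing rule and returns percentile bounds — the synthetic
#' counterpart of "the exposure range observed in older children on the
#' approved dose".
#'
#' @param drug A [load_drug_config()] object.
#' @param age_range Reference age range, years.
#' @param n Number of simulated subjects.
#' @param dose_mg_per_kg Reference dose rule.
#' @param cap_mg Optional dose cap.
#' @param bsv_cl Log-SD of the clearance random effect.
#' @param probs Percentile bounds of the interval.
#' @param seed Integer seed.
#' @return Length-2 numeric interval (ng.h/mL).
#' @export
reference_exposure_interval <- function(drug, age_range = c(1 / 6, 2),
                                        n = 500, dose_mg_per_kg = 0.2,
                                        cap_mg = NULL, bsv_cl = 0.3,
                                        probs = c(0.05, 0.95), seed = 1) {
  set.seed(seed)
  dem <- sample_demographics(age_range, n)
  physio <- profile_for_age(dem$age, body_weight = dem$body_weight)
  eta <- rnorm(n, 0, bsv_cl)
  ip <- individual_parameters(drug, physio, dem$age,
                              eta = list(CL_int = eta))
  dose <- dose_mg_per_kg * dem$body_weight
  if (!is.null(cap_mg)) dose <- pmin(dose, cap_mg)
  quantile(auc_ss(ip, dose), probs = probs, names = FALSE)
}
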