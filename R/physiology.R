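# Age-dependent system parameters: growth, hepatic scalars, blood flow,
# renal maturation. All functional forms and constants live in the packaged
# physiology.yaml so they can be swapped to match a whole-body PBPK
# platform; the functions below only evaluate them.

.load_physiology <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.onto_env$physiology)) return(.onto_env$physiology)
    path <- onto_extdata("physiology.yaml")
  }
  phys <- yaml::read_yaml(path)
  .onto_env$physiology <- phys
  phys
}

#' Point the package at an alternative physiology constants file
#'
#' @param path Path to a YAML file with the same structure as the packaged
#'   `physiology.yaml`; `NULL` resets to the packaged defaults.
#' @return Invisibly, the loaded constants list.
#' @export
use_physiology_constants <- function(path = NULL) {
  .onto_env$physiology <- NULL
  invisible(.load_physiology(path))
}

.growth_curve <- function(age, cf) {
  cf$base + cf$infancy_gain * age / (age + cf$infancy_age50) +
    cf$puberty_gain * hill_age(age, cf$puberty_age50, cf$puberty_hill)
}

#' Typical body weight and height for age
#'
#' Smooth parametric growth curves (saturating infancy term plus pubertal
#' sigmoid) fitted to standard median weight/height-for-age tables.
#'
#' @param age Numeric vector of ages in years.
#' @return Numeric vector (kg for `weight_for_age`, cm for
#'   `height_for_age`).
#' @export
weight_for_age <- function(age) {
  phys <- .load_physiology()
  .growth_curve(age, phys$weight_for_age)
}

#' @rdname weight_for_age
#' @export
height_for_age <- function(age) {
  phys <- .load_physiology()
  .growth_curve(age, phys$height_for_age)
}

.mppgl_for_age <- function(age, cf) {
  10^(cf$log10_intercept + cf$age_linear * age +
        cf$age_quadratic * age^2 + cf$age_cubic * age^3)
}

.gfr_frac_for_age <- function(age) {
  prof <- fixed_profile(.load_physiology()$gfr$profile)
  raw <- evaluate_ontogeny(prof$model, prof$params, age)
  ref <- evaluate_ontogeny(prof$model, prof$params, adult_reference_age())
  raw / ref
}

#' Age-resolved physiology profile
#'
#' Assembles the system parameters used to scale adult drug parameters to a
#' child of a given age: body weight (typical-for-age unless supplied),
#' liver weight, microsomal protein per gram liver (MPPGL), hepatic blood
#' flow (adult value scaled by body surface area), and the fraction of
#' adult glomerular filtration rate. At the adult reference age the profile
#' reproduces the packaged adult constants exactly.
#'
#' @param age Age in years (scalar or vector, `>= 0`).
#' @param body_weight Optional observed body weight in kg (recycled);
#'   overrides the typical weight-for-age.
#' @return A data.frame of class `physiology_profile` with columns `age`,
#'   `body_weight`, `height`, `bsa`, `liver_weight` (g), `MPPGL`
#'   (mg/g), `Q_H` (L/h) and `GFR_frac`.
#' @export
#' @examples
#' profile_for_age(c(0.5, 2, 35))
profile_for_age <- function(age, body_weight = NULL) {
  if (any(!is.finite(age)) || any(age < 0)) stopf("age must be >= 0")
  phys <- .load_physiology()
  wt <- if (is.null(body_weight)) weight_for_age(age) else {
    if (any(body_weight <= 0)) stopf("body_weight must be > 0")
    rep_len(body_weight, length(age))
  }
  ht <- height_for_age(age)
  bsa <- phys$bsa$coef * wt^phys$bsa$wt_exp * ht^phys$bsa$ht_exp
  ref_age <- phys$adult_reference_age
  wt_ref <- weight_for_age(ref_age)
  ht_ref <- height_for_age(ref_age)
  bsa_ref <- phys$bsa$coef * wt_ref^phys$bsa$wt_exp * ht_ref^phys$bsa$ht_exp
  out <- data.frame(
    age = age,
    body_weight = wt,
    height = ht,
    bsa = bsa,
    liver_weight = phys$liver_weight$coef * wt^phys$liver_weight$exponent,
    MPPGL = .mppgl_for_age(age, phys$mppgl),
    Q_H = phys$hepatic_blood_flow$adult_LPH * bsa / bsa_ref,
    # fraction of the *absolute* adult GFR: maturation x size (BSA)
    GFR_frac = .gfr_frac_for_age(age) * bsa / bsa_ref
  )
  class(out) <- c("physiology_profile", "data.frame")
  out
}

#' Adult reference physiology constants
#'
#' @return The [profile_for_age()] row at the adult reference age.
#' @export
adult_reference_profile <- function() {
  profile_for_age(adult_reference_age())
}

#' Sample demographics for a virtual trial arm
#'
#' Ages are drawn uniformly (or log-uniformly, useful to enrich infants in
#' arms spanning 0-2 years) over the requested range; body weights are
#' log-normal around the typical weight-for-age with coefficient of
#' variation `weight_cv`; sex is assigned 1:1 and carried along (no
#' physiology function in the defaults uses it).
#'
#' @param age_range Numeric length-2, years.
#' @param n Number of subjects (`>= 1`).
#' @param weight_cv CV of body weight around the typical curve (0 puts all
#'   weights exactly on the curve).
#' @param age_dist `"uniform"` or `"log_uniform"`.
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with columns `age`, `body_weight`, `sex`.
#' @export
sample_demographics <- function(age_range, n, weight_cv = 0.15,
                                age_dist = c("uniform", "log_uniform"),
                                seed = NULL) {
  age_dist <- match.arg(age_dist)
  if (length(age_range) != 2L || diff(age_range) < 0 || any(age_range < 0)) {
    stopf("age_range must be an increasing pair of non-negative years")
  }
  if (diff(age_range) == 0 && age_dist == "log_uniform") {
    age_dist <- "uniform"
  }
  assert_number(n, "n", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  age <- if (age_dist == "uniform") {
    runif(n, age_range[1], age_range[2])
  } else {
    if (age_range[1] <= 0) stopf("log_uniform age_dist needs range > 0")
    exp(runif(n, log(age_range[1]), log(age_range[2])))
  }
  wt_typ <- weight_for_age(age)
  wt <- if (weight_cv > 0) {
    sdlog <- sqrt(log(1 + weight_cv^2))
    wt_typ * exp(rnorm(n, -sdlog^2 / 2, sdlog))
  } else wt_typ
  data.frame(age = age, body_weight = wt,
             sex = sample(c("F", "M"), n, replace = TRUE))
}
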