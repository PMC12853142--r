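# Structural ontogeny model families.
#
# Every family returns F_activity, the enzyme or transporter activity at a
# given postnatal age expressed as a fraction of the typical adult value.
# Rising limbs are Hill (sigmoid Emax in age) or Gompertz terms, declining
# limbs are Hill or Gompertz decays, and the bell-shaped families combine
# one of each. Bell-shaped families are reparameterised so their adult
# asymptote is exactly 1: F_max is derived as 1/(1 - FRD) and is not a free
# parameter.

.ONTOGENY_FAMILIES <- list(
  eq1_sigmoid_up = list(
    roster = c("F_birth", "F_max", "Age_up50", "gamma_u"),
    capped = FALSE, shape = "rising"),
  eq2_gompertz_up = list(
    roster = c("F_birth", "F_max", "K"),
    capped = FALSE, shape = "rising"),
  eq3a_sigmoid_down = list(
    roster = c("F_birth", "F_min", "Age_down50", "gamma_d"),
    capped = FALSE, shape = "declining"),
  eq3b_exp_down = list(
    roster = c("F_birth", "F_min", "K"),
    capped = FALSE, shape = "declining"),
  eq4a = list(
    roster = c("F_birth", "Age_up50", "gamma_u", "FRD", "Age_down50",
               "gamma_d"),
    capped = FALSE, shape = "bell"),
  eq4b = list(
    roster = c("F_birth", "Age_up50", "gamma_u", "FRD", "Age_down50",
               "gamma_d", "AGECAP"),
    capped = TRUE, shape = "bell"),
  eq4c = list(
    roster = c("F_birth", "K", "gamma_u", "FRD", "Age_down50", "gamma_d"),
    capped = FALSE, shape = "bell"),
  eq4d = list(
    roster = c("F_birth", "Age_up50", "gamma_u", "FRD", "K", "gamma_d"),
    capped = FALSE, shape = "bell"),
  eq4e = list(
    roster = c("F_birth", "Age_up50", "gamma_u", "FRD", "Age_down50",
               "gamma_d"),
    capped = FALSE, shape = "bell"),
  eq4f = list(
    roster = c("F_birth", "K", "gamma_u", "FRD", "Age_down50", "gamma_d"),
    capped = FALSE, shape = "bell"),
  eq4g_double_sigmoid = list(
    roster = c("F_birth", "K", "F_max", "gamma_u", "Age_up50", "FRD",
               "gamma_d", "Age_down50", "AGECAP"),
    capped = TRUE, shape = "bell")
)

.ONTOGENY_PARAM_NAMES <- c("F_birth", "F_max", "F_min", "Age_up50", "gamma_u",
                           "Age_down50", "gamma_d", "FRD", "K", "AGECAP")

#' Structural ontogeny model families
#'
#' The registry of maturation-function families available for describing
#' enzyme/transporter activity as a fraction of the adult value
#' (`F_activity`). Families `eq1`/`eq2` are monotonically rising (sigmoid
#' Emax and Gompertz), `eq3a`/`eq3b` monotonically declining, `eq4a`-`eq4f`
#' are six bell-shaped variants (activity in children transiently exceeding
#' the adult level) with 6-7 free parameters each, and
#' `eq4g_double_sigmoid` is a 9-parameter capped double-sigmoid.
#'
#' @return A named list of `ontogeny_model` objects.
#' @seealso [ontogeny_model()], [evaluate_ontogeny()]
#' @export
#' @examples
#' names(ontogeny_registry())
#' ontogeny_model("eq4a")$roster
ontogeny_registry <- function() {
  lapply(setNames(names(.ONTOGENY_FAMILIES), names(.ONTOGENY_FAMILIES)),
         ontogeny_model)
}

#' Retrieve one ontogeny model family
#'
#' @param family_id One of the family identifiers listed by
#'   [ontogeny_registry()].
#' @return An object of class `ontogeny_model` with elements `family_id`,
#'   `roster` (ordered free-parameter names), `capped` (whether `AGECAP`
#'   pins activity to 1), `shape` and `n_free`.
#' @export
ontogeny_model <- function(family_id) {
  fam <- .ONTOGENY_FAMILIES[[family_id]]
  if (is.null(fam)) {
    stopf("unknown ontogeny family '%s'; see ontogeny_registry()", family_id)
  }
  structure(
    list(family_id = family_id, roster = fam$roster, capped = fam$capped,
         shape = fam$shape, n_free = length(fam$roster)),
    class = "ontogeny_model")
}

#' @export
print.ontogeny_model <- function(x, ...) {
  cat(sprintf("<ontogeny family %s: %s, %d free parameters%s>\n",
              x$family_id, x$shape, x$n_free,
              if (x$capped) ", capped at AGECAP" else ""))
  cat("  parameters:", paste(x$roster, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a named ontogeny parameter set
#'
#' Parameters are named after the field's usual symbols: `F_birth` (fraction
#' of adult activity at birth), `F_max`/`F_min` (maximum/minimum fraction),
#' `Age_up50`/`Age_down50` (ages, in years, at 50% of the rising/declining
#' limb), `gamma_u`/`gamma_d` (Hill coefficients), `FRD` (fractional
#' contribution of the down slope, in `[0, 1)`), `K` (development rate,
#' 1/years) and `AGECAP` (age at which activity is pinned to 1).
#'
#' @param ... Named numeric parameters drawn from the set above.
#' @return An object of class `ontogeny_parameters` (a named numeric vector).
#' @export
ontogeny_parameters <- function(...) {
  vals <- c(...)
  if (length(vals) == 0L) vals <- numeric(0)
  bad <- setdiff(names(vals), .ONTOGENY_PARAM_NAMES)
  if (length(bad)) {
    stopf("unknown ontogeny parameter(s): %s", paste(bad, collapse = ", "))
  }
  structure(as.numeric(vals), names = names(vals),
            class = "ontogeny_parameters")
}

as_ontogeny_parameters <- function(x) {
  if (inherits(x, "ontogeny_parameters")) return(x)
  do.call(ontogeny_parameters, as.list(x))
}

#' Validate an ontogeny parameter set against its family's invariants
#'
#' Produces a report rather than throwing: each violated invariant is one
#' message. An empty report means the set is admissible for the family.
#'
#' @param model An [ontogeny_model()].
#' @param params An [ontogeny_parameters()] set (or named vector).
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_ontogeny_parameters <- function(model, params) {
  params <- as_ontogeny_parameters(params)
  p <- as.list(params)
  report <- character(0)
  missing <- setdiff(model$roster, names(p))
  if (length(missing)) {
    report <- c(report, sprintf("missing parameter(s): %s",
                                paste(missing, collapse = ", ")))
  }
  chk <- function(name, ok, msg) {
    if (name %in% names(p) && !isTRUE(ok)) c(report, msg) else report
  }
  for (nm in intersect(names(p), .ONTOGENY_PARAM_NAMES)) {
    if (!is.finite(p[[nm]])) {
      report <- c(report, sprintf("%s is not finite", nm))
    }
  }
  report <- chk("F_birth", p$F_birth >= 0, "F_birth must be >= 0")
  report <- chk("F_max", p$F_max > 0, "F_max must be > 0")
  report <- chk("F_min", p$F_min >= 0, "F_min must be >= 0")
  report <- chk("gamma_u", p$gamma_u > 0,
                "Hill coefficient gamma_u must be > 0")
  report <- chk("gamma_d", p$gamma_d > 0,
                "Hill coefficient gamma_d must be > 0")
  report <- chk("Age_up50", p$Age_up50 > 0, "Age_up50 must be > 0")
  report <- chk("Age_down50", p$Age_down50 > 0, "Age_down50 must be > 0")
  report <- chk("K", p$K > 0, "development rate K must be > 0")
  report <- chk("AGECAP", p$AGECAP > 0, "AGECAP must be > 0")
  report <- chk("FRD", p$FRD >= 0 && p$FRD < 1, "FRD must lie in [0, 1)")
  gompertz_up <- model$family_id %in% c("eq2_gompertz_up", "eq4c", "eq4f")
  if (gompertz_up && !is.null(p$F_birth) && is.finite(p$F_birth) &&
      p$F_birth <= 0) {
    report <- c(report,
                "Gompertz rising limb requires F_birth > 0 (log of ratio)")
  }
  # Bell families: the adult asymptote F_max * (1 - FRD) = 1 is enforced by
  # deriving F_max; a user-supplied F_max must agree.
  if (model$shape == "bell" && model$family_id != "eq4g_double_sigmoid" &&
      !is.null(p$F_max) && !is.null(p$FRD) &&
      is.finite(p$F_max) && is.finite(p$FRD) && p$FRD < 1) {
    fmax_implied <- 1 / (1 - p$FRD)
    if (abs(p$F_max - fmax_implied) > 1e-6 * fmax_implied) {
      report <- c(report, sprintf(
        "F_max = %.6g inconsistent with adult asymptote 1/(1-FRD) = %.6g",
        p$F_max, fmax_implied))
    }
  }
  report
}

assert_ontogeny_valid <- function(model, params) {
  rep <- validate_ontogeny_parameters(model, params)
  if (length(rep)) {
    stopf("invalid parameters for family %s: %s", model$family_id,
          paste(rep, collapse = "; "))
  }
  invisible(TRUE)
}

# Limb building blocks --------------------------------------------------------

# Rising Hill limb from F_birth to F_max.
.limb_hill_up <- function(age, F_birth, F_max, Age_up50, gamma_u) {
  F_birth + (F_max - F_birth) * hill_age(age, Age_up50, gamma_u)
}

# Rising (generalised) Gompertz limb from F_birth to F_max; shape = 1 gives
# the classic Gompertz in age with development rate K.
.limb_gompertz_up <- function(age, F_birth, F_max, K, shape = 1) {
  F_max * exp(log(F_birth / F_max) * exp(-(K * pmax(age, 0))^shape))
}

# Declining Hill limb from 1 to (1 - FRD).
.limb_hill_down <- function(age, FRD, Age_down50, gamma_d) {
  1 - FRD * hill_age(age, Age_down50, gamma_d)
}

# Declining Gompertz limb from 1 to (1 - FRD); x is the scaled age term.
.limb_gompertz_down <- function(x, FRD) {
  (1 - FRD)^(1 - exp(-x))
}

#' Evaluate an ontogeny model at one or more ages
#'
#' Returns `F_activity`, the fraction of the adult activity at each age.
#' Capped families return exactly 1 for ages at or beyond `AGECAP`.
#'
#' @param model An [ontogeny_model()] or family identifier string.
#' @param params An [ontogeny_parameters()] set covering the family roster.
#' @param age Numeric vector of postnatal ages in years (all `>= 0`).
#' @return Numeric vector of fractional activities (`>= 0`).
#' @export
#' @examples
#' m <- ontogeny_model("eq1_sigmoid_up")
#' p <- ontogeny_parameters(F_birth = 0.2, F_max = 1, Age_up50 = 0.5,
#'                          gamma_u = 2)
#' evaluate_ontogeny(m, p, c(0, 0.5, 2, 35))
evaluate_ontogeny <- function(model, params, age) {
  if (is.character(model)) model <- ontogeny_model(model)
  params <- as_ontogeny_parameters(params)
  if (any(!is.finite(age)) || any(age < 0)) {
    stopf("ages must be finite and >= 0")
  }
  assert_ontogeny_valid(model, params)
  p <- as.list(params)
  fmax_bell <- if (!is.null(p$FRD)) 1 / (1 - p$FRD) else NULL
  f <- switch(
    model$family_id,
    eq1_sigmoid_up =
      .limb_hill_up(age, p$F_birth, p$F_max, p$Age_up50, p$gamma_u),
    eq2_gompertz_up =
      .limb_gompertz_up(age, p$F_birth, p$F_max, p$K),
    eq3a_sigmoid_down =
      p$F_min + (p$F_birth - p$F_min) *
        (1 - hill_age(age, p$Age_down50, p$gamma_d)),
    eq3b_exp_down =
      p$F_min + (p$F_birth - p$F_min) * exp(-p$K * age),
    eq4a = ,
    eq4b =
      .limb_hill_up(age, p$F_birth, fmax_bell, p$Age_up50, p$gamma_u) *
        .limb_hill_down(age, p$FRD, p$Age_down50, p$gamma_d),
    eq4c =
      .limb_gompertz_up(age, p$F_birth, fmax_bell, p$K, p$gamma_u) *
        .limb_hill_down(age, p$FRD, p$Age_down50, p$gamma_d),
    eq4d =
      .limb_hill_up(age, p$F_birth, fmax_bell, p$Age_up50, p$gamma_u) *
        .limb_gompertz_down((p$K * age)^p$gamma_d, p$FRD),
    eq4e =
      pmax(0, p$F_birth + (fmax_bell - p$F_birth) *
             hill_age(age, p$Age_up50, p$gamma_u) -
             fmax_bell * p$FRD * hill_age(age, p$Age_down50, p$gamma_d)),
    eq4f =
      .limb_gompertz_up(age, p$F_birth, fmax_bell, p$K, p$gamma_u) *
        .limb_gompertz_down((age / p$Age_down50)^p$gamma_d, p$FRD),
    eq4g_double_sigmoid =
      (p$F_birth * exp(-p$K * age) +
         p$F_max * (1 - exp(-p$K * age)) *
           hill_age(age, p$Age_up50, p$gamma_u)) *
        .limb_hill_down(age, p$FRD, p$Age_down50, p$gamma_d),
    stopf("unknown ontogeny family '%s'", model$family_id)
  )
  if (model$capped) f[age >= p$AGECAP] <- 1
  pmax(f, 0)
}

#' A constant (flat) ontogeny: activity equal to the adult value at all ages
#'
#' Used when a pathway's maturation is ignored, e.g. in the post hoc
#' clearance-versus-age scan that deliberately omits the target pathway's
#' ontogeny.
#'
#' @return A list with elements `model` and `params`.
#' @export
flat_ontogeny <- function() {
  list(model = ontogeny_model("eq1_sigmoid_up"),
       params = ontogeny_parameters(F_birth = 1, F_max = 1, Age_up50 = 1,
                                    gamma_u = 1))
}

# Fixed (non-estimable) system profiles ---------------------------------------

.load_profiles <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.onto_env$profiles)) return(.onto_env$profiles)
    path <- onto_extdata("ontogeny_profiles.yaml")
  }
  prof <- yaml::read_yaml(path)
  .onto_env$profiles <- prof
  prof
}

#' Fixed ontogeny profiles for well-characterised pathways
#'
#' Frozen (non-estimable) maturation functions intended as system inputs:
#' two published-style hepatic CYP3A profiles (which disagree in infancy, a
#' known inconsistency in the literature), a glomerular-filtration
#' maturation curve, and the bundled `risdiplam_case` bell-shaped example
#' truth used by the simulator (activity peaking near 3x adult around 2
#' years of age). Constants are read from the packaged, editable
#' `ontogeny_profiles.yaml`.
#'
#' @param name Profile identifier, e.g. `"CYP3A_profile1"`,
#'   `"CYP3A_profile2"`, `"GFR_maturation"`, `"risdiplam_case"`.
#' @param path Optional path to an alternative profiles file.
#' @return A list with elements `model` ([ontogeny_model()]), `params`
#'   ([ontogeny_parameters()]) and `note` (provenance string).
#' @export
#' @examples
#' prof <- fixed_profile("CYP3A_profile1")
#' evaluate_ontogeny(prof$model, prof$params, c(0, 1, 35))
fixed_profile <- function(name, path = NULL) {
  prof <- .load_profiles(path)
  entry <- prof[[name]]
  if (is.null(entry)) {
    stopf("unknown fixed profile '%s'; available: %s", name,
          paste(names(prof), collapse = ", "))
  }
  params <- do.call(ontogeny_parameters, entry$parameters)
  model <- ontogeny_model(entry$family)
  assert_ontogeny_valid(model, params)
  list(model = model, params = params, note = entry$note %||% "")
}

# Serialisation ----------------------------------------------------------------

#' Serialise an ontogeny model + parameters to a config block
#'
#' @param model An [ontogeny_model()].
#' @param params An [ontogeny_parameters()] set.
#' @return A plain list (`family`, `parameters`) suitable for YAML.
#' @export
ontogeny_to_config <- function(model, params) {
  params <- as_ontogeny_parameters(params)
  list(family = model$family_id, parameters = as.list(params))
}

#' Rebuild an ontogeny model + parameters from a config block
#'
#' @param config A list as produced by [ontogeny_to_config()].
#' @return A list with elements `model` and `params`.
#' @export
ontogeny_from_config <- function(config) {
  model <- ontogeny_model(config$family)
  params <- do.call(ontogeny_parameters, config$parameters)
  list(model = model, params = params)
}
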