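# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Adult reference age used for normalisation and adult-identity checks
#'
#' Fractional ontogeny curves are expressed relative to the typical adult;
#' 35 years is the conventional reference in paediatric scaling and is the
#' age at which the packaged physiology table defines its adult constants.
#'
#' @return Age in years (35).
#' @export
adult_reference_age <- function() 35

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Hill function in age; returns 0 at age <= 0 for any exponent.
hill_age <- function(age, a50, gamma) {
  out <- numeric(length(age))
  pos <- age > 0
  out[pos] <- age[pos]^gamma / (a50^gamma + age[pos]^gamma)
  out
}

# Locate the installed copy of a packaged constants/config file.
onto_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ontopbpk")
  if (!nzchar(path)) stopf("packaged data file '%s' not found", file)
  path
}

# mg/L -> ng/mL conversion for plasma concentrations.
MGL_TO_NGML <- 1000
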