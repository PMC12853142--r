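# Model qualification: post hoc clearance-age scan, multi-family ontogeny
# scan, nonparametric bootstrap, visual predictive check, goodness of fit,
# and comparison against independent external ontogeny observations.

.DEFAULT_AGE_BANDS <- c(0, 2, 12, 18, Inf)

.age_stratum <- function(age, bands = .DEFAULT_AGE_BANDS) {
  cut(age, bands, right = FALSE, include.lowest = TRUE)
}

#' Post hoc clearance-versus-age scan
#'
#' Fits the population model *without* ontogeny on the target pathway
#' (activity fixed at 1 at all ages) and examines how the per-subject
#' empirical Bayes intrinsic-clearance effects vary with age. The shape of
#' that relationship indicates which ontogeny model class the data call
#' for.
#'
#' @param drug A [load_drug_config()] object.
#' @param data Dataset.
#' @param target_pathway Pathway whose ontogeny is deliberately omitted.
#' @param flat_window Log-scale half-width below which the smoothed trend
#'   is classified as flat.
#' @param ... Passed to [fit_population_model()].
#' @return A list of class `posthoc_scan`: `table` (one row per subject
#'   with observations: ID, age, post hoc CL_int and eta), `trend`
#'   (classification, Spearman rho with CI, smoothed curve) and `fit`.
#' @export
posthoc_age_scan <- function(drug, data, target_pathway = "FMO3",
                             flat_window = 0.3, ...) {
  spec <- popmodel_spec(drug, target_pathway = target_pathway,
                        family = NULL)
  fit <- fit_population_model(spec, data, ...)
  ebe <- empirical_bayes(fit, data)
  tab <- data.frame(ID = ebe$ID, age = ebe$AGE, CL_int = ebe$CL_int,
                    eta_CL = ebe$eta_CL_int %||% 0)
  lx <- log(tab$age)
  lo <- loess(tab$eta_CL ~ lx, span = 0.75)
  grid <- seq(min(lx), max(lx), length.out = 80)
  sm <- predict(lo, data.frame(lx = grid))
  rng <- range(sm)
  n <- nrow(tab)
  rho <- suppressWarnings(cor(tab$age, tab$eta_CL, method = "spearman"))
  z <- atanh(rho)
  zse <- 1.06 / sqrt(n - 3)   # Fieller-type SE for Spearman
  rho_ci <- tanh(z + c(-1, 1) * qnorm(0.975) * zse)
  peak_i <- which.max(sm)
  interior <- peak_i > 4 && peak_i < length(sm) - 4
  class <- if (diff(rng) < flat_window) "flat"
    else if (interior && sm[peak_i] > sm[1] + flat_window / 2 &&
               sm[peak_i] > sm[length(sm)] + flat_window / 2) "bell"
    else if (sm[length(sm)] > sm[1]) "rising" else "falling"
  structure(list(
    table = tab,
    trend = list(class = class, rho = rho, rho_ci = rho_ci,
                 smooth = data.frame(age = exp(grid), eta = sm)),
    fit = fit), class = "posthoc_scan")
}

#' @export
print.posthoc_scan <- function(x, ...) {
  cat(sprintf("<post hoc CL_int-age scan: %d subjects, trend '%s', Spearman rho %.2f [%.2f, %.2f]>\n",
              nrow(x$table), x$trend$class, x$trend$rho, x$trend$rho_ci[1],
              x$trend$rho_ci[2]))
  invisible(x)
}

#' Multi-family ontogeny scan
#'
#' Estimates the target pathway's ontogeny with each requested structural
#' family (from family-appropriate neutral starts), ranks the fits by
#' OFV/AIC, and flags the age strata in which the fitted curves agree
#' within a relative tolerance — the qualitative pattern being that
#' near-degenerate families agree where data are informative and diverge
#' where they are not.
#'
#' @param data Dataset.
#' @param families Character vector of family identifiers (default: the
#'   six bell-shaped families).
#' @param drug A [load_drug_config()] object.
#' @param target_pathway Estimated pathway.
#' @param age_grid Shared age grid for the fitted curves.
#' @param agreement_tol Relative spread below which families "agree".
#' @param ... Passed to [fit_population_model()].
#' @return A list of class `ontogeny_scan`: `table` (family, OFV, AIC,
#'   deltas, convergence), `curves` (age grid x family), `agreement`
#'   (per-stratum flags), `fits`.
#' @export
ontogeny_scan <- function(data,
                          families = c("eq4a", "eq4b", "eq4c", "eq4d",
                                       "eq4e", "eq4f"),
                          drug = load_drug_config(),
                          target_pathway = "FMO3",
                          age_grid = c(0.05, 0.1, 1 / 6, 1 / 3, 0.5, 0.75,
                                       1, 1.5, 2, 3, 4, 6, 8, 12, 18, 35),
                          agreement_tol = 0.2, ...) {
  if (length(families) < 1L) stopf("need at least one family")
  fits <- list()
  rows <- list()
  for (fam in families) {
    fit <- try(fit_population_model(
      popmodel_spec(drug, target_pathway = target_pathway, family = fam),
      data, ...), silent = TRUE)
    ok <- !inherits(fit, "try-error")
    fits[[fam]] <- if (ok) fit else NULL
    rows[[fam]] <- data.frame(
      family = fam,
      ofv = if (ok) fit$ofv else NA_real_,
      aic = if (ok) fit_aic(fit) else NA_real_,
      converged = ok && fit$convergence == 0,
      failed = !ok)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$delta_ofv <- tab$ofv - min(tab$ofv, na.rm = TRUE)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  curves <- vapply(families, function(fam) {
    if (is.null(fits[[fam]])) rep(NA_real_, length(age_grid))
    else fitted_ontogeny(fits[[fam]], age_grid)
  }, numeric(length(age_grid)))
  curves <- matrix(curves, nrow = length(age_grid),
                   dimnames = list(NULL, families))
  ok_cols <- colSums(is.na(curves)) == 0
  spread <- apply(curves[, ok_cols, drop = FALSE], 1, function(v) {
    (max(v) - min(v)) / max(median(v), 1e-9)
  })
  stratum <- .age_stratum(age_grid)
  agree <- tapply(spread <= agreement_tol, stratum, all)
  structure(list(table = tab, curves = curves, age_grid = age_grid,
                 spread = spread, agreement = agree,
                 agreement_tol = agreement_tol, fits = fits),
            class = "ontogeny_scan")
}

#' @export
print.ontogeny_scan <- function(x, ...) {
  cat(sprintf("<ontogeny scan: %d families>\n", nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Nonparametric bootstrap of a population PBPK fit
#'
#' Subjects are resampled with replacement, stratified by age band so that
#' sparse paediatric strata keep their representation, and the model is
#' refitted to every resample starting from the original estimates.
#'
#' @param spec A [popmodel_spec()].
#' @param data Dataset.
#' @param fit Original fit supplying starting values (fitted here when
#'   `NULL`).
#' @param n_resamples Number of bootstrap resamples (`>= 1`).
#' @param seed Integer seed.
#' @param age_bands Stratification boundaries in years.
#' @param ... Passed to the per-resample [fit_population_model()] calls
#'   (which default to a single start and no standard errors).
#' @return A list of class `ontopbpk_bootstrap`: `ci` (2.5/50/97.5
#'   percentiles per parameter), `estimates` (per-resample), and the
#'   failure rate.
#' @export
bootstrap_fit <- function(spec, data, fit = NULL, n_resamples = 200,
                          seed = 1, age_bands = .DEFAULT_AGE_BANDS, ...) {
  if (n_resamples < 1) stopf("n_resamples must be >= 1")
  ids <- unique(data$ID)
  if (length(ids) < 2L) stopf("degenerate design: need >= 2 subjects")
  if (is.null(fit)) fit <- fit_population_model(spec, data, ...)
  ages <- data$AGE[match(ids, data$ID)]
  stratum <- .age_stratum(ages, age_bands)
  inits <- c(as.list(fit$theta),
             setNames(as.list(fit$omega),
                      paste0("omega_", names(fit$omega))),
             sigma_prop = unname(fit$sigma[["prop"]]),
             sigma_add = unname(fit$sigma[["add"]]))
  set.seed(seed)
  draws <- vector("list", n_resamples)
  n_fail <- 0L
  for (r in seq_len(n_resamples)) {
    take <- unlist(lapply(levels(stratum), function(s) {
      pool <- ids[which(stratum == s)]
      if (!length(pool)) return(NULL)
      sample(pool, length(pool), replace = TRUE)
    }))
    pieces <- lapply(seq_along(take), function(k) {
      d <- data[data$ID == take[k], , drop = FALSE]
      d$ID <- k
      d
    })
    boot_data <- do.call(rbind, pieces)
    bf <- try(fit_population_model(spec, boot_data, inits = inits,
                                   n_starts = 1, compute_se = FALSE, ...),
              silent = TRUE)
    if (inherits(bf, "try-error") || bf$convergence != 0) {
      n_fail <- n_fail + 1L
      next
    }
    draws[[r]] <- c(bf$theta, setNames(bf$omega,
                                       paste0("omega_", names(bf$omega))),
                    sigma_prop = unname(bf$sigma[["prop"]]))
  }
  est <- do.call(rbind, draws[!vapply(draws, is.null, TRUE)])
  if (is.null(est) || nrow(est) == 0L) {
    stopf("all %d bootstrap refits failed", n_resamples)
  }
  ci <- t(apply(est, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  structure(list(ci = ci, estimates = est, n_resamples = n_resamples,
                 failure_rate = n_fail / n_resamples, seed = seed),
            class = "ontopbpk_bootstrap")
}

#' @export
print.ontopbpk_bootstrap <- function(x, ...) {
  cat(sprintf("<bootstrap: %d resamples, %.0f%% failed>\n", x$n_resamples,
              100 * x$failure_rate))
  print(signif(x$ci, 4))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model and the
#' observed design, and compares observed concentration percentiles
#' (5/50/95) with the simulation-based 95% prediction bands of each
#' percentile. Binning is by time-after-dose bins within age strata
#' (`by = "tad"`) or by age bins (`by = "age"`).
#'
#' @param fit An `ontopbpk_fit`.
#' @param data Dataset.
#' @param n_sim Number of replicate simulations.
#' @param bins Number of time-after-dose bins per stratum (or age bins).
#' @param by `"tad"` or `"age"`.
#' @param seed Integer seed.
#' @param age_bands Age strata boundaries (used when `by = "tad"`).
#' @return A list of class `ontopbpk_vpc` with the percentile table (one
#'   row per bin: observed and simulated-band percentiles, bin ranges and
#'   counts).
#' @export
vpc <- function(fit, data, n_sim = 200, bins = 4, by = c("tad", "age"),
                seed = 1, age_bands = .DEFAULT_AGE_BANDS) {
  by <- match.arg(by)
  spec <- fit$spec
  ctx <- .build_ctx(spec, data)
  obs <- ctx$prep$obs
  tad <- tapply(ctx$prep$contrib$tad, ctx$prep$contrib$obs, min)
  tad <- as.numeric(tad[as.character(seq_len(nrow(obs)))])
  age <- ctx$prep$subjects$AGE[obs$subject]
  if (by == "tad") {
    stratum <- .age_stratum(age, age_bands)
    qs <- quantile(tad, probs = seq(0, 1, length.out = bins + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    tbin <- cut(tad, unique(qs))
    bin <- interaction(stratum, tbin, drop = TRUE)
  } else {
    qs <- quantile(age, probs = seq(0, 1, length.out = bins + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    bin <- cut(age, unique(qs))
  }
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- do.call(rbind, tapply(obs$dv, bin, quantile, probs = probs))
  sims <- array(NA_real_, c(nlevels(bin), length(probs), n_sim))
  omega <- fit$omega
  sigma <- fit$sigma
  n_sub <- ctx$n_sub
  for (r in seq_len(n_sim)) {
    # same draw order as simulate_from_dataset, without rebuilding the
    # context each replicate
    set.seed(seed + r)
    eta <- matrix(0, n_sub, length(omega),
                  dimnames = list(NULL, names(omega)))
    for (nm in names(omega)) eta[, nm] <- rnorm(n_sub, 0, sqrt(omega[[nm]]))
    pred <- .predict_obs(ctx, fit$theta, names(omega), eta)
    dv_r <- pmax(pred * (1 + sigma[["prop"]] * rnorm(length(pred))) +
                   sigma[["add"]] * rnorm(length(pred)), 0)
    sims[, , r] <- do.call(rbind, tapply(dv_r, bin, quantile, probs = probs))
  }
  band <- apply(sims, c(1, 2), quantile, probs = c(0.025, 0.5, 0.975))
  tab <- data.frame(bin = levels(bin), n = as.integer(table(bin)),
                    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
                    obs_p95 = obs_pct[, 3],
                    sim_p5_lo = band[1, , 1], sim_p5_hi = band[3, , 1],
                    sim_p50_lo = band[1, , 2], sim_p50_md = band[2, , 2],
                    sim_p50_hi = band[3, , 2],
                    sim_p95_lo = band[1, , 3], sim_p95_hi = band[3, , 3])
  rownames(tab) <- NULL
  empty <- tab$n == 0
  if (any(empty)) warnf("%d empty VPC bin(s)", sum(empty))
  structure(list(table = tab, by = by, n_sim = n_sim, seed = seed),
            class = "ontopbpk_vpc")
}

#' @export
print.ontopbpk_vpc <- function(x, ...) {
  cover <- mean(x$table$obs_p50 >= x$table$sim_p50_lo &
                  x$table$obs_p50 <= x$table$sim_p50_hi)
  cat(sprintf("<VPC by %s: %d bins, median covered in %.0f%% of bins (%d sims)>\n",
              x$by, nrow(x$table), 100 * cover, x$n_sim))
  invisible(x)
}

#' VPC plot (observed percentiles vs simulated prediction bands)
#' @param x An `ontopbpk_vpc`.
#' @return A ggplot object.
#' @export
plot_vpc <- function(x) {
  tab <- x$table
  tab$idx <- seq_len(nrow(tab))
  ggplot2::ggplot(tab, ggplot2::aes(x = idx)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo, ymax = sim_p50_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50)) +
    ggplot2::geom_point(ggplot2::aes(y = obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p95), linetype = 2) +
    ggplot2::labs(x = "bin", y = "concentration (ng/mL)",
                  title = "Visual predictive check") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit summary
#'
#' Population predictions (random effects at 0), individual predictions
#' (empirical Bayes modes) and first-order conditional-style weighted
#' residuals, whose variance combines the linearised random-effect
#' contribution with the residual model. Under the true model the weighted
#' residuals have mean ~0 and variance ~1.
#'
#' @param fit An `ontopbpk_fit`.
#' @param data Dataset.
#' @param trend_threshold Absolute smoothed-residual size above which a
#'   residual-age trend is flagged.
#' @return A list of class `ontopbpk_gof`: per-observation `table` (DV,
#'   PRED, IPRED, WRES, age, tad), `summary` (residual moments), and the
#'   age-trend flag.
#' @export
gof <- function(fit, data, trend_threshold = 0.5) {
  spec <- fit$spec
  ctx <- .build_ctx(spec, data)
  obs <- ctx$prep$obs
  omega_names <- names(fit$omega)
  pred0 <- .predict_obs(ctx, fit$theta, omega_names, eta = NULL)
  res_eb <- .ofv_cpp(ctx, fit$theta, fit$omega, fit$sigma)
  eta <- res_eb$eta
  if (length(omega_names)) colnames(eta) <- omega_names
  ipred <- .predict_obs(ctx, fit$theta, omega_names, eta = eta)
  # linearised variance: G Omega G' + g^2 with G = df/deta at eta = 0
  var_lin <- (fit$sigma[["prop"]] * pred0)^2 + fit$sigma[["add"]]^2
  h <- 1e-4
  for (nm in omega_names) {
    ep <- matrix(0, ctx$n_sub, length(omega_names),
                 dimnames = list(NULL, omega_names))
    ep[, nm] <- h
    gcol <- (.predict_obs(ctx, fit$theta, omega_names, ep) -
               .predict_obs(ctx, fit$theta, omega_names, -ep)) / (2 * h)
    var_lin <- var_lin + gcol^2 * fit$omega[[nm]]
  }
  wres <- (obs$dv - pred0) / sqrt(var_lin)
  age <- ctx$prep$subjects$AGE[obs$subject]
  tad <- tapply(ctx$prep$contrib$tad, ctx$prep$contrib$obs, min)
  tad <- as.numeric(tad[as.character(seq_len(nrow(obs)))])
  tab <- data.frame(ID = ctx$prep$subjects$ID[obs$subject], age = age,
                    tad = tad, DV = obs$dv, PRED = pred0, IPRED = ipred,
                    WRES = wres)
  lo <- loess(wres ~ log(age), span = 0.75)
  grid <- seq(min(log(age)), max(log(age)), length.out = 60)
  sm <- predict(lo, data.frame(age = exp(grid)))
  trend <- max(abs(sm)) > trend_threshold
  structure(list(
    table = tab,
    summary = c(mean_wres = mean(wres), var_wres = var(wres)),
    age_trend = list(flagged = trend, max_abs_smooth = max(abs(sm)),
                     smooth = data.frame(age = exp(grid), wres = sm))),
    class = "ontopbpk_gof")
}

#' @export
print.ontopbpk_gof <- function(x, ...) {
  cat(sprintf("<GOF: %d obs, WRES mean %.3f var %.3f, age trend %s>\n",
              nrow(x$table), x$summary[["mean_wres"]],
              x$summary[["var_wres"]],
              if (x$age_trend$flagged) "FLAGGED" else "none"))
  invisible(x)
}

#' Goodness-of-fit plots (observed vs predicted; residuals vs age)
#' @param x An `ontopbpk_gof`.
#' @return A ggplot object.
#' @export
plot_gof <- function(x) {
  tab <- x$table
  p1 <- ggplot2::ggplot(tab, ggplot2::aes(PRED, DV)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(title = "Observed vs population predicted") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(tab, ggplot2::aes(age, WRES)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = "Weighted residuals vs age") +
    ggplot2::theme_minimal()
  list(obs_vs_pred = p1, res_vs_age = p2)
}

#' Compare estimated ontogeny curves with independent external data
#'
#' @param scan An `ontogeny_scan` (or a single `ontopbpk_fit`).
#' @param external data.frame with columns `age`, `value`
#'   (fraction-of-adult activity, `> 0`) and optionally `source`.
#' @param fold_limit Agreement limit (default 2-fold).
#' @return A list of class `external_comparison`: per-point fold
#'   differences per family and the fraction within the fold limit.
#' @export
compare_external <- function(scan, external, fold_limit = 2) {
  if (nrow(external) < 1L) stopf("need at least one external point")
  if (any(external$value <= 0)) stopf("external values must be > 0")
  fits <- if (inherits(scan, "ontopbpk_fit")) {
    setNames(list(scan), scan$spec$family$family_id)
  } else Filter(Negate(is.null), scan$fits)
  rows <- list()
  for (fam in names(fits)) {
    pred <- fitted_ontogeny(fits[[fam]], external$age)
    rows[[fam]] <- data.frame(
      family = fam, age = external$age, observed = external$value,
      predicted = pred, fold = pred / external$value,
      source = external$source %||% NA)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  within <- tapply(pmax(tab$fold, 1 / tab$fold) <= fold_limit, tab$family,
                   mean)
  structure(list(table = tab, fraction_within = within,
                 fold_limit = fold_limit),
            class = "external_comparison")
}

#' @export
print.external_comparison <- function(x, ...) {
  cat(sprintf("<external comparison: %d points, within %g-fold:>\n",
              nrow(x$table), x$fold_limit))
  print(round(x$fraction_within, 3))
  invisible(x)
}
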