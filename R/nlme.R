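# Nonlinear mixed-effects estimation: population model specification,
# Laplace marginal likelihood (compiled core with a pure-R reference
# backend), optimisation with multi-start, standard errors from the
# numerically differentiated Hessian, and empirical Bayes estimates.

# Fixed-effect transforms: positive parameters on the log scale, Hill
# coefficients bounded in [0.1, 15] via logit, FRD in [0, 1) via logit.
.GAMMA_BOUNDS <- c(0.1, 15)

.tf_fwd <- function(name, v) {
  if (name %in% c("gamma_u", "gamma_d")) {
    qlogis((v - .GAMMA_BOUNDS[1]) / diff(.GAMMA_BOUNDS))
  } else if (name == "FRD") qlogis(v) else log(v)
}

.tf_inv <- function(name, x) {
  if (name %in% c("gamma_u", "gamma_d")) {
    .GAMMA_BOUNDS[1] + diff(.GAMMA_BOUNDS) * plogis(x)
  } else if (name == "FRD") plogis(x) else exp(x)
}

# d(natural)/d(transformed), for delta-method standard errors
.tf_jac <- function(name, x) {
  if (name %in% c("gamma_u", "gamma_d")) {
    diff(.GAMMA_BOUNDS) * plogis(x) * (1 - plogis(x))
  } else if (name == "FRD") plogis(x) * (1 - plogis(x)) else exp(x)
}

#' Family-appropriate generic starting values for ontogeny parameters
#'
#' Neutral mid-range starts used by [fit_population_model()] and the
#' multi-family scan; deliberately not centred on any particular truth.
#'
#' @param family_id Ontogeny family identifier.
#' @return Named numeric vector covering the family roster.
#' @export
ontogeny_default_inits <- function(family_id) {
  all <- c(F_birth = 0.5, F_max = 1.5, F_min = 0.8, Age_up50 = 0.5,
           gamma_u = 2, Age_down50 = 5, gamma_d = 3, FRD = 0.5, K = 1,
           AGECAP = 20)
  all[ontogeny_model(family_id)$roster]
}

#' Specify a population PBPK model for estimation
#'
#' Binds a drug configuration to the estimation problem: which pathway's
#' ontogeny is estimated and with which structural family, which
#' fixed-effect parameters are free, the random-effect structure
#' (log-normal, diagonal) and the residual model (proportional CV plus an
#' additive floor).
#'
#' @param drug A [load_drug_config()] object; its non-target pathways keep
#'   their fixed ontogeny profiles.
#' @param target_pathway Pathway whose ontogeny is estimated (or forced
#'   flat when `family` is `NULL`, as in the post hoc age scan).
#' @param family Ontogeny family identifier for the target pathway, or
#'   `NULL` for no ontogeny (activity fixed at 1 at all ages).
#' @param ontogeny_init Named starting values for the family's parameters;
#'   defaults to [ontogeny_default_inits()].
#' @param theta_init Starting values for `CLint_adult` (whole-liver adult
#'   intrinsic clearance, L/h), `V_ref` (L) and `ka` (1/h); defaults from
#'   the drug config.
#' @param eta_on Random-effect placement: subset of
#'   `c("CL_int", "V", "ka")`.
#' @param omega_init Named variances of the log-normal random effects.
#' @param sigma_init `c(prop = , add = )` residual parameters; the additive
#'   term has a floor of 1e-6 and is fixed by default.
#' @param fixed Names of parameters to fix at their initial values: theta
#'   names, `omega_<name>`, `sigma_prop`, `sigma_add`.
#' @return An object of class `popmodel_spec`.
#' @export
popmodel_spec <- function(drug, target_pathway = "FMO3", family = "eq4a",
                          ontogeny_init = NULL, theta_init = NULL,
                          eta_on = c("CL_int", "V"),
                          omega_init = c(CL_int = 0.09, V = 0.04),
                          sigma_init = c(prop = 0.15, add = 0.1),
                          fixed = "sigma_add") {
  if (!target_pathway %in% names(drug$pathway_ontogeny)) {
    stopf("target pathway '%s' not in drug config", target_pathway)
  }
  eta_on <- match.arg(eta_on, c("CL_int", "V", "ka"), several.ok = TRUE)
  fam <- if (!is.null(family)) ontogeny_model(family) else NULL
  onto <- if (!is.null(fam)) {
    init <- ontogeny_default_inits(fam$family_id)
    if (!is.null(ontogeny_init)) {
      init[names(ontogeny_init)] <- ontogeny_init
    }
    init
  } else NULL
  theta_pk <- c(CLint_adult = drug$CLint_adult_total, V_ref = drug$V_ref,
                ka = drug$ka)
  if (!is.null(theta_init)) theta_pk[names(theta_init)] <- theta_init
  omega <- omega_init[eta_on]
  if (any(is.na(omega))) stopf("omega_init must cover eta_on")
  sigma <- c(prop = unname(sigma_init["prop"]),
             add = max(unname(sigma_init["add"]), 1e-6))
  structure(list(drug = drug, target_pathway = target_pathway,
                 family = fam, theta = c(theta_pk, onto),
                 eta_on = eta_on, omega = omega, sigma = sigma,
                 fixed = fixed),
            class = "popmodel_spec")
}

# --- estimation context -------------------------------------------------------

.build_ctx <- function(spec, data) {
  prep <- .prepare_obs(data)
  subj <- prep$subjects
  physio <- profile_for_age(subj$AGE, body_weight = subj$WT)
  drug <- spec$drug
  # fixed (non-estimated) pathway activities
  act_fixed <- vapply(names(drug$pathway_ontogeny), function(p) {
    if (p == spec$target_pathway) rep(1, nrow(subj)) else {
      b <- drug$pathway_ontogeny[[p]]
      evaluate_ontogeny(b$model, b$params, subj$AGE)
    }
  }, numeric(nrow(subj)))
  act_fixed <- matrix(act_fixed, nrow = nrow(subj),
                      dimnames = list(NULL, names(drug$pathway_ontogeny)))
  renal <- drug$renal_ontogeny
  renal_act <- evaluate_ontogeny(renal$model, renal$params, subj$AGE) /
    evaluate_ontogeny(renal$model, renal$params, adult_reference_age())
  list(prep = prep, spec = spec, n_sub = nrow(subj),
       age = subj$AGE, wt = subj$WT,
       scaling = physio$MPPGL * physio$liver_weight * UL_MIN_TO_L_H,
       qh = physio$Q_H,
       clr = drug$CLR_adult * renal_act * physio$bsa /
         drug$adult_profile$bsa,
       wt_ratio = subj$WT / drug$adult_profile$body_weight,
       act_fixed = act_fixed)
}

# per-subject structural bases for a given theta
.subject_bases <- function(ctx, theta) {
  spec <- ctx$spec
  drug <- spec$drug
  scale_cl <- theta[["CLint_adult"]] / drug$CLint_adult_total
  act <- ctx$act_fixed
  if (!is.null(spec$family)) {
    roster <- spec$family$roster
    act[, spec$target_pathway] <-
      evaluate_ontogeny(spec$family, theta[roster], ctx$age)
  }
  per_mg <- drug$CLint_per_mg * scale_cl
  clint <- as.numeric(act %*% per_mg) * ctx$scaling
  list(clint_base = clint,
       vbase = theta[["V_ref"]] * ctx$wt_ratio^drug$vol_allometric_exponent,
       kabase = rep(theta[["ka"]], ctx$n_sub))
}

.ofv_cpp <- function(ctx, theta, omega, sigma, eta_start = NULL) {
  bases <- .subject_bases(ctx, theta)
  prep <- ctx$prep
  q <- length(omega)
  use <- c("CL_int", "V", "ka") %in% names(omega)
  if (is.null(eta_start)) eta_start <- matrix(0, ctx$n_sub, max(q, 1))
  res <- ofv_laplace_cpp(
    obs_subject = as.integer(prep$obs$subject - 1L),
    obs_dv = prep$obs$dv,
    contrib_obs = as.integer(prep$contrib$obs - 1L),
    contrib_amt = prep$contrib$amt, contrib_tad = prep$contrib$tad,
    contrib_ii = prep$contrib$ii, contrib_ss = as.integer(prep$contrib$ss),
    clint_base = bases$clint_base, qh = ctx$qh, clr = ctx$clr,
    vbase = bases$vbase, kabase = bases$kabase,
    fub = ctx$spec$drug$fu_B, fafg = ctx$spec$drug$FaFg,
    eta_flags = use, omega = unname(omega),
    sig_prop = sigma[["prop"]], sig_add = sigma[["add"]],
    eta_start = eta_start)
  res
}

# Vectorised per-observation predictions for given theta and eta matrix.
.predict_obs <- function(ctx, theta, omega_names, eta = NULL) {
  bases <- .subject_bases(ctx, theta)
  n <- ctx$n_sub
  e <- function(nm) {
    if (!is.null(eta) && nm %in% colnames(eta)) eta[, nm] else numeric(n)
  }
  if (!is.null(eta) && is.null(colnames(eta))) colnames(eta) <- omega_names
  clint <- bases$clint_base * exp(e("CL_int"))
  denom <- ctx$qh + ctx$spec$drug$fu_B * clint
  clh <- ctx$qh * ctx$spec$drug$fu_B * clint / denom
  Fb <- ctx$spec$drug$FaFg * ctx$qh / denom
  cl <- clh + ctx$clr
  V <- bases$vbase * exp(e("V"))
  ka <- bases$kabase * exp(e("ka"))
  con <- ctx$prep$contrib
  s_of_obs <- ctx$prep$obs$subject
  s <- s_of_obs[con$obs]
  contrib <- .conc_1cmt_oral(con$amt, Fb[s], V[s], cl[s], ka[s], con$tad,
                             ss = FALSE, ii = con$ii)
  is_ss <- con$ss > 0
  if (any(is_ss)) {
    contrib[is_ss] <- .conc_1cmt_oral(con$amt[is_ss], Fb[s][is_ss],
                                      V[s][is_ss], cl[s][is_ss],
                                      ka[s][is_ss], con$tad[is_ss],
                                      ss = TRUE, ii = con$ii[is_ss])
  }
  pred <- numeric(nrow(ctx$prep$obs))
  agg <- rowsum(contrib, con$obs)
  pred[as.integer(rownames(agg))] <- agg[, 1]
  pmax(pred, 0)
}

# --- packing ------------------------------------------------------------------

.pack_names <- function(spec) {
  c(names(spec$theta), paste0("omega_", names(spec$omega)),
    "sigma_prop", "sigma_add")
}

.pack <- function(spec, theta, omega, sigma) {
  x <- c(
    vapply(names(theta), function(nm) .tf_fwd(nm, theta[[nm]]), 0),
    log(sqrt(omega)),
    log(sigma[["prop"]]), log(sigma[["add"]]))
  names(x) <- .pack_names(spec)
  x
}

.unpack <- function(spec, x) {
  nt <- length(spec$theta)
  no <- length(spec$omega)
  theta <- vapply(seq_len(nt), function(i) {
    .tf_inv(names(spec$theta)[i], x[[i]])
  }, 0)
  names(theta) <- names(spec$theta)
  omega <- exp(2 * x[nt + seq_len(no)])
  names(omega) <- names(spec$omega)
  sigma <- c(prop = exp(x[[nt + no + 1]]),
             add = max(exp(x[[nt + no + 2]]), 1e-6))
  list(theta = theta, omega = omega, sigma = sigma)
}

#' Laplace objective function value for a population model
#'
#' Computes `-2 log` marginal likelihood with each subject's random-effect
#' integral approximated by the Laplace method at the mode of the joint
#' density. Deterministic given its inputs.
#'
#' @param spec A [popmodel_spec()].
#' @param data A dataset as returned by [read_dataset()] or
#'   [simulate_trial()].
#' @param theta,omega,sigma Parameter values; default to `spec`'s initial
#'   values. `omega` of length 0 (or all zeros) gives the fixed-effect
#'   weighted deviance (degenerate prior).
#' @param backend `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation, identical algorithm).
#' @return The OFV (numeric scalar) with attribute `eta` (matrix of
#'   per-subject conditional modes).
#' @export
laplace_ofv <- function(spec, data, theta = NULL, omega = NULL,
                        sigma = NULL, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  theta <- theta %||% spec$theta
  omega <- omega %||% spec$omega
  sigma <- sigma %||% spec$sigma
  if (length(omega) > 0 && any(omega < 0)) stopf("omega must be >= 0")
  if (length(omega) > 0 && all(omega == 0)) omega <- numeric(0)
  ctx <- .build_ctx(spec, data)
  if (backend == "cpp") {
    res <- .ofv_cpp(ctx, theta, omega, sigma)
    out <- res$ofv
    attr(out, "eta") <- res$eta
    attr(out, "n_inner_fail") <- res$n_inner_fail
    return(out)
  }
  # pure-R reference: same Laplace algebra via the general engine
  bases <- .subject_bases(ctx, theta)
  prep <- ctx$prep
  subjects <- lapply(seq_len(ctx$n_sub), function(i) {
    rows <- which(prep$obs$subject == i)
    con <- prep$contrib[prep$contrib$obs %in% rows, , drop = FALSE]
    force(i)
    list(y = prep$obs$dv[rows],
         f = function(eta) {
           e <- setNames(numeric(3), c("CL_int", "V", "ka"))
           e[names(omega)] <- eta
           clint <- bases$clint_base[i] * exp(e[["CL_int"]])
           ws <- well_stirred(clint, ctx$qh[i], ctx$spec$drug$fu_B)
           cl <- ws$CL_H + ctx$clr[i]
           Fb <- ctx$spec$drug$FaFg * ws$F_H
           V <- bases$vbase[i] * exp(e[["V"]])
           ka <- bases$kabase[i] * exp(e[["ka"]])
           p <- vapply(seq_len(nrow(con)), function(k) {
             .conc_1cmt_oral(con$amt[k], Fb, V, cl, ka, con$tad[k],
                             ss = con$ss[k] > 0, ii = con$ii[k])
           }, 0)
           as.numeric(rowsum(p, match(con$obs, rows)))
         })
  })
  out <- laplace_ofv_general(subjects,
                             omega = diag(omega, nrow = length(omega)),
                             sigma = sigma)
  out
}

#' General-purpose Laplace marginal OFV for user-supplied subject models
#'
#' The same approximation as [laplace_ofv()] but for arbitrary per-subject
#' prediction functions; used as the reference implementation and in
#' cross-checks against closed-form and quadrature results.
#'
#' @param subjects List of subjects, each a list with numeric `y` and
#'   `f(eta)` returning predictions of `y`.
#' @param omega Random-effect covariance matrix (q x q, possibly 0 x 0).
#' @param sigma List or vector with `prop` and `add` residual components.
#' @return OFV (numeric scalar) with attribute `eta`.
#' @export
laplace_ofv_general <- function(subjects, omega, sigma) {
  q <- nrow(omega)
  sig_p <- sigma[["prop"]]
  sig_a <- sigma[["add"]]
  dev <- function(y, f) {
    g2 <- (sig_p * f)^2 + sig_a^2
    sum((y - f)^2 / g2 + log(2 * pi * g2))
  }
  etas <- matrix(0, length(subjects), max(q, 1))
  total <- 0
  if (q > 0) {
    oinv <- solve(omega)
    ldo <- determinant(omega, logarithm = TRUE)$modulus[1]
  }
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (q == 0) {
      total <- total + dev(s$y, s$f(numeric(0)))
      next
    }
    J <- function(eta) {
      dev(s$y, s$f(eta)) + as.numeric(t(eta) %*% oinv %*% eta)
    }
    opt <- nlminb(numeric(q), J, control = list(abs.tol = 1e-14,
                                                rel.tol = 1e-12))
    H <- optimHess(opt$par, J)
    Hh <- H / 2
    ldh <- determinant(Hh, logarithm = TRUE)$modulus[1]
    total <- total + opt$objective + ldo + ldh
    etas[i, ] <- opt$par
  }
  structure(total, eta = etas)
}

# --- fitting ------------------------------------------------------------------

#' Fit a population PBPK model by Laplace nonlinear mixed effects
#'
#' Minimises [laplace_ofv()] over the free parameters, on transformed
#' scales (log for positive parameters, bounded logits for Hill
#' coefficients and `FRD`). Multiple jittered starts guard against local
#' minima; the best converged start wins. Standard errors come from the
#' numerically differentiated Hessian of the objective at the optimum
#' (delta method back to the natural scale).
#'
#' @param spec A [popmodel_spec()].
#' @param data Dataset.
#' @param inits Optional named overrides of initial values (theta names,
#'   `omega_<name>`, `sigma_prop`, `sigma_add`).
#' @param fix Additional parameter names to fix (on top of `spec$fixed`).
#' @param n_starts Number of optimisation starts (first is unjittered).
#' @param seed Seed for the start jitter.
#' @param compute_se Set `FALSE` to skip the Hessian (e.g. in bootstrap).
#' @param control Passed to [nlminb()].
#' @return An object of class `ontopbpk_fit`: estimates and standard
#'   errors, `ofv`, per-subject empirical Bayes `eta`, convergence
#'   diagnostics and condition number.
#' @export
fit_population_model <- function(spec, data, inits = NULL, fix = NULL,
                                 n_starts = 5, seed = 1,
                                 compute_se = TRUE,
                                 control = list(iter.max = 400,
                                                eval.max = 600)) {
  ctx <- .build_ctx(spec, data)
  x0 <- .pack(spec, spec$theta, spec$omega, spec$sigma)
  if (!is.null(inits)) {
    for (nm in names(inits)) {
      if (!nm %in% names(x0)) stopf("unknown init '%s'", nm)
      base <- sub("^(omega_|sigma_)", "", nm)
      x0[nm] <- if (startsWith(nm, "omega_")) log(sqrt(inits[[nm]]))
        else if (startsWith(nm, "sigma_")) log(inits[[nm]])
        else .tf_fwd(base, inits[[nm]])
    }
  }
  fixed <- union(spec$fixed, fix %||% character(0))
  unknown <- setdiff(fixed, names(x0))
  if (length(unknown)) stopf("unknown fixed parameter(s): %s",
                             paste(unknown, collapse = ", "))
  free <- setdiff(names(x0), fixed)

  eta_env <- new.env()
  eta_env$eta <- NULL
  n_eval <- 0L
  obj <- function(xf) {
    x <- x0
    x[free] <- xf
    p <- .unpack(spec, x)
    res <- try(.ofv_cpp(ctx, p$theta, p$omega, p$sigma,
                        eta_start = eta_env$eta), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    eta_env$eta <- res$eta
    n_eval <<- n_eval + 1L
    res$ofv
  }

  ofv_init <- obj(x0[free])
  if (length(free) == 0L) {
    p <- .unpack(spec, x0)
    res <- .ofv_cpp(ctx, p$theta, p$omega, p$sigma)
    return(.make_fit(spec, ctx, x0, free, res$ofv, res, convergence = 0L,
                     message = "all parameters fixed", n_iter = 0L,
                     compute_se = FALSE))
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- x0[free]
    if (s > 1) start <- start + rnorm(length(start), 0, 0.2)
    eta_env$eta <- NULL
    opt <- try(nlminb(start, obj, control = control), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stopf("all optimisation starts failed")
  x_hat <- x0
  x_hat[free] <- best$par
  p <- .unpack(spec, x_hat)
  eta_env$eta <- NULL
  res <- .ofv_cpp(ctx, p$theta, p$omega, p$sigma)
  ofv <- min(res$ofv, ofv_init)
  conv <- if (best$convergence == 0 || grepl("relative convergence|X-conv|both X",
                                             best$message %||% "")) 0L else 1L
  .make_fit(spec, ctx, x_hat, free, ofv, res, convergence = conv,
            message = best$message %||% "", n_iter = best$iterations %||% NA,
            compute_se = compute_se, obj = obj)
}

.make_fit <- function(spec, ctx, x_hat, free, ofv, res, convergence,
                      message, n_iter, compute_se, obj = NULL) {
  p <- .unpack(spec, x_hat)
  se <- setNames(rep(NA_real_, length(x_hat)), names(x_hat))
  cond <- NA_real_
  if (compute_se && length(free) > 0 && !is.null(obj)) {
    H <- try(optimHess(x_hat[free], obj), silent = TRUE)
    if (!inherits(H, "try-error")) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) {
        cond <- max(ev) / min(ev)
        cov_t <- 2 * solve(H)   # OFV = -2 logL
        se_t <- sqrt(pmax(diag(cov_t), 0))
        names(se_t) <- free
        nt <- length(spec$theta)
        for (nm in free) {
          i <- match(nm, names(x_hat))
          jac <- if (i <= nt) .tf_jac(nm, x_hat[[nm]])
            else if (startsWith(nm, "omega_")) 2 * exp(2 * x_hat[[nm]])
            else exp(x_hat[[nm]])
          se[nm] <- se_t[nm] * abs(jac)
        }
      }
    }
  }
  eta <- res$eta
  if (length(spec$omega) > 0) colnames(eta) <- names(spec$omega)
  structure(list(
    spec = spec, theta = p$theta, omega = p$omega, sigma = p$sigma,
    se = se, ofv = ofv, ofv_i = res$ofv_i, eta = eta,
    convergence = convergence, message = message, n_iter = n_iter,
    condition_number = cond, n_inner_fail = res$n_inner_fail,
    subjects = ctx$prep$subjects, n_obs = nrow(ctx$prep$obs),
    packed = x_hat, free = free
  ), class = "ontopbpk_fit")
}

#' @export
print.ontopbpk_fit <- function(x, ...) {
  cat(sprintf("<population PBPK fit: OFV = %.3f, %d subjects, %d obs%s>\n",
              x$ofv, nrow(x$subjects), x$n_obs,
              if (x$convergence != 0) ", NOT CONVERGED" else ""))
  est <- data.frame(estimate = signif(x$theta, 4),
                    se = signif(x$se[names(x$theta)], 3))
  print(est)
  if (length(x$omega)) {
    cat("omega (variances):",
        paste(sprintf("%s=%.4g", names(x$omega), x$omega), collapse = ", "),
        "\n")
  }
  cat(sprintf("sigma: prop=%.4g add=%.4g\n", x$sigma[["prop"]],
              x$sigma[["add"]]))
  invisible(x)
}

#' AIC for a population PBPK fit (OFV + 2 x number of free parameters)
#' @param fit An `ontopbpk_fit`.
#' @return Numeric AIC.
#' @export
fit_aic <- function(fit) fit$ofv + 2 * length(fit$free)

#' Estimated ontogeny curve from a fit
#'
#' @param fit An `ontopbpk_fit` whose spec estimates an ontogeny family.
#' @param ages Age grid, years.
#' @return Numeric vector of fractional activities.
#' @export
fitted_ontogeny <- function(fit, ages) {
  if (is.null(fit$spec$family)) stopf("fit has no estimated ontogeny family")
  evaluate_ontogeny(fit$spec$family,
                    fit$theta[fit$spec$family$roster], ages)
}

#' Empirical Bayes estimates and post hoc individual parameters
#'
#' Returns each subject's conditional mode of the random effects at the
#' population estimates and the implied post hoc individual parameters
#' (the random effects pushed through the structural model). A subject
#' without observations has `eta = 0` (the prior mode).
#'
#' @param fit An `ontopbpk_fit`.
#' @param data The dataset the model was fitted to.
#' @param id Optional subject identifier(s) to extract; errors if unknown.
#' @return data.frame with `ID`, `AGE`, `WT`, the `eta_*` columns and post
#'   hoc `CL_int`, `CL`, `V`.
#' @export
empirical_bayes <- function(fit, data, id = NULL) {
  ctx <- .build_ctx(fit$spec, data)
  res <- .ofv_cpp(ctx, fit$theta, fit$omega, fit$sigma)
  eta <- res$eta
  if (length(fit$omega)) colnames(eta) <- names(fit$omega)
  bases <- .subject_bases(ctx, fit$theta)
  e <- function(nm) if (nm %in% colnames(eta)) eta[, nm] else 0
  clint <- bases$clint_base * exp(e("CL_int"))
  ws <- well_stirred(clint, ctx$qh, fit$spec$drug$fu_B)
  out <- data.frame(ID = ctx$prep$subjects$ID, AGE = ctx$prep$subjects$AGE,
                    WT = ctx$prep$subjects$WT)
  for (nm in colnames(eta)) out[[paste0("eta_", nm)]] <- eta[, nm]
  out$CL_int <- clint
  out$CL <- ws$CL_H + ctx$clr
  out$V <- bases$vbase * exp(e("V"))
  if (!is.null(id)) {
    if (!all(id %in% out$ID)) stopf("unknown subject ID(s)")
    out <- out[match(id, out$ID), , drop = FALSE]
  }
  out
}
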