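# Maximum marginal likelihood estimation of a pk_model_spec on a
# pk_dataset, by FO or FOCE-I approximation, with an EBE pass and a
# finite-difference covariance step.

.BIG_OBJ <- 1e10

#' Estimation settings
#'
#' @param method `"FOCE_I"` (first-order conditional with interaction;
#'   default) or `"FO"` (linearization at `eta = 0`).  The two coincide
#'   exactly when the model has no IIV terms.
#' @param outer_tol relative tolerance of the outer objective.
#' @param max_evals hard cap on objective evaluations (including the
#'   optimizer's internal finite-difference gradient calls).  A fit that
#'   exhausts the cap keeps the best point found and reports
#'   `converged = FALSE`.
#' @param max_iter cap on outer optimizer iterations.
#' @param inner_tol gradient tolerance of the per-subject conditional-mode
#'   (eta) search.
#' @param inner_max iteration cap of the inner search.
#' @param fd_step relative finite-difference step of the covariance-step
#'   Hessian.
#' @param grad_tol absolute gradient-norm threshold (on the -2LL scale)
#'   below which the outer optimum is accepted as converged.
#' @param timeout wall-clock limit in seconds; an exceeded fit returns
#'   `converged = FALSE` instead of raising.
#' @param fo_prefit for FOCE-I fits of models with IIV, first run a short
#'   FO optimization and start the FOCE-I search from its solution (a
#'   pure optimization warm start; the reported objective is always the
#'   fully converged FOCE-I one).
#' @param include_2pi add the `n log(2 pi)` constant to the objective
#'   (off by default; the reported OBV is then -2 log L minus that fixed
#'   constant, the convention of the estimation software this toolkit
#'   emulates).
#' @return A list of class `pk_estimation_settings`.
#' @export
estimation_settings <- function(method = c("FOCE_I", "FO"),
                                outer_tol = 1e-8, max_evals = 6000,
                                max_iter = 200,
                                inner_tol = 1e-6, inner_max = 50,
                                fd_step = 1e-4, grad_tol = 0.5,
                                timeout = 600, include_2pi = FALSE,
                                fo_prefit = TRUE) {
  method <- match.arg(method)
  stopifnot(outer_tol > 0, inner_tol > 0, fd_step > 0, timeout > 0)
  structure(list(method = method, outer_tol = outer_tol,
                 max_evals = max_evals, max_iter = max_iter,
                 inner_tol = inner_tol,
                 inner_max = inner_max, fd_step = fd_step,
                 grad_tol = grad_tol, timeout = timeout,
                 include_2pi = include_2pi, fo_prefit = fo_prefit),
            class = "pk_estimation_settings")
}

# ---- internal problem assembly ------------------------------------------

.resid_code <- function(kind)
  match(kind, c("additive", "proportional", "combined"))

# Per-subject observation/dose data as concatenated arrays (subject
# order, non-missing observations only) with 0-based offset vectors.
build_problem <- function(spec, ds) {
  subjects <- ds$subjects
  o <- ds$observations[!ds$observations$missing_flag, , drop = FALSE]
  oi <- order(match(o$subject_id, subjects))
  o <- o[oi, , drop = FALSE]
  d <- ds$doses[order(match(ds$doses$subject_id, subjects)), ,
                drop = FALSE]
  obs_counts <- tabulate(match(o$subject_id, subjects),
                         nbins = length(subjects))
  dose_counts <- tabulate(match(d$subject_id, subjects),
                          nbins = length(subjects))
  dose_flat <- as.numeric(t(cbind(d$time, d$amount, d$duration)))
  covs <- ds$covariates[match(subjects, ds$covariates$subject_id), ,
                        drop = FALSE]
  struct_names <- structural_parameters(spec$structural)
  iiv_names <- names(spec$iiv)[spec$iiv != "none"]
  list(subjects = subjects,
       times = o$time, dv = o$dv,
       obs_off = c(0L, cumsum(obs_counts)),
       dose_flat = dose_flat,
       dose_off = c(0L, cumsum(dose_counts)),
       covs = covs,
       obs_subject = o$subject_id, obs_time = o$time, obs_dv = o$dv,
       struct_names = struct_names, iiv_names = iiv_names,
       iiv_idx0 = match(iiv_names, struct_names) - 1L,
       iiv_code = ifelse(spec$iiv[iiv_names] == "exponential", 1L, 2L),
       kind_code = .kind_code(spec$structural),
       resid_code = .resid_code(spec$residual),
       n_obs = nrow(o))
}

# Split a flat natural-scale parameter vector into components.
split_params <- function(spec, pv) {
  nm <- spec_param_names(spec)
  if (is.list(pv) && !is.null(pv$theta)) {
    flat <- c(pv$theta, unlist(pv$cov), pv$omega, pv$sigma)
    if (length(flat) != length(nm))
      stop("parameter vector has wrong length")
    pv <- setNames(as.numeric(flat), nm)
  }
  if (length(pv) != length(nm)) stop("parameter vector has wrong length")
  if (!is.null(names(pv)) && all(nm %in% names(pv))) pv <- pv[nm]
  ns <- length(structural_parameters(spec$structural))
  ncv <- sum(vapply(spec$effects, n_effect_thetas, integer(1)))
  nom <- sum(spec$iiv != "none")
  theta <- setNames(pv[seq_len(ns)], nm[seq_len(ns)])
  covv <- pv[ns + seq_len(ncv)]
  cov_list <- list(); pos <- 0
  for (e in spec$effects) {
    k <- n_effect_thetas(e)
    cov_list[[length(cov_list) + 1L]] <- unname(covv[pos + seq_len(k)])
    pos <- pos + k
  }
  omega <- pv[ns + ncv + seq_len(nom)]
  sigma <- unname(pv[(ns + ncv + nom + 1L):length(pv)])
  list(theta = theta, cov = cov_list, omega = unname(omega), sigma = sigma)
}

# Typical value matrix (subjects x structural parameters).
tv_matrix <- function(spec, theta, cov_thetas, covs, struct_names) {
  m <- matrix(rep(theta, each = nrow(covs)), nrow = nrow(covs),
              dimnames = list(NULL, struct_names))
  if (length(spec$effects)) {
    for (p in unique(vapply(spec$effects, `[[`, character(1), "target"))) {
      sel <- vapply(spec$effects, function(e) e$target == p, logical(1))
      m[, p] <- typical_value(theta[[p]], spec$effects[sel], covs,
                              cov_thetas[sel])
    }
  }
  m
}

# Estimation-scale packing: log for positive quantities, natural for
# covariate coefficients.
pack_est <- function(spec) {
  nm <- spec_param_names(spec)
  ns <- length(structural_parameters(spec$structural))
  ncv <- sum(vapply(spec$effects, n_effect_thetas, integer(1)))
  nom <- sum(spec$iiv != "none")
  nsg <- if (spec$residual == "combined") 2L else 1L
  is_log <- c(rep(TRUE, ns), rep(FALSE, ncv), rep(TRUE, nom),
              rep(TRUE, nsg))
  start_nat <- c(spec$init$theta, unlist(lapply(spec$effects, `[[`, "init")),
                 spec$init$omega, spec$init$sigma)
  lower_nat <- c(spec$theta_bounds$lower[structural_parameters(spec$structural)],
                 unlist(lapply(spec$effects, `[[`, "lower")),
                 rep(1e-3, nom), rep(1e-10, nsg))
  upper_nat <- c(spec$theta_bounds$upper[structural_parameters(spec$structural)],
                 unlist(lapply(spec$effects, `[[`, "upper")),
                 rep(100, nom), rep(1e4, nsg))
  to_est <- function(x) { x[is_log] <- log(x[is_log]); x }
  to_nat <- function(x) { x[is_log] <- exp(x[is_log]); x }
  list(names = nm, is_log = is_log,
       start = to_est(start_nat),
       lower = to_est(lower_nat), upper = to_est(upper_nat),
       to_nat = to_nat, to_est = to_est)
}

# ---- objective -----------------------------------------------------------

make_objective <- function(spec, prob, settings, deadline = NULL) {
  pk <- pack_est(spec)
  n_eta <- length(prob$iiv_names)
  env <- new.env(parent = emptyenv())
  env$evals <- 0L
  env$eta_warm <- matrix(0, length(prob$subjects), n_eta)
  method_code <- if (settings$method == "FOCE_I") 1L else 0L

  # fixed parameter layout, resolved once
  ns <- length(prob$struct_names)
  eff_sizes <- vapply(spec$effects, n_effect_thetas, integer(1))
  ncv <- sum(eff_sizes)
  cov_pos <- if (length(eff_sizes))
    split(ns + seq_len(ncv), rep(seq_along(eff_sizes), eff_sizes))
  else list()
  omega_pos <- ns + ncv + seq_len(n_eta)
  sigma_pos <- (ns + ncv + n_eta + 1L):length(pk$names)
  # effects grouped by target parameter, preserving list order
  eff_targets <- vapply(spec$effects, `[[`, character(1), "target")
  nsub <- nrow(prob$covs)

  obj_nat <- function(pv_nat) {
    theta <- pv_nat[seq_len(ns)]
    m <- matrix(rep(theta, each = nsub), nrow = nsub)
    if (length(spec$effects)) {
      cov_thetas <- lapply(cov_pos, function(ix) unname(pv_nat[ix]))
      for (p in unique(eff_targets)) {
        sel <- eff_targets == p
        pi <- match(p, prob$struct_names)
        m[, pi] <- typical_value(theta[[pi]], spec$effects[sel],
                                 prob$covs, cov_thetas[sel])
      }
    }
    if (any(!is.finite(m))) return(.BIG_OBJ)
    if (prob$kind_code != 5L && any(m <= 0)) return(.BIG_OBJ)
    res <- cpp_neg2ll(prob$kind_code, method_code, m,
                      prob$iiv_idx0, prob$iiv_code,
                      if (n_eta) pv_nat[omega_pos] else numeric(0),
                      prob$resid_code, pv_nat[sigma_pos],
                      prob$times, prob$dv, prob$obs_off,
                      prob$dose_flat, prob$dose_off,
                      settings$inner_tol, settings$inner_max,
                      env$eta_warm)
    if (!isTRUE(res$ok) || !is.finite(res$obv)) return(.BIG_OBJ)
    if (n_eta) env$eta_warm <- res$etas
    res$obv
  }
  env$best_val <- Inf
  env$best_par <- NULL
  env$cap <- settings$max_evals
  obj_est <- function(par) {
    if (env$evals >= env$cap) return(.BIG_OBJ)  # deterministic budget
    env$evals <- env$evals + 1L
    if (!is.null(deadline) && proc.time()[["elapsed"]] > deadline)
      stop(errorCondition("fit wall-clock timeout", class = "pk_timeout"))
    v <- obj_nat(pk$to_nat(par))
    if (!is.finite(v)) return(.BIG_OBJ)
    if (v < env$best_val) {
      env$best_val <- v
      env$best_par <- par
    }
    v
  }
  list(obj_est = obj_est, obj_nat = obj_nat, pack = pk, env = env)
}

#' -2 log marginal likelihood of a model at given parameters
#'
#' FO linearizes the subject model around `eta = 0`; FOCE-I finds each
#' subject's conditional mode and linearizes there with the residual
#' variance evaluated at the mode (interaction).  Each subject contributes
#' `log det Sigma_i + r_i' Sigma_i^-1 r_i` with
#' `Sigma_i = G Omega G' + R(eta)` and the linearized residual
#' `r_i = y_i - F(eta) + G eta`; the `n log(2 pi)` constant is omitted
#' unless `settings$include_2pi`.
#'
#' @param spec a [model_spec()].
#' @param params flat named natural-scale parameter vector in
#'   [coef.pkfit()] order, or a list with elements `theta`, `cov`,
#'   `omega`, `sigma`.
#' @param ds a [pk_dataset()].
#' @param settings an [estimation_settings()].
#' @return The objective value (OBV); `NA` for an invalid evaluation.
#' @export
neg2ll <- function(spec, params, ds, settings = estimation_settings()) {
  prob <- build_problem(spec, ds)
  ob <- make_objective(spec, prob, settings)
  sp <- split_params(spec, params)  # canonicalizes order by name
  flat <- as.numeric(c(sp$theta, unlist(sp$cov), sp$omega, sp$sigma))
  v <- ob$obj_nat(flat)
  if (v >= .BIG_OBJ) return(NA_real_)
  if (settings$include_2pi) v <- v + prob$n_obs * log(2 * pi)
  v
}

# ---- fitting -------------------------------------------------------------

failed_fit <- function(spec, settings, prob, reason, evals = 0L,
                       elapsed = NA_real_) {
  structure(list(spec = spec, settings = settings,
                 params = setNames(rep(NA_real_,
                                       length(spec_param_names(spec))),
                                   spec_param_names(spec)),
                 obv = NA_real_, converged = FALSE,
                 covariance_success = FALSE, se = NULL, rse_pct = NULL,
                 correlation = NULL, condition_number = NA_real_,
                 etas = NULL, ipred = NULL, evals = evals,
                 elapsed = elapsed, message = reason,
                 n_obs = prob$n_obs, n_subjects = length(prob$subjects),
                 obs = data.frame(subject_id = prob$obs_subject,
                                  time = prob$obs_time, dv = prob$obs_dv)),
            class = "pkfit")
}

#' Fit a population PK model by maximum marginal likelihood
#'
#' Minimizes [neg2ll()] over log-transformed positive parameters
#' (structural values, IIV standard deviations, residual variances) and
#' natural-scale covariate coefficients, starting from `spec$init`.
#' Numerical failure never raises: the fit is returned with
#' `converged = FALSE` so that search engines can absorb it as a penalty.
#'
#' @param spec a [model_spec()] whose initial values are within bounds.
#' @param ds a [pk_dataset()].
#' @param settings an [estimation_settings()].
#' @param do_covariance run the finite-difference covariance step
#'   (standard errors, correlation matrix, condition number).
#' @return An object of class `pkfit`: estimates (`params`, natural
#'   scale), `obv`, `converged`, `covariance_success`, `se`, `rse_pct`,
#'   `correlation`, `condition_number` (largest/smallest eigenvalue of the
#'   correlation matrix), per-subject `etas`, individual predictions
#'   `ipred` aligned with the non-missing observations, and `evals`.
#' @export
fit_model <- function(spec, ds, settings = estimation_settings(),
                      do_covariance = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  prob <- build_problem(spec, ds)
  deadline <- t0 + settings$timeout
  ob <- make_objective(spec, prob, settings, deadline)
  pk <- ob$pack

  start <- pk$start
  opt <- tryCatch({
    if (isTRUE(settings$fo_prefit) && settings$method == "FOCE_I" &&
        length(prob$iiv_names) > 0) {
      st_fo <- settings
      st_fo$method <- "FO"
      ob_fo <- make_objective(spec, prob, st_fo, deadline)
      pre <- nlminb(start, ob_fo$obj_est, lower = pk$lower,
                    upper = pk$upper,
                    control = list(eval.max = 300, iter.max = 60,
                                   rel.tol = 1e-5))
      if (is.finite(pre$objective) && pre$objective < .BIG_OBJ)
        start <- pre$par
    }
    nlminb(start, ob$obj_est, lower = pk$lower, upper = pk$upper,
           control = list(eval.max = settings$max_evals,
                          iter.max = settings$max_iter,
                          rel.tol = settings$outer_tol))
  },
    pk_timeout = function(e) NULL,
    error = function(e) NULL)
  if (is.null(opt))
    return(failed_fit(spec, settings, prob, "timeout or optimizer error",
                      ob$env$evals, proc.time()[["elapsed"]] - t0))
  cap_hit <- ob$env$evals >= settings$max_evals
  par <- if (cap_hit && !is.null(ob$env$best_par)) ob$env$best_par
         else opt$par
  obv <- if (cap_hit) ob$env$best_val else opt$objective
  if (!is.finite(obv) || obv >= .BIG_OBJ)
    return(failed_fit(spec, settings, prob, "no finite likelihood",
                      ob$env$evals, proc.time()[["elapsed"]] - t0))

  if (cap_hit) {
    converged <- FALSE
  } else {
    # convergence: small gradient + no active bound.  The gradient at
    # the optimum is the authoritative check; nlminb's "false
    # convergence" code is routinely triggered by sub-tolerance
    # objective noise from the warm-started inner eta search.
    ob$env$cap <- ob$env$cap + 2L * length(par)
    g <- tryCatch(fd_gradient(ob$obj_est, par),
                  pk_timeout = function(e) NULL)
    if (is.null(g))
      return(failed_fit(spec, settings, prob, "timeout in gradient check",
                        ob$env$evals, proc.time()[["elapsed"]] - t0))
    pinned <- any(par - pk$lower < 1e-6) || any(pk$upper - par < 1e-6)
    converged <- all(is.finite(g)) && max(abs(g)) < settings$grad_tol &&
      !pinned
  }

  params <- setNames(pk$to_nat(par), pk$names)
  sp <- split_params(spec, params)

  # covariance step
  se <- rse <- corr <- NULL
  condn <- NA_real_
  cov_ok <- FALSE
  if (do_covariance && converged) {
    ob$env$cap <- Inf  # the Hessian's own cost is bounded (2 p^2 calls)
    cs <- tryCatch(
      covariance_step_internal(ob$obj_est, par, pk, settings),
      pk_timeout = function(e) NULL, error = function(e) NULL)
    if (!is.null(cs)) {
      se <- cs$se; rse <- cs$rse_pct; corr <- cs$correlation
      condn <- cs$condition_number; cov_ok <- cs$covariance_success
      if (!is.null(se)) {
        names(se) <- pk$names
        rse <- 100 * se / abs(params)
      }
    }
  }

  # EBE pass at the estimates
  m <- tv_matrix(spec, sp$theta, sp$cov, prob$covs, prob$struct_names)
  ebe <- cpp_ebe(prob$kind_code, m, prob$iiv_idx0, prob$iiv_code,
                 if (length(prob$iiv_names)) sp$omega else numeric(0),
                 prob$resid_code, sp$sigma, prob$times, prob$dv,
                 prob$obs_off, prob$dose_flat, prob$dose_off,
                 settings$inner_tol, settings$inner_max)
  etas <- ebe$etas
  if (ncol(etas) > 0) {
    dimnames(etas) <- list(prob$subjects, prob$iiv_names)
  } else etas <- matrix(0, length(prob$subjects), 0,
                        dimnames = list(prob$subjects, NULL))

  if (settings$include_2pi) obv <- obv + prob$n_obs * log(2 * pi)

  structure(list(spec = spec, settings = settings, params = params,
                 obv = obv, converged = converged,
                 covariance_success = cov_ok, se = se, rse_pct = rse,
                 correlation = corr, condition_number = condn,
                 etas = etas, ipred = as.numeric(ebe$ipred),
                 ebe_flagged = as.logical(ebe$flagged),
                 evals = ob$env$evals,
                 elapsed = proc.time()[["elapsed"]] - t0,
                 message = opt$message,
                 n_obs = prob$n_obs, n_subjects = length(prob$subjects),
                 obs = data.frame(subject_id = prob$obs_subject,
                                  time = prob$obs_time, dv = prob$obs_dv)),
            class = "pkfit")
}

fd_gradient <- function(f, x, h_rel = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- h_rel * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Central finite-difference Hessian of f/2 at x, inverted to a covariance
# matrix and mapped from the estimation to the reporting scale.
covariance_step_internal <- function(f, x, pk, settings) {
  p <- length(x)
  h <- settings$fd_step * pmax(1, abs(x))
  f0 <- f(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H <- H / 2  # Hessian of -log L
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) <= 0)
    return(list(covariance_success = FALSE, se = NULL, rse_pct = NULL,
                correlation = NULL, condition_number = NA_real_))
  cov_est <- solve(H)
  # delta-method map to the natural (reporting) scale
  jac <- ifelse(pk$is_log, exp(x), 1)
  cov_nat <- diag(jac, p) %*% cov_est %*% diag(jac, p)
  se <- sqrt(pmax(diag(cov_nat), 0))
  dd <- se; dd[dd == 0] <- 1
  corr <- cov_nat / outer(dd, dd)
  diag(corr) <- 1
  dimnames(corr) <- list(pk$names, pk$names)
  cev <- eigen((corr + t(corr)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  condn <- if (min(cev) > 0) max(cev) / min(cev) else Inf
  list(covariance_success = TRUE, se = se, rse_pct = NULL,
       correlation = corr, condition_number = condn)
}

#' Covariance step at given parameter values
#'
#' Finite-difference Hessian of the half objective on the estimation
#' scale, inverted and delta-method mapped to the reporting scale.
#'
#' @inheritParams neg2ll
#' @return List with `se`, `rse_pct`, `correlation`, `condition_number`
#'   (eigenvalue ratio of the correlation matrix) and
#'   `covariance_success`.
#' @export
covariance_step <- function(spec, params, ds,
                            settings = estimation_settings()) {
  prob <- build_problem(spec, ds)
  ob <- make_objective(spec, prob, settings)
  pk <- ob$pack
  if (is.list(params) && !is.null(params$theta))
    params <- setNames(c(params$theta, unlist(params$cov), params$omega,
                         params$sigma), pk$names)
  x <- pk$to_est(as.numeric(params[pk$names]))
  cs <- covariance_step_internal(ob$obj_est, x, pk, settings)
  if (cs$covariance_success) {
    names(cs$se) <- pk$names
    cs$rse_pct <- 100 * cs$se / abs(as.numeric(params[pk$names]))
  }
  cs
}

#' Empirical Bayes estimates and individual predictions
#'
#' Per-subject MAP `eta` given population parameters, with the individual
#' prediction evaluated at the mode.  A subject whose inner search fails
#' falls back to `eta = 0` and is flagged.
#'
#' @inheritParams neg2ll
#' @return List with `etas` (subjects x IIV-parameters matrix; zero
#'   columns when the model has no IIV), `ipred` (aligned with the
#'   non-missing observations in subject order) and `flagged`.
#' @export
empirical_bayes_etas <- function(spec, params, ds,
                                 settings = estimation_settings()) {
  prob <- build_problem(spec, ds)
  sp <- split_params(spec, params)
  m <- tv_matrix(spec, sp$theta, sp$cov, prob$covs, prob$struct_names)
  ebe <- cpp_ebe(prob$kind_code, m, prob$iiv_idx0, prob$iiv_code,
                 if (length(prob$iiv_names)) sp$omega else numeric(0),
                 prob$resid_code, sp$sigma, prob$times, prob$dv,
                 prob$obs_off, prob$dose_flat, prob$dose_off,
                 settings$inner_tol, settings$inner_max)
  etas <- ebe$etas
  dimnames(etas) <- list(prob$subjects,
                         if (ncol(etas)) prob$iiv_names else NULL)
  list(etas = etas, ipred = as.numeric(ebe$ipred),
       flagged = as.logical(ebe$flagged))
}
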