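# Model comparison statistics.

#' Akaike information criterion from an objective value
#'
#' @param obv objective value (-2 log likelihood up to a constant).
#' @param k number of model parameters.
#' @return `obv + 2 k`.
#' @export
aic <- function(obv, k) {
  if (any(k < 0)) stop("k must be >= 0")
  obv + 2 * k
}

#' Bayesian information criterion from an objective value
#'
#' @inheritParams aic
#' @param n number of data points (>= 1).
#' @return `obv + k * log(n)` (natural log).
#' @export
bic <- function(obv, k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  obv + k * log(n)
}

#' Mean prediction error
#'
#' @param ipred individual predictions.
#' @param dv observed concentrations (same length).
#' @return `mean(ipred - dv)`.
#' @export
mpe <- function(ipred, dv) {
  if (length(ipred) != length(dv)) stop("length mismatch")
  if (length(dv) < 1) stop("need at least one observation")
  mean(ipred - dv)
}

#' Root mean squared prediction error
#'
#' @inheritParams mpe
#' @return `sqrt(mean((ipred - dv)^2))`.
#' @export
rmse <- function(ipred, dv) {
  if (length(ipred) != length(dv)) stop("length mismatch")
  if (length(dv) < 1) stop("need at least one observation")
  sqrt(mean((ipred - dv)^2))
}

#' Cohen's kappa for two inclusion vectors
#'
#' Chance-corrected agreement between two binary classifications over the
#' same slots (e.g. covariate inclusion decisions of two model-building
#' methods): `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal inclusion rates.
#'
#' @param incl_a,incl_b logical vectors of equal length.
#' @return Kappa in `[-1, 1]`; 1 when both marginals are degenerate and
#'   identical.
#' @export
cohen_kappa <- function(incl_a, incl_b) {
  if (length(incl_a) != length(incl_b)) stop("length mismatch")
  if (length(incl_a) < 1) stop("need at least one slot")
  a <- as.logical(incl_a); b <- as.logical(incl_b)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Median percent difference of shared parameters
#'
#' @param ref named reference parameter values (e.g. the stepwise
#'   model's).
#' @param other named comparison values.
#' @param shared parameter names to compare; defaults to the common
#'   names.
#' @return Median over shared parameters of `100 |other - ref| / |ref|`;
#'   zero-reference parameters are skipped with a warning.
#' @export
median_pct_param_difference <- function(ref, other, shared = NULL) {
  if (is.null(shared)) shared <- intersect(names(ref), names(other))
  if (length(shared) == 0) stop("no shared parameters")
  zero <- shared[ref[shared] == 0]
  if (length(zero)) {
    warning("skipping zero-reference parameter(s): ",
            paste(zero, collapse = ", "))
    shared <- setdiff(shared, zero)
  }
  median(100 * abs(other[shared] - ref[shared]) / abs(ref[shared]))
}

#' Covariate inclusion vector of a model over a slot universe
#'
#' @param spec a [model_spec()].
#' @param universe character vector of `target~covariate` labels.
#' @return Logical vector over `universe`.
#' @export
covariate_inclusion <- function(spec, universe) {
  present <- vapply(spec$effects, function(e)
    paste0(e$target, "~", e$covariate), character(1))
  setNames(universe %in% present, universe)
}

#' Compare two fitted models
#'
#' Side-by-side OBV/AIC/BIC/MPE/RMSE, the AIC difference, Cohen's kappa
#' for covariate inclusion over a slot universe, kappa for IIV-term
#' inclusion, and the median percent difference of shared parameters
#' (model A as the reference).
#'
#' @param fit_a,fit_b `pkfit` objects on the same data.
#' @param universe covariate slot universe (`target~covariate` labels);
#'   defaults to the union of both models' pairs.
#' @return A list of class `pk_model_comparison`.
#' @export
compare_models <- function(fit_a, fit_b, universe = NULL) {
  one <- function(f) {
    k <- total_parameter_count(f$spec)
    c(obv = f$obv, k = k, n = f$n_obs,
      aic = aic(f$obv, k), bic = bic(f$obv, k, f$n_obs),
      mpe = mpe(f$ipred, f$obs$dv), rmse = rmse(f$ipred, f$obs$dv))
  }
  pairs_of <- function(f) vapply(f$spec$effects, function(e)
    paste0(e$target, "~", e$covariate), character(1))
  if (is.null(universe))
    universe <- sort(unique(c(pairs_of(fit_a), pairs_of(fit_b))))
  ka <- if (length(universe))
    cohen_kappa(covariate_inclusion(fit_a$spec, universe),
                covariate_inclusion(fit_b$spec, universe)) else NA_real_
  iiv_a <- fit_a$spec$iiv != "none"
  iiv_b <- fit_b$spec$iiv[names(fit_a$spec$iiv)] != "none"
  shared <- intersect(names(fit_a$params), names(fit_b$params))
  structure(list(
    model_a = one(fit_a), model_b = one(fit_b),
    delta_aic = unname(one(fit_b)["aic"] - one(fit_a)["aic"]),
    kappa_covariates = ka,
    kappa_variability = cohen_kappa(iiv_a, iiv_b),
    median_pct_diff = if (length(shared))
      median_pct_param_difference(fit_a$params, fit_b$params, shared)
    else NA_real_,
    universe = universe), class = "pk_model_comparison")
}

#' @export
print.pk_model_comparison <- function(x, ...) {
  m <- rbind(A = x$model_a, B = x$model_b)
  print(signif(m, 5))
  cat("delta AIC (B - A): ", signif(x$delta_aic, 5), "\n", sep = "")
  cat("kappa covariates: ", signif(x$kappa_covariates, 3),
      "   kappa variability: ", signif(x$kappa_variability, 3), "\n",
      sep = "")
  cat("median % parameter difference: ", signif(x$median_pct_diff, 4),
      "\n", sep = "")
  invisible(x)
}
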