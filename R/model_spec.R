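# Candidate model representation: structural kind, covariate effects with
# functional forms, inter-individual variability, residual error, initial
# estimates and bounds.

.cont_effect_kinds <- c("add", "prop", "exp", "pow", "mm")
.disc_effect_kinds <- c("add_d", "prop_d", "exp_d")

#' Number of coefficients carried by a covariate effect
#' @noRd
n_effect_thetas <- function(e) {
  if (e$kind == "mm") return(2L)
  if (e$kind %in% .disc_effect_kinds) return(length(e$reference) - 1L)
  1L
}

#' Define a covariate effect on a structural parameter
#'
#' Functional forms for a continuous covariate `x` with reference (median)
#' value `x~`: additive `TV + (x - x~) theta`; proportional
#' `TV (1 + theta x / x~)`; exponential `TV exp(theta x / x~)`; power-law
#' `TV (x / x~)^theta`; Michaelis-Menten
#' `TV theta1 (x/x~) / (theta2 + x/x~)`.  Discrete forms sum an indicator
#' term per non-reference category: additive `TV + sum theta_k`,
#' proportional `TV (1 + sum theta_k)`, exponential `TV exp(sum theta_k)`.
#'
#' @param target structural parameter name (e.g. `"CL"`).
#' @param covariate covariate column name.
#' @param kind one of `"add"`, `"prop"`, `"exp"`, `"pow"`, `"mm"`
#'   (continuous) or `"add_d"`, `"prop_d"`, `"exp_d"` (discrete).
#' @param reference for continuous kinds the positive reference value
#'   (typically the per-subject median of the covariate); for discrete
#'   kinds the vector of category labels with the reference category first.
#' @param init initial coefficient value(s): 1 for most kinds, 2 for
#'   `"mm"`, one per non-reference category for discrete kinds.
#' @param lower,upper coefficient bounds (recycled).
#' @return An object of class `pk_covariate_effect`.
#' @export
covariate_effect <- function(target, covariate, kind, reference,
                             init = NULL, lower = -20, upper = 20) {
  kind <- match.arg(kind, c(.cont_effect_kinds, .disc_effect_kinds))
  if (kind %in% .cont_effect_kinds) {
    if (kind != "add" || TRUE) {
      # every continuous Table-style form scales by the reference
      if (!is.numeric(reference) || length(reference) != 1 || reference <= 0)
        stop("continuous effects need a single positive reference value")
    }
  } else {
    if (length(reference) < 2)
      stop("discrete effects need >= 2 category labels (reference first)")
  }
  e <- structure(list(target = target, covariate = covariate, kind = kind,
                      reference = reference),
                 class = "pk_covariate_effect")
  nt <- n_effect_thetas(e)
  if (is.null(init)) init <- if (kind == "mm") c(1, 1) else rep(0, nt)
  if (length(init) != nt)
    stop("effect ", target, "~", covariate, " (", kind, ") needs ", nt,
         " initial value(s)")
  e$init <- init
  e$lower <- rep_len(lower, nt)
  e$upper <- rep_len(upper, nt)
  e
}

#' Label used for an effect's coefficients
#' @noRd
effect_label <- function(e) paste0(e$target, "~", e$covariate, ".", e$kind)

effect_theta_names <- function(e) {
  nt <- n_effect_thetas(e)
  if (nt == 1) effect_label(e) else paste0(effect_label(e), seq_len(nt))
}

#' Specify a candidate population PK model
#'
#' @param structural structural kind (see [structural_parameters()]).
#' @param effects list of [covariate_effect()] objects; applied in list
#'   order when computing typical values.
#' @param iiv named character vector over structural parameters with values
#'   `"none"`, `"exponential"` (lognormal, `P_i = TV exp(eta)`) or
#'   `"additive"` (`P_i = TV + eta`; a validation device for the
#'   `linear_test` kind).  Parameters not named default to `"none"`.
#' @param residual `"additive"`, `"proportional"` or `"combined"`.
#' @param init list with elements `theta` (named structural values),
#'   `omega` (named IIV standard deviations for parameters with IIV) and
#'   `sigma` (residual variances: length 1, or 2 for `"combined"` in the
#'   order proportional, additive).
#' @param theta_bounds optional list `list(lower=, upper=)` of named
#'   structural bounds (natural scale).
#' @return An object of class `pk_model_spec`.
#' @export
model_spec <- function(structural, effects = list(),
                       iiv = NULL, residual = "additive", init = NULL,
                       theta_bounds = NULL) {
  struct_names <- structural_parameters(structural)
  residual <- match.arg(residual, c("additive", "proportional", "combined"))

  iiv_full <- setNames(rep("none", length(struct_names)), struct_names)
  if (!is.null(iiv)) {
    if (is.null(names(iiv)) || !all(names(iiv) %in% struct_names))
      stop("iiv must be named by structural parameters of kind ", structural)
    bad <- !iiv %in% c("none", "exponential", "additive")
    if (any(bad)) stop("unknown iiv kind: ", iiv[bad][1])
    iiv_full[names(iiv)] <- iiv
  }

  for (e in effects) {
    if (!inherits(e, "pk_covariate_effect"))
      stop("effects must be covariate_effect objects")
    if (!e$target %in% struct_names)
      stop("effect targets unknown parameter ", e$target)
  }

  if (is.null(init)) init <- list()
  if (is.null(init$theta))
    init$theta <- setNames(rep(1, length(struct_names)), struct_names)
  if (!all(struct_names %in% names(init$theta)))
    stop("init$theta must name every structural parameter")
  init$theta <- init$theta[struct_names]
  iiv_names <- struct_names[iiv_full != "none"]
  if (is.null(init$omega))
    init$omega <- setNames(rep(0.3, length(iiv_names)), iiv_names)
  if (!all(iiv_names %in% names(init$omega)))
    stop("init$omega must name every parameter with IIV")
  init$omega <- init$omega[iiv_names]
  n_sig <- if (residual == "combined") 2L else 1L
  if (is.null(init$sigma)) init$sigma <- rep(0.1, n_sig)
  if (length(init$sigma) != n_sig)
    stop("init$sigma must have length ", n_sig, " for ", residual,
         " residual error")

  if (is.null(theta_bounds))
    theta_bounds <- list(
      lower = setNames(rep(1e-6, length(struct_names)), struct_names),
      upper = setNames(rep(1e6, length(struct_names)), struct_names))
  if (any(init$theta < theta_bounds$lower[struct_names]) ||
      any(init$theta > theta_bounds$upper[struct_names]))
    stop("initial structural values outside bounds")

  structure(list(structural = structural, effects = effects,
                 iiv = iiv_full, residual = residual, init = init,
                 theta_bounds = theta_bounds),
            class = "pk_model_spec")
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cat("<pk_model_spec> ", x$structural, ", residual: ", x$residual, "\n",
      sep = "")
  iiv_on <- names(x$iiv)[x$iiv != "none"]
  cat("IIV: ", if (length(iiv_on))
    paste0(iiv_on, " (", x$iiv[iiv_on], ")", collapse = ", ")
    else "none", "\n", sep = "")
  if (length(x$effects))
    cat("effects: ",
        paste(vapply(x$effects, effect_label, character(1)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted typical value of a structural parameter
#'
#' Starts from the covariate-free base value and applies each effect in
#' list order using the functional forms documented in
#' [covariate_effect()].
#'
#' @param base positive base value (scalar).
#' @param effects list of [covariate_effect()] objects (all applied;
#'   pre-filter by target when mixing parameters).
#' @param covs one-row data frame (or named list/vector) of covariate
#'   values; or a multi-row data frame for vectorized evaluation.
#' @param thetas list of coefficient vectors aligned with `effects`;
#'   defaults to each effect's `init`.
#' @return Numeric vector of typical values (length `nrow(covs)`).
#' @export
typical_value <- function(base, effects, covs, thetas = NULL) {
  covs <- as.data.frame(covs)
  if (is.null(thetas)) thetas <- lapply(effects, `[[`, "init")
  tv <- rep(base, max(1L, nrow(covs)))
  for (i in seq_along(effects)) {
    e <- effects[[i]]; th <- thetas[[i]]
    x <- covs[[e$covariate]]
    if (is.null(x)) stop("covariate ", e$covariate, " not found")
    tv <- switch(e$kind,
      add  = tv + (x - e$reference) * th[1],
      prop = tv * (1 + th[1] * x / e$reference),
      exp  = tv * exp((x / e$reference) * th[1]),
      pow  = tv * (x / e$reference)^th[1],
      mm   = tv * th[1] * (x / e$reference) / (th[2] + x / e$reference),
      {
        # discrete: indicator sum over non-reference categories
        s <- rep(0, length(x))
        for (k in seq_along(e$reference)[-1])
          s <- s + (x == e$reference[k]) * th[k - 1]
        switch(e$kind,
               add_d  = tv + s,
               prop_d = tv * (1 + s),
               exp_d  = tv * exp(s))
      })
  }
  tv
}

#' Individual parameter from a typical value and a random effect
#'
#' @param tv positive typical value.
#' @param iiv_kind `"none"`, `"exponential"` or `"additive"`.
#' @param eta random-effect value.
#' @return `tv` (`none`), `tv * exp(eta)` (`exponential`) or `tv + eta`
#'   (`additive`).
#' @export
individual_parameter <- function(tv, iiv_kind, eta) {
  switch(match.arg(iiv_kind, c("none", "exponential", "additive")),
         none = tv, exponential = tv * exp(eta), additive = tv + eta)
}

#' Residual error variance at a prediction
#'
#' @param pred model prediction(s).
#' @param kind `"additive"` (`s1`), `"proportional"` (`pred^2 s1`) or
#'   `"combined"` (`pred^2 s1 + s2`).
#' @param sigmas residual variance(s); for `"combined"`, the proportional
#'   variance first.
#' @return Variance vector aligned with `pred`.
#' @export
residual_variance <- function(pred, kind, sigmas) {
  switch(match.arg(kind, c("additive", "proportional", "combined")),
         additive = rep(sigmas[1], length(pred)),
         proportional = pred^2 * sigmas[1],
         combined = pred^2 * sigmas[1] + sigmas[2])
}

#' Count parsimony-penalized parameters of a model
#'
#' The GA's parsimony penalty applies per covariate coefficient, per
#' inter-individual variability term and per residual error term;
#' structural fixed effects are not penalized.
#'
#' @param spec a [model_spec()].
#' @return Named integer vector `c(n_cov_theta, n_omega, n_sigma)`.
#' @export
count_penalized_parameters <- function(spec) {
  n_cov <- sum(vapply(spec$effects, n_effect_thetas, integer(1)))
  c(n_cov_theta = as.integer(n_cov),
    n_omega = sum(spec$iiv != "none"),
    n_sigma = if (spec$residual == "combined") 2L else 1L)
}

#' Total number of estimated parameters
#'
#' @param spec a [model_spec()].
#' @return Structural thetas + covariate thetas + omegas + sigmas.
#' @export
total_parameter_count <- function(spec) {
  length(structural_parameters(spec$structural)) +
    sum(count_penalized_parameters(spec))
}

#' Full parameter names of a model in estimation order
#' @noRd
spec_param_names <- function(spec) {
  c(structural_parameters(spec$structural),
    unlist(lapply(spec$effects, effect_theta_names)),
    if (any(spec$iiv != "none"))
      paste0("omega.", names(spec$iiv)[spec$iiv != "none"]),
    switch(spec$residual, combined = c("sigma.prop", "sigma.add"),
           additive = "sigma.add", proportional = "sigma.prop"))
}

#' Short digest string identifying a model's structure
#' @noRd
spec_digest <- function(spec) {
  paste0(spec$structural, "|",
         paste(vapply(spec$effects, effect_label, character(1)),
               collapse = "+"), "|iiv:",
         paste(names(spec$iiv)[spec$iiv != "none"], collapse = ","),
         "|", spec$residual)
}
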