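# Methods for fitted model objects.

#' @export
print.pkfit <- function(x, ...) {
  cat("<pkfit> ", spec_digest(x$spec), "\n", sep = "")
  cat("OBV: ", formatC(x$obv, format = "f", digits = 3),
      "  converged: ", x$converged,
      "  covariance: ", x$covariance_success, "\n", sep = "")
  print(signif(x$params, 4))
  invisible(x)
}

#' @export
coef.pkfit <- function(object,
                       type = c("all", "theta", "omega", "sigma"), ...) {
  type <- match.arg(type)
  p <- object$params
  if (type == "all") return(p)
  pre <- switch(type, omega = "^omega\\.", sigma = "^sigma\\.",
                theta = "^(?!omega\\.|sigma\\.)")
  p[grepl(pre, names(p), perl = TRUE)]
}

#' @export
logLik.pkfit <- function(object, ...) {
  # OBV omits the n log(2 pi) constant unless include_2pi was set
  ll <- -object$obv / 2
  attr(ll, "df") <- total_parameter_count(object$spec)
  attr(ll, "nobs") <- object$n_obs
  class(ll) <- "logLik"
  ll
}

#' @export
summary.pkfit <- function(object, ...) {
  tab <- data.frame(estimate = object$params)
  if (!is.null(object$se)) {
    tab$se <- object$se
    tab$rse_pct <- object$rse_pct
  }
  out <- list(digest = spec_digest(object$spec), obv = object$obv,
              aic = aic(object$obv, total_parameter_count(object$spec)),
              bic = bic(object$obv, total_parameter_count(object$spec),
                        object$n_obs),
              converged = object$converged,
              covariance_success = object$covariance_success,
              condition_number = object$condition_number,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              coefficients = tab)
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Population PK fit: ", x$digest, "\n", sep = "")
  cat(x$n_subjects, " subjects, ", x$n_obs, " observations\n", sep = "")
  cat("OBV ", formatC(x$obv, format = "f", digits = 3),
      "   AIC ", formatC(x$aic, format = "f", digits = 3),
      "   BIC ", formatC(x$bic, format = "f", digits = 3), "\n", sep = "")
  cat("converged: ", x$converged, "   covariance step: ",
      x$covariance_success,
      if (is.finite(x$condition_number))
        paste0(" (condition number ", signif(x$condition_number, 3), ")"),
      "\n", sep = "")
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}

#' Predictions from a fitted population PK model
#'
#' @param object a `pkfit`.
#' @param newdata optional [pk_dataset()]; defaults to the fitted data.
#' @param type `"individual"` (at the empirical Bayes `eta`) or
#'   `"population"` (at `eta = 0`).
#' @param ... unused.
#' @return Data frame `subject_id`, `time`, `pred` over the non-missing
#'   observations.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  if (is.null(newdata) && type == "individual")
    return(data.frame(object$obs[c("subject_id", "time")],
                      pred = object$ipred))
  if (is.null(newdata))
    stop("population predictions need `newdata` (e.g. the fitted dataset)")
  if (type == "population") {
    ebe <- empirical_bayes_etas(zero_iiv_spec(object$spec),
                                strip_omega(object$params), newdata,
                                object$settings)
  } else {
    ebe <- empirical_bayes_etas(object$spec, object$params, newdata,
                                object$settings)
  }
  prob <- build_problem(object$spec, newdata)
  data.frame(subject_id = prob$obs_subject, time = prob$obs_time,
             pred = ebe$ipred)
}

zero_iiv_spec <- function(spec) {
  spec$iiv[] <- "none"
  spec$init$omega <- setNames(numeric(0), character(0))
  spec
}

strip_omega <- function(params) params[!grepl("^omega\\.", names(params))]

#' @export
residuals.pkfit <- function(object, type = c("individual", "weighted"),
                            ...) {
  type <- match.arg(type)
  r <- object$obs$dv - object$ipred
  if (type == "weighted") {
    sp <- split_params(object$spec, object$params)
    v <- residual_variance(object$ipred, object$spec$residual, sp$sigma)
    r <- r / sqrt(v)
  }
  r
}

#' Observed-versus-predicted diagnostic plot
#'
#' @param x a `pkfit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pkfit <- function(x, ...) {
  graphics::plot(x$ipred, x$obs$dv, xlab = "Individual prediction",
                 ylab = "Observed concentration", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
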