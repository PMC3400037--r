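# Automated stepwise covariate modeling: forward inclusion and backward
# elimination by likelihood-ratio thresholds.

#' Likelihood-ratio OBV threshold
#'
#' @param p significance level in (0, 1).
#' @param df degrees of freedom (number of added coefficients).
#' @return The chi-squared quantile at `1 - p`; e.g. 3.84 (`p = 0.05`),
#'   6.63 (`p = 0.01`), 7.88 (`p = 0.005`) at 1 df.
#' @export
lrt_threshold <- function(p, df = 1) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  qchisq(1 - p, df = df)
}

add_effect <- function(spec, e) {
  model_spec(spec$structural, effects = c(spec$effects, list(e)),
             iiv = spec$iiv, residual = spec$residual, init = spec$init,
             theta_bounds = spec$theta_bounds)
}

drop_effect <- function(spec, i) {
  model_spec(spec$structural, effects = spec$effects[-i],
             iiv = spec$iiv, residual = spec$residual, init = spec$init,
             theta_bounds = spec$theta_bounds)
}

# Carry a fit's estimates into a spec's initial values (warm start for
# the next nested fit).
update_init_from_fit <- function(spec, fit) {
  if (!is.finite(fit$obv)) return(spec)
  sp <- split_params(spec, fit$params)
  spec$init$theta <- sp$theta
  iiv_names <- names(spec$iiv)[spec$iiv != "none"]
  spec$init$omega <- setNames(sp$omega, iiv_names)
  spec$init$sigma <- sp$sigma
  for (i in seq_along(spec$effects))
    spec$effects[[i]]$init <- sp$cov[[i]]
  spec
}

scm_trace_row <- function(phase, step, candidate, obv, ref_obv, delta,
                          threshold, decision) {
  data.frame(phase = phase, step = step, candidate = candidate,
             obv = obv, ref_obv = ref_obv, delta = delta,
             threshold = threshold, decision = decision,
             stringsAsFactors = FALSE)
}

#' Forward covariate inclusion
#'
#' Each remaining candidate effect is added singly to the current model;
#' the candidate with the largest OBV drop is included if the drop is at
#' least `lrt_threshold(p_in, df)` with `df` the number of coefficients
#' it adds.  Ties break to the earlier-listed candidate.  Candidates whose
#' fit fails are skipped (logged).  The search stops when no candidate
#' qualifies.
#'
#' @param base a [model_spec()] that fits successfully.
#' @param ds a [pk_dataset()].
#' @param candidates list of [covariate_effect()]s.
#' @param p_in forward inclusion significance level.
#' @param settings [estimation_settings()] for the candidate fits.
#' @return List with `spec` (final model), `fit`, `trace` (step log) and
#'   `included` (candidate indices in inclusion order).
#' @export
forward_search <- function(base, ds, candidates, p_in = 0.05,
                           settings = estimation_settings()) {
  cur_fit <- fit_model(base, ds, settings, do_covariance = FALSE)
  if (!is.finite(cur_fit$obv)) stop("base model fit failed")
  cur <- update_init_from_fit(base, cur_fit)
  remaining <- seq_along(candidates)
  included <- integer(0)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    best <- NULL
    for (i in remaining) {
      e <- candidates[[i]]
      df_i <- n_effect_thetas(e)
      thr <- lrt_threshold(p_in, df_i)
      f <- fit_model(add_effect(cur, e), ds, settings,
                     do_covariance = FALSE)
      delta <- cur_fit$obv - f$obv
      ok <- is.finite(f$obv)
      trace[[length(trace) + 1L]] <- scm_trace_row(
        "forward", step, effect_label(e),
        f$obv, cur_fit$obv, delta, thr,
        if (!ok) "fit failed" else "tested")
      if (ok && delta >= thr && (is.null(best) || delta > best$delta))
        best <- list(i = i, delta = delta, fit = f)
    }
    if (is.null(best)) {
      trace[[length(trace) + 1L]] <- scm_trace_row(
        "forward", step, "(none)", NA, cur_fit$obv, NA, NA, "stop")
      break
    }
    cur <- update_init_from_fit(add_effect(cur, candidates[[best$i]]),
                                best$fit)
    cur_fit <- best$fit
    included <- c(included, best$i)
    remaining <- setdiff(remaining, best$i)
    trace[[length(trace) + 1L]] <- scm_trace_row(
      "forward", step, effect_label(candidates[[best$i]]),
      cur_fit$obv, NA, best$delta, NA, "added")
    if (length(remaining) == 0) break
  }
  list(spec = cur, fit = cur_fit, trace = do.call(rbind, trace),
       included = included)
}

#' Backward covariate elimination
#'
#' Repeatedly removes the included effect whose removal increases the OBV
#' the least, provided that increase is below `lrt_threshold(p_out, df)`;
#' stops when every removal is significant.
#'
#' @param full a [model_spec()] containing the candidate effects.
#' @param ds a [pk_dataset()].
#' @param p_out backward elimination significance level.
#' @param settings [estimation_settings()].
#' @return List with `spec`, `fit` and `trace`.
#' @export
backward_search <- function(full, ds, p_out = 0.01,
                            settings = estimation_settings()) {
  cur_fit <- fit_model(full, ds, settings, do_covariance = FALSE)
  cur <- update_init_from_fit(full, cur_fit)
  trace <- list()
  step <- 0L
  while (length(cur$effects) > 0) {
    step <- step + 1L
    best <- NULL
    for (i in seq_along(cur$effects)) {
      e <- cur$effects[[i]]
      thr <- lrt_threshold(p_out, n_effect_thetas(e))
      f <- fit_model(drop_effect(cur, i), ds, settings,
                     do_covariance = FALSE)
      inc <- f$obv - cur_fit$obv
      ok <- is.finite(f$obv)
      trace[[length(trace) + 1L]] <- scm_trace_row(
        "backward", step, effect_label(e), f$obv, cur_fit$obv, inc, thr,
        if (!ok) "fit failed" else "tested")
      if (ok && inc < thr && (is.null(best) || inc < best$inc))
        best <- list(i = i, inc = inc, fit = f)
    }
    if (is.null(best)) {
      trace[[length(trace) + 1L]] <- scm_trace_row(
        "backward", step, "(none)", NA, cur_fit$obv, NA, NA, "stop")
      break
    }
    lab <- effect_label(cur$effects[[best$i]])
    cur <- update_init_from_fit(drop_effect(cur, best$i), best$fit)
    cur_fit <- best$fit
    trace[[length(trace) + 1L]] <- scm_trace_row(
      "backward", step, lab, cur_fit$obv, NA, best$inc, NA, "removed")
  }
  list(spec = cur, fit = cur_fit,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Automated stepwise covariate modeling
#'
#' Forward inclusion at `p_in` followed by backward elimination at
#' `p_out` on the forward result.
#'
#' @inheritParams forward_search
#' @param p_out backward elimination significance level.
#' @return An object of class `scm_run` with the final `spec`, its `fit`
#'   (with covariance step), the concatenated `trace`, and the
#'   effect labels `selected`.
#' @export
run_scm <- function(base, ds, candidates, p_in = 0.05, p_out = 0.01,
                    settings = estimation_settings()) {
  t0 <- proc.time()[["elapsed"]]
  fw <- forward_search(base, ds, candidates, p_in, settings)
  bw <- backward_search(fw$spec, ds, p_out, settings)
  final_fit <- fit_model(bw$spec, ds, settings, do_covariance = TRUE)
  structure(list(spec = bw$spec, fit = final_fit,
                 trace = rbind(fw$trace, bw$trace),
                 selected = vapply(bw$spec$effects, effect_label,
                                   character(1)),
                 p_in = p_in, p_out = p_out,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "scm_run")
}

#' @export
print.scm_run <- function(x, ...) {
  cat("<scm_run> forward p = ", x$p_in, ", backward p = ", x$p_out, "\n",
      sep = "")
  cat("selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("final OBV: ", formatC(x$fit$obv, format = "f", digits = 2), "\n",
      sep = "")
  invisible(x)
}

#' Replay an SCM trace
#'
#' Re-applies the logged add/remove decisions to the base model; the
#' result must equal the search's final model.
#'
#' @param base the base [model_spec()] used for the search.
#' @param trace the `trace` of an [run_scm()] result.
#' @param candidates the candidate list used for the search.
#' @return The reconstructed [model_spec()].
#' @export
replay_scm_trace <- function(base, trace, candidates) {
  labels <- vapply(candidates, effect_label, character(1))
  cur <- base
  for (r in seq_len(nrow(trace))) {
    if (trace$decision[r] == "added") {
      cur <- add_effect(cur, candidates[[match(trace$candidate[r],
                                               labels)]])
    } else if (trace$decision[r] == "removed") {
      cur_labels <- vapply(cur$effects, effect_label, character(1))
      cur <- drop_effect(cur, match(trace$candidate[r], cur_labels))
    }
  }
  cur
}
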