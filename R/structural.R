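# Closed-form linear compartment models.

.pk_kinds <- list(
  onecpt_iv   = c("CL", "V"),
  onecpt_oral = c("CL", "V", "KA"),
  twocpt_iv   = c("CL", "V", "Q", "V2"),
  twocpt_oral = c("CL", "V", "KA", "Q", "V2"),
  linear_test = "CL")

.kind_code <- function(kind) match(kind, names(.pk_kinds))

#' Structural model parameter names
#'
#' @param kind one of `"onecpt_iv"`, `"onecpt_oral"`, `"twocpt_iv"`,
#'   `"twocpt_oral"`, `"linear_test"`.
#' @return Character vector of parameter names in canonical order.
#' @export
structural_parameters <- function(kind) {
  if (!kind %in% names(.pk_kinds)) stop("unknown structural kind: ", kind)
  .pk_kinds[[kind]]
}

#' Construct structural model parameters
#'
#' @inheritParams structural_parameters
#' @param CL clearance (L/h, > 0).
#' @param V central volume (L, > 0).
#' @param KA absorption rate constant (1/h, > 0; oral kinds only).
#' @param Q inter-compartment clearance (L/h, >= 0; two-compartment kinds).
#' @param V2 peripheral volume (L, > 0; two-compartment kinds).
#' @return A named numeric vector of class `structural_params`.
#' @export
structural_params <- function(kind, CL, V = NULL, KA = NULL, Q = NULL,
                              V2 = NULL) {
  nm <- structural_parameters(kind)
  vals <- c(CL = CL, V = V, KA = KA, Q = Q, V2 = V2)
  if (!all(nm %in% names(vals)))
    stop("kind ", kind, " requires parameters: ", paste(nm, collapse = ", "))
  p <- vals[nm]
  lower_ok <- ifelse(names(p) == "Q", p >= 0, p > 0)
  if (any(!lower_ok) || anyNA(p))
    stop("structural parameters must be positive (Q may be zero)")
  structure(p, kind = kind, class = "structural_params")
}

#' Predicted concentration under a linear compartment model
#'
#' Superposes the closed-form single-dose solutions over all dosing events:
#' one-compartment IV bolus `C = (D/V) exp(-(CL/V)(t - t_dose))`, the
#' standard during/after-infusion forms for infusions, the one-compartment
#' first-order absorption form with an analytic switch at the `KA -> CL/V`
#' singularity, and bi-exponential two-compartment forms from the
#' micro-constants `k10 = CL/V`, `k12 = Q/V`, `k21 = Q/V2`.  Returns 0
#' before the first dose.
#'
#' @param p a [structural_params()] object.
#' @param doses data frame with columns `time`, `amount`, `duration`.
#' @param t vector of times (h, >= 0).
#' @return Numeric vector of concentrations, one per element of `t`.
#' @export
concentration <- function(p, doses, t) {
  if (!inherits(p, "structural_params")) stop("p must be structural_params")
  if (any(t < 0)) stop("negative t")
  doses <- as.data.frame(doses)
  if (nrow(doses) == 0) stop("doses must be non-empty")
  if (is.null(doses$duration)) doses$duration <- 0
  dm <- cbind(doses$time, doses$amount, doses$duration)
  as.numeric(cpp_predict_conc(.kind_code(attr(p, "kind")), as.numeric(p),
                              dm, as.numeric(t)))
}

#' Elimination half-life of a one-compartment model
#'
#' @param CL clearance (L/h, > 0).
#' @param V volume of distribution (L, > 0).
#' @return `ln(2) * V / CL` in hours.
#' @export
half_life <- function(CL, V) {
  if (any(CL <= 0) || any(V <= 0)) stop("CL and V must be positive")
  log(2) * V / CL
}

#' Bi-exponential macro rate constants of a two-compartment model
#'
#' Solves `alpha + beta = k10 + k12 + k21`, `alpha * beta = k10 * k21`
#' with `k10 = CL/V`, `k12 = Q/V`, `k21 = Q/V2`.
#'
#' @param CL,V,Q,V2 two-compartment parameters (positive; `Q >= 0`).
#' @return Named vector `c(alpha, beta)` with `alpha >= beta >= 0` (1/h).
#' @export
biexp_rates <- function(CL, V, Q, V2) {
  if (V <= 0 || V2 <= 0) stop("V and V2 must be positive")
  if (CL <= 0 || Q < 0) stop("CL must be positive and Q non-negative")
  k10 <- CL / V; k12 <- Q / V; k21 <- Q / V2
  s <- k10 + k12 + k21; pr <- k10 * k21
  r <- sqrt(max(s^2 - 4 * pr, 0))
  c(alpha = (s + r) / 2, beta = max((s - r) / 2, 0))
}
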