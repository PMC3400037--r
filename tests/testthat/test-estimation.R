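test_that("objective is zero for a perfect no-IIV fit with unit additive variance", {
  # linear_test predictions equal the data exactly
  ids <- as.character(1:4)
  ds <- pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = 1,
                       duration = 0),
    observations = data.frame(subject_id = ids, time = 1, dv = 5,
                              missing_flag = FALSE))
  spec <- model_spec("linear_test", residual = "additive",
                     init = list(theta = c(CL = 5), sigma = 1))
  expect_equal(neg2ll(spec, c(CL = 5, sigma = 1), ds), 0)
  # FO and FOCE-I coincide exactly without IIV
  expect_identical(
    neg2ll(spec, c(CL = 5, sigma = 1), ds,
           estimation_settings(method = "FO")),
    neg2ll(spec, c(CL = 5, sigma = 1), ds,
           estimation_settings(method = "FOCE_I")))
})

test_that("FO equals FOCE-I on real data when the model has no IIV", {
  ds <- toy_iv_dataset(n_subjects = 8, omega = 0, sigma_add = 0.5)
  spec <- model_spec("onecpt_iv", residual = "additive",
                     init = list(theta = c(CL = 0.8, V = 2), sigma = 0.3))
  pv <- c(CL = 0.8, V = 2, sigma = 0.3)
  expect_identical(neg2ll(spec, pv, ds, estimation_settings(method = "FO")),
                   neg2ll(spec, pv, ds))
})

test_that("linear test model matches the closed-form Gaussian marginal", {
  ds <- linear_test_dataset(n = 40, theta = 5, omega = 1, sigma = 0.5,
                            seed = 7)
  spec <- linear_test_spec(theta = 5, omega = 1, sigma = 0.5)
  pv <- c(CL = 5, omega.CL = 1, sigma = 0.25)
  y <- ds$observations$dv
  closed <- sum(log(1 + 0.25) + (y - 5)^2 / 1.25)  # -2LL minus n log 2pi
  expect_equal(neg2ll(spec, pv, ds), closed, tolerance = 1e-8)
  # and with the 2*pi constant restored
  expect_equal(neg2ll(spec, pv, ds,
                      estimation_settings(include_2pi = TRUE)),
               closed + length(y) * log(2 * pi), tolerance = 1e-8)
})

test_that("FOCE-I matches adaptive quadrature on a small one-eta problem", {
  set.seed(42)
  n <- 6; times <- c(0.5, 1, 2, 4, 8); dose <- 50; V <- 2; CL <- 0.8
  omega <- 0.3; s_prop <- 0.1
  cl_i <- CL * exp(rnorm(n, 0, omega))
  dv <- t(sapply(seq_len(n), function(i) {
    pr <- dose / V * exp(-(cl_i[i] / V) * times)
    abs(pr * (1 + rnorm(length(times), 0, s_prop)))
  }))
  ids <- as.character(seq_len(n))
  ds <- pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = dose,
                       duration = 0),
    observations = data.frame(subject_id = rep(ids, each = length(times)),
                              time = rep(times, n),
                              dv = as.numeric(t(dv)),
                              missing_flag = FALSE))
  spec <- model_spec("onecpt_iv", iiv = c(CL = "exponential"),
                     residual = "proportional",
                     init = list(theta = c(CL = CL, V = V),
                                 omega = c(CL = omega),
                                 sigma = s_prop^2))
  pv <- c(CL = CL, V = V, omega.CL = omega, sigma = s_prop^2)
  obv <- neg2ll(spec, pv, ds, estimation_settings(include_2pi = TRUE))
  # independent oracle: numeric integration of each subject's marginal
  marg <- function(i) {
    f <- function(eta) vapply(eta, function(e) {
      pr <- dose / V * exp(-(CL * exp(e) / V) * times)
      exp(sum(dnorm(dv[i, ], pr, abs(pr) * s_prop, log = TRUE))) *
        dnorm(e, 0, omega)
    }, numeric(1))
    integrate(f, -1.5, 1.5, rel.tol = 1e-10)$value
  }
  obv_quad <- -2 * sum(log(vapply(seq_len(n), marg, numeric(1))))
  expect_lt(abs(obv - obv_quad), 0.5)
})

test_that("fit_model recovers parameters from nearly noise-free data", {
  ds <- toy_iv_dataset(n_subjects = 20, CL = 0.763, V = 1.94,
                       omega = 0, sigma_add = 0.05, seed = 3)
  spec <- model_spec("onecpt_iv", residual = "additive",
                     init = list(theta = c(CL = 1, V = 3), sigma = 0.1))
  f <- fit_model(spec, ds)
  expect_true(f$converged)
  expect_lt(abs(f$params[["CL"]] - 0.763) / 0.763, 0.02)
  expect_lt(abs(f$params[["V"]] - 1.94) / 1.94, 0.02)
  # restarting at the optimum does not worsen the objective
  spec2 <- spec
  spec2$init$theta <- c(CL = f$params[["CL"]], V = f$params[["V"]])
  spec2$init$sigma <- f$params[["sigma.add"]]
  f2 <- fit_model(spec2, ds)
  expect_lte(f2$obv, f$obv + 1e-6)
})

test_that("a forced timeout returns an unconverged fit instead of raising", {
  ds <- toy_iv_dataset(n_subjects = 10, omega = 0.2, sigma_add = 0.5)
  spec <- model_spec("onecpt_iv", iiv = c(CL = "exponential"),
                     residual = "additive",
                     init = list(theta = c(CL = 1, V = 3),
                                 omega = c(CL = 0.3), sigma = 0.3))
  st <- estimation_settings()
  st$timeout <- 0.001
  f <- fit_model(spec, ds, st)
  expect_false(f$converged)
  expect_false(f$covariance_success)
})

test_that("objective is invariant to subject relabelling and ordering", {
  ds <- toy_iv_dataset(n_subjects = 6, omega = 0.2, sigma_add = 0.3,
                       seed = 9)
  spec <- model_spec("onecpt_iv", iiv = c(CL = "exponential"),
                     residual = "additive",
                     init = list(theta = c(CL = 0.8, V = 2),
                                 omega = c(CL = 0.2), sigma = 0.09))
  pv <- c(CL = 0.8, V = 2, omega.CL = 0.2, sigma = 0.09)
  v1 <- neg2ll(spec, pv, ds)
  # relabel subjects (reverse ids) and permute their order
  relabel <- setNames(as.character(rev(seq_len(6) * 100)), ds$subjects)
  ds2 <- ds
  ds2$subjects <- unname(relabel[ds$subjects])
  ds2$doses$subject_id <- unname(relabel[ds$doses$subject_id])
  ds2$observations$subject_id <- unname(relabel[ds$observations$subject_id])
  ds2$covariates$subject_id <- unname(relabel[ds$covariates$subject_id])
  expect_equal(neg2ll(spec, pv, ds2), v1)
})

test_that("empirical Bayes etas shrink toward zero and vanish without IIV", {
  ds <- toy_iv_dataset(n_subjects = 12, omega = 0.3, sigma_add = 0.2,
                       seed = 5)
  spec <- model_spec("onecpt_iv", iiv = c(CL = "exponential"),
                     residual = "additive",
                     init = list(theta = c(CL = 0.763, V = 1.94),
                                 omega = c(CL = 0.3), sigma = 0.04))
  pv <- c(CL = 0.763, V = 1.94, omega.CL = 0.3, sigma = 0.04)
  ebe <- empirical_bayes_etas(spec, pv, ds)
  expect_equal(dim(ebe$etas), c(12, 1))
  expect_true(all(abs(ebe$etas) < 3 * 0.3))
  # omega -> 0 shrinks the MAP etas by orders of magnitude (the residual
  # shrink is O(omega^2) times the data gradient, not exactly zero)
  pv0 <- pv; pv0["omega.CL"] <- 1e-3
  ebe0 <- empirical_bayes_etas(spec, pv0, ds)
  expect_lt(max(abs(ebe0$etas)), 0.05)
  expect_lt(max(abs(ebe0$etas)), 0.1 * max(abs(ebe$etas)))
  # no-IIV spec: zero eta columns, ipred equals population prediction
  spec_no <- model_spec("onecpt_iv", residual = "additive",
                        init = list(theta = c(CL = 0.763, V = 1.94),
                                    sigma = 0.04))
  ebe_no <- empirical_bayes_etas(spec_no,
                                 c(CL = 0.763, V = 1.94, sigma = 0.04),
                                 ds)
  expect_equal(ncol(ebe_no$etas), 0)
  p <- structural_params("onecpt_iv", CL = 0.763, V = 1.94)
  pop <- concentration(p, data.frame(time = 0, amount = 100,
                                     duration = 0),
                       ds$observations$time[1:8])
  expect_equal(ebe_no$ipred[1:8], pop)
})

test_that("covariance step reproduces the analytic standard error of a mean", {
  # linear_test without IIV: y_j ~ N(theta, sigma^2); SE(theta-hat) is
  # sigma-hat / sqrt(n)
  set.seed(21)
  n <- 80
  ids <- as.character(seq_len(n))
  y <- abs(10 + rnorm(n, 0, 2))
  ds <- pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = 1,
                       duration = 0),
    observations = data.frame(subject_id = ids, time = 1, dv = y,
                              missing_flag = FALSE))
  spec <- model_spec("linear_test", residual = "additive",
                     init = list(theta = c(CL = 8), sigma = 1))
  f <- fit_model(spec, ds)
  expect_true(f$converged)
  expect_true(f$covariance_success)
  expect_equal(f$params[["CL"]], mean(y), tolerance = 1e-4)
  s2hat <- mean((y - mean(y))^2)
  expect_equal(f$se[["CL"]], sqrt(s2hat / n), tolerance = 1e-3)
  # orthogonal parameters: correlation ~ identity, condition number ~ 1
  expect_lt(f$condition_number, 1.05)
})

test_that("condition number is the eigenvalue ratio of the correlation matrix", {
  # 2x2 correlation with off-diagonal 0.6 has eigenvalues 1.6 and 0.4
  cm <- matrix(c(1, 0.6, 0.6, 1), 2)
  ev <- eigen(cm, only.values = TRUE)$values
  expect_equal(max(ev) / min(ev), 4)
})
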