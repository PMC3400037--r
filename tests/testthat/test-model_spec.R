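covs1 <- data.frame(WT = 80, AGE = 50, SEX = 1)

test_that("typical_value applies each continuous functional form correctly", {
  # neutral points: theta = 0 (theta1 = theta2 = 1 for MM), x at reference
  for (kind in c("prop", "exp", "pow")) {
    e <- covariate_effect("CL", "WT", kind, reference = 70, init = 0)
    expect_equal(typical_value(1, list(e), covs1, list(0)),
                 if (kind == "prop") 1 + 0 else 1, tolerance = 1e-12)
  }
  e_add <- covariate_effect("CL", "WT", "add", reference = 70, init = 5)
  expect_equal(typical_value(1, list(e_add), data.frame(WT = 70)), 1)
  e_mm <- covariate_effect("CL", "WT", "mm", reference = 80,
                           init = c(1, 1))
  expect_equal(typical_value(1, list(e_mm), covs1), 0.5)
  # worked values
  e_exp <- covariate_effect("CL", "WT", "exp", reference = 80,
                            init = log(2))
  expect_equal(typical_value(2, list(e_exp), covs1), 4)
  e_mm2 <- covariate_effect("CL", "WT", "mm", reference = 80,
                            init = c(2, 1))
  expect_equal(typical_value(1, list(e_mm2), covs1), 1)  # 2*1/(1+1)
  e_pow <- covariate_effect("CL", "WT", "pow", reference = 80, init = 7)
  expect_equal(typical_value(1, list(e_pow), covs1), 1)  # 1^theta
})

test_that("discrete forms sum indicator terms over non-reference categories", {
  e <- covariate_effect("V", "SEX", "add_d", reference = c(0, 1),
                        init = 0.5)
  expect_equal(typical_value(1, list(e), data.frame(SEX = 0)), 1)
  expect_equal(typical_value(1, list(e), data.frame(SEX = 1)), 1.5)
  e3 <- covariate_effect("V", "SITE", "exp_d", reference = c(1, 2, 3),
                        init = c(log(2), log(3)))
  expect_equal(typical_value(1, list(e3), data.frame(SITE = c(1, 2, 3))),
               c(1, 2, 3))
  ep <- covariate_effect("V", "SEX", "prop_d", reference = c(0, 1),
                         init = 0.2)
  expect_equal(typical_value(2, list(ep), data.frame(SEX = 1)), 2.4)
})

test_that("effects apply sequentially in list order and order matters", {
  e_add <- covariate_effect("CL", "WT", "add", reference = 70, init = 1)
  e_prop <- covariate_effect("CL", "WT", "prop", reference = 80,
                             init = 0.5)
  covs <- data.frame(WT = 80)
  tv_ap <- typical_value(1, list(e_add, e_prop), covs)   # (1+10)*1.5
  tv_pa <- typical_value(1, list(e_prop, e_add), covs)   # 1*1.5+10
  expect_equal(tv_ap, 16.5)
  expect_equal(tv_pa, 11.5)
  expect_false(tv_ap == tv_pa)
  expect_equal(typical_value(3.7, list(), covs), 3.7)  # empty list: identity
})

test_that("individual_parameter handles all IIV kinds", {
  expect_equal(individual_parameter(5, "none", 0.7), 5)
  expect_equal(individual_parameter(5, "exponential", 0), 5)
  expect_equal(individual_parameter(1, "exponential", log(3)), 3)
  expect_equal(individual_parameter(5, "additive", -1), 4)
})

test_that("residual_variance matches its definitions", {
  expect_equal(residual_variance(123, "additive", 4), 4)
  expect_equal(residual_variance(10, "proportional", 0.01), 1)
  expect_equal(residual_variance(0, "combined", c(0.01, 0.001)), 0.001)
  expect_equal(residual_variance(c(0, 10), "combined", c(0.01, 0.001)),
               c(0.001, 1.001))
})

test_that("parameter counting follows the parsimony rules", {
  covs <- data.frame(subject_id = "1", WT = 80)
  # true simulated model structure: 2 omegas + 2 sigmas, no covariates
  s0 <- model_spec("onecpt_iv", iiv = c(CL = "exponential",
                                        V = "exponential"),
                   residual = "combined",
                   init = list(theta = c(CL = 1, V = 2)))
  expect_equal(count_penalized_parameters(s0),
               c(n_cov_theta = 0L, n_omega = 2L, n_sigma = 2L))
  # Michaelis-Menten carries two coefficients
  s1 <- model_spec("onecpt_iv",
                   effects = list(covariate_effect("CL", "WT", "mm", 70)),
                   residual = "additive",
                   init = list(theta = c(CL = 1, V = 2)))
  expect_equal(count_penalized_parameters(s1),
               c(n_cov_theta = 2L, n_omega = 0L, n_sigma = 1L))
  expect_equal(total_parameter_count(s1), 2 + 2 + 0 + 1)
  # minimum: one residual term always present
  s2 <- model_spec("onecpt_iv", init = list(theta = c(CL = 1, V = 2)))
  expect_equal(unname(count_penalized_parameters(s2)), c(0L, 0L, 1L))
  # adding one single-theta effect raises k by exactly 1
  s3 <- model_spec("onecpt_iv",
                   effects = list(covariate_effect("CL", "WT", "exp", 70)),
                   init = list(theta = c(CL = 1, V = 2)))
  expect_equal(total_parameter_count(s3), total_parameter_count(s2) + 1)
  # the true simulated model has k = 10
  scovs <- simulate_covariates(covariate_sim_config(n_subjects = 20),
                               seed = 1)
  expect_equal(total_parameter_count(true_model_spec(scovs)), 10)
})

test_that("specs validate their structure", {
  expect_error(model_spec("onecpt_iv",
                          effects = list(covariate_effect("KA", "WT",
                                                          "exp", 70)),
                          init = list(theta = c(CL = 1, V = 2))),
               "unknown parameter")
  expect_error(covariate_effect("CL", "WT", "exp", reference = -1),
               "positive reference")
  expect_error(covariate_effect("CL", "SEX", "add_d", reference = 0),
               ">= 2 category labels")
  expect_error(covariate_effect("CL", "WT", "mm", 70, init = 1),
               "2 initial")
})
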