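test_that("IV bolus concentration follows the closed form", {
  p <- structural_params("onecpt_iv", CL = 0.763, V = 1.94)
  d <- data.frame(time = 0, amount = 100, duration = 0)
  expect_equal(concentration(p, d, 0), 100 / 1.94)
  expect_equal(concentration(p, d, half_life(0.763, 1.94)),
               100 / (2 * 1.94))
  expect_equal(concentration(p, d, c(1, 2)),
               100 / 1.94 * exp(-(0.763 / 1.94) * c(1, 2)))
})

test_that("half-life formula and worked values", {
  expect_equal(round(half_life(0.763, 1.94), 2), 1.76)
  expect_equal(half_life(log(2), 1), 1)
  expect_equal(half_life(2 * log(2), 1), 0.5)
  expect_error(half_life(0, 1))
})

test_that("two-compartment collapses to one compartment when Q = 0", {
  p1 <- structural_params("onecpt_iv", CL = 0.763, V = 1.94)
  p2 <- structural_params("twocpt_iv", CL = 0.763, V = 1.94, Q = 0,
                          V2 = 3)
  d <- data.frame(time = 0, amount = 100, duration = 0)
  tt <- c(0.1, 0.25, 0.5, 1, 2, 4, 6, 10, 16, 24)
  expect_equal(concentration(p2, d, tt), concentration(p1, d, tt),
               tolerance = 1e-12)
  # and for an infusion
  di <- data.frame(time = 0, amount = 100, duration = 2)
  expect_equal(concentration(p2, di, tt), concentration(p1, di, tt),
               tolerance = 1e-10)
})

test_that("biexponential rates satisfy their defining identities", {
  expect_equal(unname(biexp_rates(1, 1, 0, 1)), c(1, 0))
  # k10 = k12 = k21 = 1: alpha + beta = 3, alpha beta = 1
  r <- biexp_rates(1, 1, 1, 1)
  expect_equal(unname(r["alpha"]), (3 + sqrt(5)) / 2)
  expect_equal(sum(r), 3)
  expect_equal(prod(r), 1)
  set.seed(42)
  for (i in 1:25) {
    CL <- runif(1, 0.1, 10); V <- runif(1, 0.5, 50)
    Q <- runif(1, 0, 10); V2 <- runif(1, 0.5, 50)
    r <- biexp_rates(CL, V, Q, V2)
    k10 <- CL / V; k12 <- Q / V; k21 <- Q / V2
    expect_true(r["alpha"] >= r["beta"])
    expect_equal(unname(sum(r)), k10 + k12 + k21, tolerance = 1e-10)
    expect_equal(unname(prod(r)), k10 * k21, tolerance = 1e-10)
  }
})

test_that("dose linearity and superposition hold for every kind", {
  d1 <- data.frame(time = 0, amount = 100, duration = 0)
  d2 <- data.frame(time = 0, amount = 200, duration = 0)
  dd <- data.frame(time = c(0, 4), amount = 100, duration = 0)
  tt <- c(0.5, 1, 3, 5, 8, 12)
  specs <- list(
    structural_params("onecpt_iv", CL = 1, V = 10),
    structural_params("onecpt_oral", CL = 1, V = 10, KA = 1.5),
    structural_params("twocpt_iv", CL = 1, V = 10, Q = 2, V2 = 20),
    structural_params("twocpt_oral", CL = 1, V = 10, KA = 1.5, Q = 2,
                      V2 = 20))
  for (p in specs) {
    expect_equal(concentration(p, d2, tt), 2 * concentration(p, d1, tt))
    shifted <- concentration(p, d1, tt) +
      ifelse(tt >= 4, concentration(p, d1, pmax(tt - 4, 0)), 0)
    expect_equal(concentration(p, dd, tt), shifted, tolerance = 1e-12)
  }
})

test_that("IV kinds decay monotonically after the last dose", {
  tt <- seq(0.1, 48, by = 0.5)
  for (p in list(structural_params("onecpt_iv", CL = 1, V = 10),
                 structural_params("twocpt_iv", CL = 1, V = 10, Q = 3,
                                   V2 = 30))) {
    cc <- concentration(p, data.frame(time = 0, amount = 50,
                                      duration = 0), tt)
    expect_true(all(diff(cc) <= 0))
  }
})

test_that("oral model is continuous through the KA -> k singularity", {
  d <- data.frame(time = 0, amount = 100, duration = 0)
  tt <- c(0.5, 1, 2, 4, 8)
  k <- 0.5
  limit <- 100 * k * tt * exp(-k * tt) / 10  # D k tau e^{-k tau} / V
  for (eps in c(1e-7, -1e-7)) {
    p <- structural_params("onecpt_oral", CL = 5, V = 10,
                           KA = k * (1 + eps))
    expect_equal(concentration(p, d, tt), limit, tolerance = 1e-6)
  }
})

test_that("concentration is zero before the first dose and rejects bad input", {
  p <- structural_params("onecpt_iv", CL = 1, V = 10)
  d <- data.frame(time = 2, amount = 100, duration = 0)
  expect_equal(concentration(p, d, c(0, 1, 1.99)), rep(0, 3))
  expect_error(concentration(p, d, -1), "negative")
  expect_error(structural_params("nope", CL = 1), "unknown")
  expect_error(structural_params("onecpt_iv", CL = -1, V = 10))
})
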