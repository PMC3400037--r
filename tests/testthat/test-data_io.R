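test_that("a minimal well-formed CSV parses into one dose and one observation", {
  ds <- read_pkdata(textConnection(minimal_csv()))
  expect_s3_class(ds, "pk_dataset")
  expect_equal(length(ds$subjects), 1)
  expect_equal(nrow(ds$doses), 1)
  expect_equal(nrow(ds$observations), 1)
  expect_equal(ds$n_obs, 1)
  expect_equal(ds$observations$dv, 42.5)
  expect_equal(ds$covariates$WT, 70)
})

test_that("dose rows are recognised by the event column, or by nonzero AMT without one", {
  txt <- paste("ID,TIME,AMT,DV", "1,0,100,.", "1,1,0,42.5", sep = "\n")
  ds <- read_pkdata(textConnection(txt))
  expect_equal(nrow(ds$doses), 1)
  expect_equal(nrow(ds$observations), 1)
  # event column wins over AMT: AMT present on a non-dose row is ignored
  txt2 <- paste("ID,TIME,AMT,EVID,DV", "1,0,100,1,.", "1,1,50,0,42.5",
                sep = "\n")
  ds2 <- read_pkdata(textConnection(txt2))
  expect_equal(nrow(ds2$doses), 1)
})

test_that("missing DV is read from empty cells and the '.' sentinel", {
  txt <- paste("ID,TIME,AMT,EVID,DV", "1,0,100,1,.", "1,1,0,0,.",
               "1,2,0,0,", "1,3,0,0,5", sep = "\n")
  ds <- read_pkdata(textConnection(txt))
  expect_equal(ds$observations$missing_flag, c(TRUE, TRUE, FALSE))
  expect_equal(ds$n_obs, 1)
})

test_that("validation rejects invariant violations with informative errors", {
  expect_error(
    read_pkdata(textConnection(paste("ID,TIME,AMT,EVID,DV",
                                     "1,1,0,0,5", "1,2,100,1,.",
                                     sep = "\n"))),
    "before any dose")
  expect_error(
    read_pkdata(textConnection(paste("ID,TIME,AMT,EVID,DV,WT",
                                     "1,0,100,1,.,70", "1,1,0,0,5,80",
                                     sep = "\n"))),
    "varies within subject")
  expect_error(
    pk_dataset(doses = data.frame(subject_id = "1", time = 0, amount = 0,
                                  duration = 0),
               observations = data.frame(subject_id = "1", time = 1,
                                         dv = 1, missing_flag = FALSE)),
    "amount")
  expect_error(
    pk_dataset(doses = data.frame(subject_id = "1", time = -1,
                                  amount = 10, duration = 0),
               observations = data.frame(subject_id = "1", time = 1,
                                         dv = 1, missing_flag = FALSE)),
    "negative dose time")
  expect_error(
    pk_dataset(doses = data.frame(subject_id = "1", time = 0, amount = 10,
                                  duration = 0),
               observations = data.frame(subject_id = "1",
                                         time = c(2, 1), dv = 1,
                                         missing_flag = FALSE)),
    "sorted")
})

test_that("write/read round-trips datasets exactly", {
  ds <- toy_iv_dataset(n_subjects = 3, omega = 0.2, sigma_add = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pkdata(ds, path)
  ds2 <- read_pkdata(path)
  expect_identical(ds2$subjects, ds$subjects)
  expect_equal(ds2$doses, ds$doses)
  expect_equal(ds2$observations, ds$observations)
  expect_equal(ds2$n_obs, ds$n_obs)
})

test_that("the simulated-study dataset round-trips and validates for any seed", {
  for (seed in c(3, 17)) {
    covs <- simulate_covariates(covariate_sim_config(n_subjects = 30),
                                seed = seed)
    ds <- simulate_pk_dataset(covs, seed = seed + 1)
    expect_silent(validate_pk_dataset(ds))
    path <- withr::local_tempfile(fileext = ".csv")
    write_pkdata(ds, path)
    ds2 <- read_pkdata(path)
    expect_equal(ds2$observations$dv, ds$observations$dv)
    expect_equal(ds2$covariates, ds$covariates)
  }
})

test_that("the default simulated design yields 1600 non-missing observations", {
  covs <- simulate_covariates(seed = 5)
  ds <- simulate_pk_dataset(covs, seed = 6)
  expect_equal(length(ds$subjects), 200)
  expect_equal(ds$n_obs, 1600)
})

test_that("an empty dataset writes a header-only file", {
  ds <- pk_dataset(
    doses = data.frame(subject_id = character(), time = numeric(),
                       amount = numeric(), duration = numeric()),
    observations = data.frame(subject_id = character(), time = numeric(),
                              dv = numeric(), missing_flag = logical()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pkdata(ds, path)
  expect_length(readLines(path), 1)
})
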