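# Shared fixtures: tiny datasets and specs built in code.

# Noise-free (or low-noise) one-compartment IV dataset.
toy_iv_dataset <- function(n_subjects = 20, CL = 0.763, V = 1.94,
                           dose = 100,
                           times = c(0.25, 0.5, 1, 2, 3, 6, 10, 24),
                           omega = 0, sigma_add = 0, seed = 1) {
  set.seed(seed)
  ids <- as.character(seq_len(n_subjects))
  eta <- rnorm(n_subjects, 0, omega)
  dv <- unlist(lapply(seq_len(n_subjects), function(i) {
    cl_i <- CL * exp(eta[i])
    conc <- dose / V * exp(-(cl_i / V) * times)
    pmax(conc + rnorm(length(times), 0, sigma_add), 0)
  }))
  pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = dose,
                       duration = 0),
    observations = data.frame(
      subject_id = rep(ids, each = length(times)),
      time = rep(times, n_subjects), dv = dv, missing_flag = FALSE))
}

# One observation per subject from the linear test model:
# y ~ N(theta, omega^2 + sigma^2).
linear_test_dataset <- function(n = 50, theta = 5, omega = 1,
                                sigma = 0.5, seed = 1) {
  set.seed(seed)
  ids <- as.character(seq_len(n))
  y <- theta + rnorm(n, 0, omega) + rnorm(n, 0, sigma)
  pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = 1,
                       duration = 0),
    observations = data.frame(subject_id = ids, time = 1, dv = pmax(y, 0),
                              missing_flag = FALSE))
}

linear_test_spec <- function(theta = 5, omega = 1, sigma = 0.5) {
  model_spec("linear_test", iiv = c(CL = "additive"),
             residual = "additive",
             init = list(theta = c(CL = theta), omega = c(CL = omega),
                         sigma = sigma^2))
}

# CSV text for a minimal two-row dataset (one dose, one observation).
minimal_csv <- function() {
  paste("ID,TIME,AMT,EVID,DV,WT",
        "1,0,100,1,.,70",
        "1,1,0,0,42.5,70", sep = "\n")
}
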