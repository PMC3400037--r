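# Hand-constructed fit summaries for penalty accounting.
fake_fit <- function(obv = 1000, converged = TRUE, cov_ok = TRUE,
                     max_corr = 0.5, condn = 50) {
  corr <- matrix(c(1, max_corr, max_corr, 1), 2)
  list(obv = obv, converged = converged, covariance_success = cov_ok,
       correlation = if (cov_ok) corr else NULL,
       condition_number = condn)
}

six_param_spec <- function() {
  covs <- data.frame(WT = 80)
  model_spec("onecpt_iv",
             effects = list(covariate_effect("CL", "WT", "exp", 70),
                            covariate_effect("V", "WT", "exp", 70)),
             iiv = c(CL = "exponential", V = "exponential"),
             residual = "combined",
             init = list(theta = c(CL = 1, V = 2)))
}

test_that("fitness penalties follow the 10/400/300 accounting rules", {
  cfg <- ga_config()
  spec <- six_param_spec()  # 2 covariate thetas + 2 omegas + 2 sigmas
  fc <- evaluate_fitness(fake_fit(obv = 1000), spec, cfg)
  expect_equal(unname(fc["parsimony"]), 60)
  expect_equal(unname(fc["total"]), 1060)
  # a failed minimization adds a single 400-unit penalty
  fc2 <- evaluate_fitness(fake_fit(obv = 1000, converged = FALSE), spec,
                          cfg)
  expect_equal(unname(fc2["total"]), 1460)
  # ... as does a failed covariance step (not stacked)
  fc2b <- evaluate_fitness(fake_fit(obv = 1000, converged = FALSE,
                                    cov_ok = FALSE), spec, cfg)
  expect_equal(unname(fc2b["total"]), 1460)
  # an off-diagonal correlation above 0.95 adds 300
  fc3 <- evaluate_fitness(fake_fit(obv = 1000, max_corr = 0.96), spec,
                          cfg)
  expect_equal(unname(fc3["total"]), 1360)
  # the condition-number penalty is off by default ...
  fc4 <- evaluate_fitness(fake_fit(obv = 1000, condn = 2830), spec, cfg)
  expect_equal(unname(fc4["condition"]), 0)
  # ... and adds 300 above 1000 when enabled
  cfg_cn <- ga_config(condition_enabled = TRUE)
  fc5 <- evaluate_fitness(fake_fit(obv = 1000, condn = 2830), spec,
                          cfg_cn)
  expect_equal(unname(fc5["condition"]), 300)
  expect_equal(unname(fc5["total"]), 1360)
  # components always sum to the total
  for (fc_i in list(fc, fc2, fc3, fc5))
    expect_equal(unname(fc_i["total"]),
                 sum(fc_i[setdiff(names(fc_i), "total")]))
})

test_that("fitness scaling maps the two-deviation window onto [0.2, 4]", {
  expect_equal(scale_fitness(c(10, 20)), c(4, 0.2))
  expect_equal(scale_fitness(rep(7, 5)), rep(1, 5))
  w <- scale_fitness(c(0, 10, 20, 1e9))
  expect_equal(w[4], 0.2)
  expect_equal(w[1], 4)
  expect_true(all(w >= 0.2 & w <= 4))
  # non-finite fitness clamps to the worst weight
  expect_equal(scale_fitness(c(5, 6, Inf))[3], 0.2)
  expect_error(scale_fitness(numeric(0)), "empty")
})

test_that("roulette selection draws parents proportional to weights", {
  set.seed(11)
  pairs <- select_parents(c(4, 0.2), 5e4)
  frac <- mean(pairs == 1)
  p <- 4 / 4.2
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e5))
  # a single positive weight always wins
  expect_true(all(select_parents(c(0, 1, 0), 10) == 2))
  expect_error(select_parents(c(0, 0), 2), "all-zero")
})

test_that("niche assignment protects distant leaders and penalizes clones", {
  cfg <- ga_config(niche_distance = 4, n_niches = 4, niche_penalty = 200)
  g <- rep("000000", 4)
  out <- assign_niches(g, c(1, 2, 3, 4), cfg)
  expect_equal(out$niche_id, rep(1L, 4))
  expect_equal(out$penalty, c(0, 200, 200, 200))
  # two genomes at Hamming distance 5: two unpenalized leaders
  out2 <- assign_niches(c("0000000", "1111100"), c(2, 1), cfg)
  expect_equal(sort(out2$niche_id), c(1L, 2L))
  expect_equal(out2$penalty, c(0, 0))
  # distance 4 or fewer joins the leader's niche
  out3 <- assign_niches(c("0000000", "1111000"), c(1, 2), cfg)
  expect_equal(out3$niche_id, c(1L, 1L))
  expect_equal(out3$penalty, c(0, 200))
  # four mutually distant genomes: four exempt niches
  g4 <- c("000000000000", "111110000000", "000001111100", "111111111111")
  out4 <- assign_niches(g4, 1:4, cfg)
  expect_equal(length(unique(out4$niche_id)), 4)
  expect_equal(out4$penalty, rep(0, 4))
})

test_that("downhill search reaches the optimum of an enumerable toy fitness", {
  # fitness = number of zero bits; unique optimum at 111
  evalr <- function(g) sum(strsplit(g, "")[[1]] == "0")
  res <- downhill_search("000", evalr)
  expect_equal(res$genome, "111")
  expect_equal(res$fitness, 0)
  # starting at a local (here global) optimum returns unchanged
  res2 <- downhill_search("111", evalr)
  expect_equal(res2$genome, "111")
  # output fitness never exceeds input fitness on rugged fitnesses
  set.seed(13)
  rugged <- new.env()
  evalr2 <- function(g) {
    if (is.null(rugged[[g]])) rugged[[g]] <- runif(1)
    rugged[[g]]
  }
  for (i in 1:10) {
    g0 <- paste(sample(0:1, 8, replace = TRUE), collapse = "")
    f0 <- evalr2(g0)
    expect_lte(downhill_search(g0, evalr2)$fitness, f0)
  }
})

test_that("one downhill sweep on a 40-bit genome evaluates its 40 neighbors", {
  calls <- new.env(); calls$n <- 0
  # flat fitness: no neighbor improves, so exactly one sweep happens
  evalr <- function(g) { calls$n <- calls$n + 1; 1 }
  g <- paste(rep("0", 40), collapse = "")
  downhill_search(g, evalr)
  expect_equal(calls$n, 41)  # the start plus its 40 one-bit neighbors
})

# -- a tiny but real GA run: 2-slot space over a fast-fitting dataset ----

tiny_run <- function(seed = 7, generations = 2) {
  set.seed(99)
  n <- 24
  ids <- as.character(seq_len(n))
  wt <- runif(n, 50, 100)
  times <- c(1, 4)
  dv <- unlist(lapply(seq_len(n), function(i) {
    cl <- 0.8 * exp(0.5 * (wt[i] / 75))  # a strong WT effect on CL
    pmax(100 / 2 * exp(-(cl / 2) * times) + rnorm(2, 0, 0.5), 0)
  }))
  ds <- pk_dataset(
    doses = data.frame(subject_id = ids, time = 0, amount = 100,
                       duration = 0),
    observations = data.frame(subject_id = rep(ids, each = 2),
                              time = rep(times, n), dv = dv,
                              missing_flag = FALSE),
    covariates = data.frame(subject_id = ids, WT = wt))
  base <- model_spec("onecpt_iv", residual = "additive",
                     init = list(theta = c(CL = 1, V = 2), sigma = 0.3))
  cand <- list(covariate_effect("CL", "WT", "exp", median(wt)),
               covariate_effect("V", "WT", "exp", median(wt)))
  space <- covariate_search_space(base, cand)
  cfg <- ga_config(pop_size = 4, generations = generations,
                   downhill_period = 0, niche_penalty = 50,
                   fit_timeout = 30, generation_timeout = 120,
                   seed = seed)
  run_sohga(space, ds, cfg, estimation_settings(max_evals = 600))
}

test_that("the GA finds the exhaustive-search optimum of a 2-slot space", {
  run <- tiny_run()
  # 4 genomes total: the best must carry the true WT-on-CL effect
  labs <- vapply(run$best$spec$effects, function(e)
    paste0(e$target, "~", e$covariate), character(1))
  expect_true("CL~WT" %in% labs)
  # elitism: the per-generation best never worsens
  nf <- run$per_generation_best$total
  expect_true(all(diff(nf) <= 1e-9))
  # every record's total equals obv + the sum of its penalties
  rec <- run$records
  ok <- is.finite(rec$obv)
  expect_equal(rec$total[ok],
               rec$obv[ok] + rec$parsimony[ok] + rec$nonconvergence[ok] +
                 rec$correlation[ok] + rec$condition[ok] + rec$niche[ok])
})

test_that("seeded runs are bit-reproducible and generations=0 logs only the start", {
  r1 <- tiny_run(seed = 21)
  r2 <- tiny_run(seed = 21)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$best$genome, r2$best$genome)
  r0 <- tiny_run(seed = 21, generations = 0)
  expect_equal(unique(r0$records$generation), 0)
  expect_equal(nrow(r0$records), 4)
})
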