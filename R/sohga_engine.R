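# Single-objective hybrid genetic algorithm: penalized fitness, scaled
# roulette selection, niching, elitism, periodic one-bit downhill search.

#' GA configuration
#'
#' Defaults follow the standard recipe for this search: population of 200 for 40
#' generations, 0.7 expected crossover events per parent pair, 0.01
#' mutations per bit, a 10-point parsimony penalty per covariate / IIV /
#' residual-error parameter, a 400-unit penalty when minimization or the
#' covariance step fails, a 300-unit penalty when any off-diagonal of the
#' estimation correlation matrix exceeds 0.95 in absolute value, an
#' optional (disabled by default) 300-unit penalty for a condition number
#' above 1000, fitness scaling of the two-standard-deviation window to
#' weights in `[0.2, 4]`, four protected niches at Hamming distance <= 4,
#' and a downhill sweep every five generations.
#'
#' @param pop_size even population size.
#' @param generations number of generations.
#' @param crossover_prob probability that a selected parent pair crosses
#'   over.
#' @param mutation_rate per-bit mutation probability.
#' @param parsimony_penalty fitness points per penalized parameter (10
#'   default; 3.84 is the likelihood-ratio-scaled alternative).
#' @param nonconvergence_penalty applied once when minimization or the
#'   covariance step fails.
#' @param correlation_penalty,correlation_threshold penalty when any
#'   absolute off-diagonal estimation correlation exceeds the threshold.
#' @param condition_penalty,condition_threshold,condition_enabled optional
#'   ill-conditioning penalty on the correlation-matrix eigenvalue ratio.
#' @param niche_distance Hamming radius of a niche.
#' @param n_niches number of niche leaders exempt from the niche penalty.
#' @param niche_penalty fitness penalty for candidates similar to a better
#'   candidate (the magnitude is a package convention).
#' @param downhill_period generations between downhill sweeps.
#' @param downhill_budget cap on candidate evaluations per niche leader
#'   in one downhill phase (`Inf` runs each search to a local optimum).
#' @param scale_bounds selection-weight range of the fitness scaling.
#' @param fit_timeout per-fit wall-clock limit (s).
#' @param generation_timeout per-generation wall-clock limit (s).
#' @param include_base_genome seed the all-zero (base-model) genome into
#'   generation 0.
#' @param seed integer RNG seed for the whole run.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, generations = 40,
                      crossover_prob = 0.7, mutation_rate = 0.01,
                      parsimony_penalty = 10,
                      nonconvergence_penalty = 400,
                      correlation_penalty = 300,
                      correlation_threshold = 0.95,
                      condition_penalty = 300,
                      condition_threshold = 1000,
                      condition_enabled = FALSE,
                      niche_distance = 4, n_niches = 4,
                      niche_penalty = 200, downhill_period = 5,
                      downhill_budget = Inf,
                      scale_bounds = c(0.2, 4), fit_timeout = 60,
                      generation_timeout = 600,
                      include_base_genome = FALSE, seed = 1L) {
  if (pop_size %% 2 != 0) stop("pop_size must be even")
  if (crossover_prob <= 0 || crossover_prob > 1)
    stop("crossover_prob must be in (0, 1]")
  stopifnot(parsimony_penalty >= 0, nonconvergence_penalty >= 0,
            correlation_penalty >= 0, niche_penalty >= 0)
  structure(as.list(environment()), class = "ga_config")
}

#' Penalized fitness of an evaluated candidate
#'
#' Total fitness = OBV + parsimony + non-convergence + correlation +
#' condition (+ a niche penalty set during the population step).  The
#' non-convergence penalty is applied once when either the minimization or
#' the covariance step failed; the correlation and condition checks are
#' skipped when no covariance matrix exists (the 400-unit penalty already
#' covers that failure).
#'
#' @param fit a [fit_model()] result for `spec`.
#' @param spec the candidate [model_spec()].
#' @param cfg a [ga_config()].
#' @return Named numeric vector of class `fitness_components` with
#'   elements `obv`, `parsimony`, `nonconvergence`, `correlation`,
#'   `condition`, `niche`, `total`.
#' @export
evaluate_fitness <- function(fit, spec, cfg = ga_config()) {
  obv <- if (is.finite(fit$obv)) fit$obv else Inf
  np <- sum(count_penalized_parameters(spec))
  parsimony <- cfg$parsimony_penalty * np
  nonconv <- if (!isTRUE(fit$converged) || !isTRUE(fit$covariance_success))
    cfg$nonconvergence_penalty else 0
  corr_pen <- 0
  cond_pen <- 0
  if (isTRUE(fit$covariance_success) && !is.null(fit$correlation)) {
    off <- fit$correlation
    diag(off) <- 0
    if (max(abs(off)) > cfg$correlation_threshold)
      corr_pen <- cfg$correlation_penalty
    if (cfg$condition_enabled && is.finite(fit$condition_number) &&
        fit$condition_number > cfg$condition_threshold)
      cond_pen <- cfg$condition_penalty
  }
  comp <- c(obv = obv, parsimony = parsimony, nonconvergence = nonconv,
            correlation = corr_pen, condition = cond_pen, niche = 0)
  structure(c(comp, total = sum(comp)), class = "fitness_components")
}

#' Scale population fitness values to selection weights
#'
#' Mean and standard deviation are computed over the finite totals; the
#' values within two standard deviations of the mean define a linear map
#' sending the window's best (lowest) fitness to `bounds[2]` and its worst
#' to `bounds[1]`; values outside the window (and non-finite totals) clamp
#' to the corresponding extreme.  A zero-spread population maps to weight
#' 1 everywhere.
#'
#' @param totals numeric vector of total fitness values (lower is better).
#' @param bounds weight range, default `c(0.2, 4)`.
#' @return Numeric selection weights aligned with `totals`.
#' @export
scale_fitness <- function(totals, bounds = c(0.2, 4)) {
  if (length(totals) == 0) stop("empty population")
  lo <- bounds[1]; hi <- bounds[2]
  w <- rep(1, length(totals))
  fin <- is.finite(totals)
  w[!fin] <- lo
  x <- totals[fin]
  if (length(x) == 0) return(w)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(w)  # degenerate window
  m <- mean(x)
  inwin <- abs(x - m) <= 2 * s
  wb <- min(x[inwin]); ww <- max(x[inwin])
  wf <- numeric(length(x))
  if (ww == wb) {
    wf[inwin] <- 1
  } else {
    wf[inwin] <- hi + (x[inwin] - wb) * (lo - hi) / (ww - wb)
  }
  wf[!inwin & x < wb] <- hi
  wf[!inwin & x > ww] <- lo
  w[fin] <- wf
  w
}

#' Roulette selection of parent pairs
#'
#' @param weights non-negative selection weights, not all zero.
#' @param n_pairs number of parent pairs to draw.
#' @return `n_pairs x 2` matrix of candidate indices.
#' @export
select_parents <- function(weights, n_pairs) {
  if (all(weights <= 0)) stop("all-zero selection weights")
  idx <- sample.int(length(weights), 2 * n_pairs, replace = TRUE,
                    prob = weights)
  matrix(idx, ncol = 2)
}

#' Assign niches and niche penalties
#'
#' Greedy leader clustering in fitness order: the best unassigned
#' candidate seeds a niche and every candidate within `niche_distance`
#' Hamming bits joins it.  Non-leader members receive `niche_penalty`;
#' leaders beyond the first `n_niches` are penalized too.
#'
#' @param genomes character vector of genomes.
#' @param totals their total fitness values (lower is better).
#' @param cfg a [ga_config()].
#' @return List with `niche_id` (integer per candidate), `penalty`
#'   (numeric per candidate) and `leaders` (candidate index per niche).
#' @export
assign_niches <- function(genomes, totals, cfg = ga_config()) {
  n <- length(genomes)
  ord <- order(totals)
  niche_id <- integer(n)
  leaders <- integer(0)
  for (i in ord) {
    if (niche_id[i] != 0) next
    leaders <- c(leaders, i)
    nid <- length(leaders)
    for (j in ord) {
      if (niche_id[j] == 0 &&
          hamming(genomes[i], genomes[j]) <= cfg$niche_distance)
        niche_id[j] <- nid
    }
  }
  penalty <- rep(cfg$niche_penalty, n)
  exempt <- leaders[seq_len(min(cfg$n_niches, length(leaders)))]
  penalty[exempt] <- 0
  list(niche_id = niche_id, penalty = penalty, leaders = leaders)
}

#' One-bit downhill local search
#'
#' Repeatedly evaluates all one-bit neighbors of the current genome and
#' moves to the best strictly improving neighbor, stopping at a local
#' optimum or when the evaluation budget is exhausted.
#'
#' @param g starting genome.
#' @param evaluator function mapping a genome to its total fitness
#'   (expected to cache repeated evaluations).
#' @param budget cap on evaluator calls.
#' @return List with `genome`, `fitness` (never worse than the start) and
#'   `evals`.
#' @export
downhill_search <- function(g, evaluator, budget = Inf) {
  f <- unname(evaluator(g))
  evals <- 1
  repeat {
    nb <- one_bit_neighbors(g)
    if (evals + length(nb) > budget) break
    fn <- unname(vapply(nb, evaluator, numeric(1)))
    evals <- evals + length(nb)
    k <- which.min(fn)
    if (length(k) == 0 || !(fn[k] < f)) break
    g <- nb[k]
    f <- fn[k]
  }
  list(genome = g, fitness = f, evals = evals)
}

# ---- run state -----------------------------------------------------------

# Seed a candidate spec's initial values from a previously fitted
# model's estimates, matched by parameter name; unseen coefficients keep
# their defaults.
warm_spec_from <- function(spec, source_params) {
  if (is.null(source_params) || anyNA(source_params)) return(spec)
  nm <- names(source_params)
  th <- structural_parameters(spec$structural)
  hit <- intersect(th, nm)
  spec$init$theta[hit] <- source_params[hit]
  for (i in seq_along(spec$effects)) {
    enm <- effect_theta_names(spec$effects[[i]])
    if (all(enm %in% nm))
      spec$effects[[i]]$init <- unname(source_params[enm])
  }
  onm <- intersect(paste0("omega.", names(spec$iiv)[spec$iiv != "none"]),
                   nm)
  spec$init$omega[sub("^omega\\.", "", onm)] <- source_params[onm]
  snm <- intersect(spec_param_names(spec), nm)
  snm <- snm[grepl("^sigma\\.", snm)]
  if (length(snm)) {
    full <- spec_param_names(spec)
    sidx <- match(snm, full[grepl("^sigma\\.", full)])
    spec$init$sigma[sidx] <- source_params[snm]
  }
  spec
}

new_candidate_evaluator <- function(space, ds, cfg, settings) {
  cache <- new.env(parent = emptyenv())
  list(
    cache = cache,
    evaluate = function(g, deadline = Inf) {
      if (!is.null(cache[[g]])) return(cache[[g]])
      spec <- decode(g, space)
      # warm start from the nearest already-fitted genome (and skip the
      # FO pre-fit when a good FOCE-I start is available)
      warmed <- FALSE
      keys <- ls(cache)
      if (length(keys)) {
        dists <- vapply(keys, hamming, numeric(1), g2 = g)
        src <- cache[[keys[which.min(dists)]]]
        if (isTRUE(src$converged)) {
          spec <- warm_spec_from(spec, src$params)
          warmed <- TRUE
        }
      }
      if (proc.time()[["elapsed"]] > deadline) {
        fit <- list(obv = NA_real_, converged = FALSE,
                    covariance_success = FALSE, correlation = NULL,
                    condition_number = NA_real_)
        evaluated <- FALSE
      } else {
        st <- settings
        st$timeout <- min(st$timeout, cfg$fit_timeout,
                          max(deadline - proc.time()[["elapsed"]], 0.001))
        if (warmed) st$fo_prefit <- FALSE
        fit <- fit_model(spec, ds, st)
        evaluated <- TRUE
      }
      comp <- evaluate_fitness(fit, spec, cfg)
      rec <- list(genome = g, digest = spec_digest(spec),
                  obv = fit$obv, converged = isTRUE(fit$converged),
                  covariance_success = isTRUE(fit$covariance_success),
                  max_abs_corr = if (isTRUE(fit$covariance_success)) {
                    off <- fit$correlation; diag(off) <- 0; max(abs(off))
                  } else NA_real_,
                  condition_number = fit$condition_number,
                  components = comp, total = unname(comp["total"]),
                  evaluated = evaluated, params = fit$params,
                  se = fit$se)
      cache[[g]] <- rec
      rec
    })
}

random_genome <- function(L) paste(sample(0:1, L, replace = TRUE),
                                   collapse = "")

#' Initialize a SOHGA run state
#'
#' Seeds the RNG, draws the initial random population (optionally
#' including the all-zero base-model genome) and evaluates it.
#'
#' @param space a [search_space()].
#' @param ds a [pk_dataset()].
#' @param cfg a [ga_config()].
#' @param settings [estimation_settings()] used for candidate fits.
#' @return An opaque state list consumed by [step_generation()].
#' @export
sohga_init <- function(space, ds, cfg = ga_config(),
                       settings = estimation_settings()) {
  set.seed(cfg$seed)
  ev <- new_candidate_evaluator(space, ds, cfg, settings)
  L <- space$total_bits
  pop <- vapply(seq_len(cfg$pop_size), function(i) random_genome(L),
                character(1))
  if (cfg$include_base_genome) pop[1] <- paste(rep("0", L), collapse = "")
  state <- list(space = space, ds = ds, cfg = cfg, settings = settings,
                ev = ev, pop = pop, gen = 0L, records = list(),
                best_genome = NA_character_, best_total = Inf,
                gen_best = list(), t0 = proc.time()[["elapsed"]])
  state <- evaluate_population(state)
  record_gen_best(state)
}

# Snapshot the best-so-far candidate at the end of a generation (after
# elitism and any downhill phase), so the per-generation series is the
# monotone elitist track.
record_gen_best <- function(state) {
  rec <- state$ev$evaluate(state$best_genome)
  state$gen_best[[length(state$gen_best) + 1L]] <-
    data.frame(generation = state$gen, genome = state$best_genome,
               digest = rec$digest, obv = rec$obv,
               total = state$best_total, stringsAsFactors = FALSE)
  state
}

evaluate_population <- function(state) {
  cfg <- state$cfg
  deadline <- proc.time()[["elapsed"]] + cfg$generation_timeout
  recs <- lapply(state$pop, state$ev$evaluate, deadline = deadline)
  totals <- vapply(recs, `[[`, numeric(1), "total")
  nich <- assign_niches(state$pop, totals, cfg)
  rows <- data.frame(
    generation = state$gen, genome = state$pop,
    digest = vapply(recs, `[[`, character(1), "digest"),
    obv = vapply(recs, `[[`, numeric(1), "obv"),
    converged = vapply(recs, `[[`, logical(1), "converged"),
    covariance_success = vapply(recs, `[[`, logical(1),
                                "covariance_success"),
    parsimony = vapply(recs, function(r) r$components[["parsimony"]],
                       numeric(1)),
    nonconvergence = vapply(recs, function(r)
      r$components[["nonconvergence"]], numeric(1)),
    correlation = vapply(recs, function(r) r$components[["correlation"]],
                         numeric(1)),
    condition = vapply(recs, function(r) r$components[["condition"]],
                       numeric(1)),
    niche = nich$penalty, total = totals + nich$penalty,
    niche_id = nich$niche_id,
    stringsAsFactors = FALSE)
  state$records[[length(state$records) + 1L]] <- rows
  state$niche <- nich
  state$totals <- totals
  b <- which.min(totals)
  if (length(b) && totals[b] < state$best_total) {
    state$best_total <- totals[b]
    state$best_genome <- state$pop[b]
  }
  state
}

#' Advance a SOHGA run by one generation
#'
#' Selection (roulette on scaled fitness including niche penalties) ->
#' crossover with probability `crossover_prob` -> per-bit mutation ->
#' evaluation of the new candidates (failures absorbed as penalties) ->
#' niche assignment -> elitism (the best-so-far genome re-enters,
#' replacing the worst child, if lost).  Every `downhill_period`
#' generations the best genome of each niche is refined by
#' [downhill_search()].
#'
#' @param state a state from [sohga_init()] or a previous step.
#' @return The updated state.
#' @export
step_generation <- function(state) {
  cfg <- state$cfg
  sel_totals <- state$totals + state$niche$penalty
  weights <- scale_fitness(sel_totals, cfg$scale_bounds)
  pairs <- select_parents(weights, cfg$pop_size / 2)
  children <- character(0)
  for (r in seq_len(nrow(pairs))) {
    p1 <- state$pop[pairs[r, 1]]; p2 <- state$pop[pairs[r, 2]]
    if (runif(1) < cfg$crossover_prob && nchar(p1) >= 2) {
      off <- crossover(p1, p2)
    } else off <- list(p1, p2)
    children <- c(children, mutate(off[[1]], cfg$mutation_rate),
                  mutate(off[[2]], cfg$mutation_rate))
  }
  state$pop <- children
  state$gen <- state$gen + 1L
  state <- evaluate_population(state)

  # elitism: keep the best-so-far genome in the population
  if (!is.na(state$best_genome) && !(state$best_genome %in% state$pop)) {
    worst <- which.max(state$totals + state$niche$penalty)
    state$pop[worst] <- state$best_genome
    state <- refresh_population(state)
  }

  if (cfg$downhill_period > 0 && state$gen %% cfg$downhill_period == 0)
    state <- downhill_phase(state)
  record_gen_best(state)
}

# Re-evaluate the current population without logging a new generation row
# (all fits are cached); used after elitism/downhill population edits.
refresh_population <- function(state) {
  recs <- lapply(state$pop, state$ev$evaluate)
  state$totals <- vapply(recs, `[[`, numeric(1), "total")
  state$niche <- assign_niches(state$pop, state$totals, state$cfg)
  b <- which.min(state$totals)
  if (state$totals[b] < state$best_total) {
    state$best_total <- state$totals[b]
    state$best_genome <- state$pop[b]
  }
  state
}

downhill_phase <- function(state) {
  cfg <- state$cfg
  evaluator <- function(g) state$ev$evaluate(g)$total
  # niche ids are assigned in fitness order, so 1..n_niches are the best
  nids <- seq_len(min(max(state$niche$niche_id), cfg$n_niches))
  for (nid in nids) {
    members <- which(state$niche$niche_id == nid)
    leader <- members[which.min(state$totals[members])]
    res <- downhill_search(state$pop[leader], evaluator,
                           budget = cfg$downhill_budget)
    state$pop[leader] <- res$genome
  }
  refresh_population(state)
}

#' Run the single-objective hybrid genetic algorithm
#'
#' @inheritParams sohga_init
#' @param verbose print a one-line summary per generation.
#' @return An object of class `sohga_run`: the `config`, the full
#'   candidate `records` (one row per candidate per generation, with
#'   decoded digest and fitness components), `per_generation_best`,
#'   the overall `best` candidate (genome, decoded spec, fitness
#'   components, parameter estimates), `best_per_niche` of the final
#'   population, `n_unique_fits` and `elapsed` seconds.
#' @export
run_sohga <- function(space, ds, cfg = ga_config(),
                      settings = estimation_settings(),
                      verbose = FALSE) {
  state <- sohga_init(space, ds, cfg, settings)
  for (gen in seq_len(cfg$generations)) {
    state <- step_generation(state)
    if (verbose)
      message(sprintf(
        "generation %d: best total %.2f (%d unique fits, %.0f s)",
        gen, state$best_total, length(ls(state$ev$cache)),
        proc.time()[["elapsed"]] - state$t0))
  }
  records <- do.call(rbind, state$records)
  pgb <- do.call(rbind, state$gen_best)
  rownames(pgb) <- NULL
  best_rec <- state$ev$evaluate(state$best_genome)
  bpn <- lapply(split(seq_along(state$pop), state$niche$niche_id),
                function(ix) {
                  i <- ix[which.min(state$totals[ix])]
                  list(genome = state$pop[i], total = state$totals[i])
                })
  structure(list(config = cfg, seed = cfg$seed, records = records,
                 per_generation_best = pgb,
                 best = list(genome = state$best_genome,
                             spec = decode(state$best_genome, space),
                             components = best_rec$components,
                             obv = best_rec$obv, params = best_rec$params,
                             total = state$best_total),
                 best_per_niche = bpn,
                 n_unique_fits = length(ls(state$ev$cache)),
                 generations = state$gen,
                 elapsed = proc.time()[["elapsed"]] - state$t0),
            class = "sohga_run")
}

#' @export
print.sohga_run <- function(x, ...) {
  cat("<sohga_run> ", x$generations, " generations, ",
      x$config$pop_size, " candidates/generation, ",
      x$n_unique_fits, " unique fits\n", sep = "")
  cat("best: ", x$best$genome, "\n  ", spec_digest(x$best$spec),
      "\n  OBV ", formatC(x$best$obv, format = "f", digits = 2),
      ", total fitness ", formatC(x$best$total, format = "f", digits = 2),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.sohga_run <- function(object, ...) {
  cat("Per-generation best total fitness:\n")
  print(object$per_generation_best[, c("generation", "total")],
        row.names = FALSE)
  invisible(object$per_generation_best)
}
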