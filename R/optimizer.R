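# Genetic-algorithm search over symmetrized, in-phase activation patterns
# (and optional tendon-length genes) maximizing centre-of-mass height
# within a time limit.  Solutions violating the bone-stress constraint are
# discarded via a sentinel fitness that ranks below every finite value.

DISCARD_SENTINEL <- -1e9

#' Genome layout for a model's activation controller
#'
#' Each actuator contributes `n_phases` duration genes and `n_phases`
#' activation-level genes (piecewise-constant pattern, both limbs
#' implicitly identical and in phase).  With `tendon_genes = TRUE` every
#' uniarticular extensor additionally contributes one tendon-length scale
#' gene bounded to \[0.9, 1.1\].
#'
#' @param model a `jump_model`.
#' @param time_limit simulation (and maximum phase-duration) limit, s.
#' @param n_phases phases per actuator (default 6).
#' @param tendon_genes include tendon-length scale genes.
#' @param min_phase shortest admissible phase duration, s.
#' @return a `genome_spec` with gene bounds and decoding metadata.
#' @export
genome_spec <- function(model, time_limit, n_phases = 6,
                        tendon_genes = FALSE, min_phase = 0.01) {
  na <- length(model$actuators)
  if (!na) stop("model has no actuators to control", call. = FALSE)
  lower <- c(rep(c(rep(min_phase, n_phases), rep(0, n_phases)), na))
  upper <- c(rep(c(rep(time_limit, n_phases), rep(1, n_phases)), na))
  tendon_idx <- integer()
  if (tendon_genes) {
    is_uni_ext <- vapply(model$actuators, function(a)
      length(a$actions) == 1L && identical(a$actions[[1]]$role, "extensor"),
      TRUE)
    tendon_idx <- which(is_uni_ext)
    lower <- c(lower, rep(0.9, length(tendon_idx)))
    upper <- c(upper, rep(1.1, length(tendon_idx)))
  }
  structure(list(n_actuators = na, n_phases = n_phases,
                 tendon_idx = tendon_idx, time_limit = time_limit,
                 lower = lower, upper = upper,
                 n_genes = length(lower)),
            class = "genome_spec")
}

#' Decode a genome into a controller
#'
#' @param spec a [genome_spec()].
#' @param genome numeric vector of length `spec$n_genes`.
#' @return a `jump_controller` (durations, levels, tendon_scale).
#' @export
decode_genome <- function(spec, genome) {
  if (length(genome) != spec$n_genes)
    stop("genome length ", length(genome), " does not match spec (",
         spec$n_genes, ")", call. = FALSE)
  na <- spec$n_actuators; np <- spec$n_phases
  per <- 2 * np
  block <- matrix(genome[seq_len(na * per)], nrow = na, byrow = TRUE)
  durations <- block[, seq_len(np), drop = FALSE]
  levels <- block[, np + seq_len(np), drop = FALSE]
  levels[] <- pmin(1, pmax(0, levels))
  tendon_scale <- rep(1, na)
  if (length(spec$tendon_idx))
    tendon_scale[spec$tendon_idx] <- genome[na * per + seq_along(spec$tendon_idx)]
  structure(list(durations = durations, levels = levels,
                 tendon_scale = tendon_scale), class = "jump_controller")
}

# internal fast evaluator: prebuilt engine + initial state
make_evaluator <- function(model, spec, dt, q0 = NULL) {
  eng <- engine_handle(model)
  if (is.null(q0)) q0 <- initial_state(model)
  qd0 <- rep(0, length(q0))
  na <- spec$n_actuators
  function(genome, record = FALSE, record_dt = 1e-3) {
    ctl <- decode_genome(spec, genome)
    res <- engine_simulate(eng, q0, qd0, ctl$durations, ctl$levels,
                           ctl$tendon_scale, spec$time_limit, dt, record_dt,
                           "semi_implicit", TRUE, record)
    if (record) return(res)
    if (isTRUE(res$blowup)) return(DISCARD_SENTINEL)
    if (isTRUE(res$stress_exceeded) && res$stress_time <= res$t_max_com)
      return(DISCARD_SENTINEL)  # height achieved through skeletal failure
    res$max_com_z
  }
}

#' Fitness of one activation genome
#'
#' Simulates the model under the decoded controller for the spec's time
#' limit and returns the maximum CoM height reached.  Trajectories that
#' exceed a bone failure stress before (or at) the CoM apex -- i.e. whose
#' height was achieved through skeletal failure -- are discarded with a
#' sentinel fitness below every physically attainable value, as are
#' diverged integrations.  A failure during the subsequent fall terminates
#' the simulation but keeps the fitness: the landing phase is outside the
#' optimization objective.
#'
#' @param model a `jump_model`.
#' @param genome numeric genome (see [genome_spec()]).
#' @param spec the matching [genome_spec()].
#' @param dt integration step, s (default from `model$sim`).
#' @return fitness in metres (max CoM height), or the discard sentinel.
#' @export
evaluate_genome <- function(model, genome, spec, dt = NULL) {
  if (is.null(dt)) dt <- model$sim$dt
  make_evaluator(model, spec, dt)(genome)
}

#' Simulate the trajectory of a genome
#'
#' @inheritParams evaluate_genome
#' @param record_dt output sampling interval, s.
#' @return a `jump_trajectory` (see [simulate_jump()]).
#' @export
genome_trajectory <- function(model, genome, spec, dt = NULL,
                              record_dt = 1e-3) {
  if (is.null(dt)) dt <- model$sim$dt
  ctl <- decode_genome(spec, genome)
  simulate_jump(model, ctl, duration = spec$time_limit, dt = dt,
                record_dt = record_dt)
}

#' Genetic algorithm configuration
#'
#' @param population population size (>= 2).
#' @param generations number of generations.
#' @param crossover_rate probability a selected pair recombines (uniform
#'   crossover).
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd Gaussian mutation scale as a fraction of each
#'   gene's range (clipped to bounds).
#' @param mutation_anneal geometric annealing of the mutation scale: the
#'   final-generation scale is `mutation_anneal * mutation_sd` (coarse
#'   exploration early, fine refinement late).
#' @param elitism number of elite genomes copied unchanged (>= 1, making
#'   best fitness monotone non-decreasing).
#' @param seed RNG seed.
#' @param time_limit simulation time limit, s.
#' @param n_phases activation phases per actuator.
#' @param tendon_genes include tendon-length scale genes.
#' @param n_replicates replicate GA runs in [time_limit_sweep()].
#' @param dt integration step override, s.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population = 50, generations = 200,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      mutation_sd = 0.25, mutation_anneal = 0.1,
                      elitism = 1, seed = 1,
                      time_limit = 1, n_phases = 6, tendon_genes = FALSE,
                      n_replicates = 25, dt = NULL) {
  stopifnot(population >= 2, elitism >= 1, generations >= 1)
  structure(list(population = population, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 mutation_anneal = mutation_anneal,
                 elitism = elitism, seed = seed, time_limit = time_limit,
                 n_phases = n_phases, tendon_genes = tendon_genes,
                 n_replicates = n_replicates, dt = dt), class = "ga_config")
}

#' Run the genetic optimization
#'
#' Tournament selection (size 2), uniform crossover, Gaussian mutation
#' clipped to gene bounds, and elitism.  Seeded and fully reproducible:
#' the same configuration and seed give bit-identical results.  Ties in
#' fitness resolve to the lower population index.
#'
#' @param model a `jump_model`; may be NULL when a custom `fitness`
#'   function and `spec` are supplied (surrogate/test mode).
#' @param cfg a [ga_config()].
#' @param fitness optional fitness function `function(genome) -> numeric`
#'   overriding the simulation-based objective.
#' @param spec optional pre-built [genome_spec()].
#' @return list with `best_genome`, `best_fitness`, `history` (data frame
#'   of per-generation best/mean), `spec` and `cfg`.
#' @export
run_ga <- function(model, cfg, fitness = NULL, spec = NULL) {
  if (is.null(spec)) {
    if (is.null(model)) stop("need a model or an explicit genome spec",
                             call. = FALSE)
    spec <- genome_spec(model, time_limit = cfg$time_limit,
                        n_phases = cfg$n_phases,
                        tendon_genes = cfg$tendon_genes)
  }
  if (is.null(fitness)) {
    dt <- if (is.null(cfg$dt)) model$sim$dt else cfg$dt
    fitness <- make_evaluator(model, spec, dt)
  }
  ng <- spec$n_genes
  lo <- spec$lower; hi <- spec$upper; range <- hi - lo
  pop_n <- cfg$population

  set.seed(cfg$seed)
  pop <- matrix(runif(pop_n * ng, rep(lo, each = pop_n), rep(hi, each = pop_n)),
                nrow = pop_n)
  if (length(spec$tendon_idx)) {
    # tendon-scale genes start at the anatomical estimate (scale 1) so the
    # search space is a strict superset of the fixed-tendon problem;
    # deviations must earn their keep through selection
    ti <- spec$n_actuators * 2 * spec$n_phases + seq_along(spec$tendon_idx)
    pop[, ti] <- 1
  }
  fit <- apply(pop, 1, fitness)
  best_hist <- mean_hist <- numeric(cfg$generations)

  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    elite_fit <- fit[ord[seq_len(cfg$elitism)]]

    n_child <- pop_n - cfg$elitism
    # tournament selection, size 2
    pick <- function(k) {
      a <- sample.int(pop_n, k, replace = TRUE)
      b <- sample.int(pop_n, k, replace = TRUE)
      ifelse(fit[a] >= fit[b], a, b)
    }
    p1 <- pick(n_child); p2 <- pick(n_child)
    child <- pop[p1, , drop = FALSE]
    mate <- pop[p2, , drop = FALSE]
    do_cx <- runif(n_child) < cfg$crossover_rate
    take <- matrix(runif(n_child * ng) < 0.5, n_child, ng) & do_cx
    child[take] <- mate[take]
    # Gaussian mutation clipped to bounds, scale annealed geometrically
    anneal <- if (is.null(cfg$mutation_anneal)) 1 else cfg$mutation_anneal
    sd_gen <- cfg$mutation_sd * anneal^(gen / cfg$generations)
    mut <- matrix(runif(n_child * ng) < cfg$mutation_rate, n_child, ng)
    noise <- matrix(rnorm(n_child * ng, sd = sd_gen), n_child, ng) *
      matrix(range, n_child, ng, byrow = TRUE)
    child[mut] <- child[mut] + noise[mut]
    child <- pmin(pmax(child, matrix(lo, n_child, ng, byrow = TRUE)),
                  matrix(hi, n_child, ng, byrow = TRUE))

    child_fit <- apply(child, 1, fitness)
    pop <- rbind(elite, child)
    fit <- c(elite_fit, child_fit)
    best_hist[gen] <- max(fit)
    mean_hist[gen] <- mean(fit[fit > DISCARD_SENTINEL / 2])
  }
  ib <- which.max(fit)
  list(best_genome = pop[ib, ], best_fitness = fit[ib],
       history = data.frame(generation = seq_len(cfg$generations),
                            best = best_hist, mean = mean_hist),
       spec = spec, cfg = cfg)
}

# documented replicate seeding scheme: independent replicate r for limit
# index l uses seed base + 7919 * (l - 1) + 101 * (r - 1)
sweep_seed <- function(base, limit_index, replicate)
  base + 7919L * (limit_index - 1L) + 101L * (replicate - 1L)

#' Time-limit sensitivity sweep
#'
#' Runs `n_replicates` independent GA optimizations (distinct seeds) for
#' each candidate time limit, reports the per-limit best, and flags the
#' performance plateau: the first limit whose best fitness is within
#' `plateau_tol` of the overall maximum.
#'
#' @param model a `jump_model`.
#' @param limits numeric vector of time limits, s.
#' @param cfg a [ga_config()]; `cfg$n_replicates` replicates per limit.
#' @param plateau_tol plateau tolerance, m (default 0.01).
#' @param fitness optional fitness factory `function(time_limit)` ->
#'   fitness function (surrogate/test mode).
#' @param spec optional pre-built [genome_spec()] shared by all runs.
#' @return list with `results` (data frame: limit, best fitness per
#'   replicate summary), `best_per_limit`, `plateau_limit`, and the best
#'   run overall.
#' @export
time_limit_sweep <- function(model, limits, cfg, plateau_tol = 0.01,
                             fitness = NULL, spec = NULL) {
  stopifnot(length(limits) >= 1, cfg$n_replicates >= 1)
  rows <- list(); best_run <- NULL; best_val <- -Inf
  for (li in seq_along(limits)) {
    for (r in seq_len(cfg$n_replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- sweep_seed(cfg$seed, li, r)
      cfg_r$time_limit <- limits[li]
      fit_fn <- if (is.null(fitness)) NULL else fitness(limits[li])
      run <- run_ga(model, cfg_r, fitness = fit_fn, spec = spec)
      rows[[length(rows) + 1L]] <-
        data.frame(time_limit = limits[li], replicate = r,
                   seed = cfg_r$seed, best_fitness = run$best_fitness)
      if (run$best_fitness > best_val) {
        best_val <- run$best_fitness
        best_run <- run
      }
    }
  }
  results <- do.call(rbind, rows)
  best_per_limit <- vapply(limits, function(L)
    max(results$best_fitness[results$time_limit == L]), 0)
  plateau_limit <- limits[which(best_per_limit >= max(best_per_limit) -
                                  plateau_tol)[1]]
  list(results = results, best_per_limit = setNames(best_per_limit,
                                                    as.character(limits)),
       plateau_limit = plateau_limit, best_run = best_run)
}
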