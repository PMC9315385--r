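#' Genetic-algorithm configuration
#'
#' Operator table and run settings for the synergy search: two-point
#' crossover (probability 0.5), per-individual mutation (probability 0.2)
#' flipping each gene independently with probability 0.05, and tournament
#' selection of size 3.  Population size and generation count are run
#' settings with defaults chosen so convergence around generation 20 is
#' observable with headroom.
#'
#' @param population_size Individuals per generation.
#' @param generations Maximum number of generations.
#' @param crossover_probability Per-pair crossover probability.
#' @param mutation_probability Per-individual mutation probability.
#' @param independent_gene_probability Per-gene flip probability within a
#'   mutation.
#' @param tournament_size Tournament size (>= 2).
#' @param seed Integer root seed for the whole run.
#' @param fitness_stop Early-stop fitness threshold.
#' @param mutation `"flip"` (gene `g -> 1 - g`, the continuous analogue of
#'   a bit flip) or `"uniform"` (resample the gene uniformly in `[0, 1]`).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L,
                      generations = 40L,
                      crossover_probability = 0.5,
                      mutation_probability = 0.2,
                      independent_gene_probability = 0.05,
                      tournament_size = 3L,
                      seed = 1L,
                      fitness_stop = 0.9999,
                      mutation = c("flip", "uniform")) {
  assert_scalar_num(population_size, "population_size", lower = 2)
  assert_scalar_num(generations, "generations", lower = 0)
  for (p in c("crossover_probability", "mutation_probability",
              "independent_gene_probability"))
    assert_scalar_num(get(p), p, lower = 0, upper = 1)
  assert_scalar_num(tournament_size, "tournament_size", lower = 2,
                    upper = population_size)
  assert_scalar_num(seed, "seed")
  assert_scalar_num(fitness_stop, "fitness_stop", lower = -1, upper = 1)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_probability = crossover_probability,
         mutation_probability = mutation_probability,
         independent_gene_probability = independent_gene_probability,
         tournament_size = as.integer(tournament_size),
         seed = as.integer(seed),
         fitness_stop = fitness_stop,
         mutation = match.arg(mutation)),
    class = "ga_config")
}

#' Torque-matching task for the synergy search
#'
#' Holds the reference counter torque (measured from EMG-derived
#' activations with [balancing_torque()]), the target knee angle and the
#' model.  During evolution the counter torque is held constant and each
#' individual is settled from the target angle, so an individual whose
#' muscle-driven torque equals the reference settles exactly at the target.
#'
#' @param target_angle Target knee angle in degrees.
#' @param reference_torque Reference counter torque magnitude in N m
#'   (nonnegative).
#' @param model A [knee_model()].
#' @param settle_method Settle path used in fitness evaluation.
#' @return An object of class `evolution_task`.
#' @export
evolution_task <- function(target_angle, reference_torque, model,
                           settle_method = c("static", "dynamic")) {
  stopifnot(inherits(model, "knee_model"))
  assert_scalar_num(reference_torque, "reference_torque", lower = 0)
  lo <- model$limb$range_deg[1]; hi <- model$limb$range_deg[2]
  assert_scalar_num(target_angle, "target_angle", lower = lo, upper = hi)
  structure(
    list(target_angle = target_angle,
         reference_torque = reference_torque,
         model = model,
         settle_method = match.arg(settle_method)),
    class = "evolution_task")
}

## cos of the (capped) angular mismatch, in radians.
angle_fitness <- function(a_current, a_target) {
  cos(min(abs(a_current - a_target) * pi / 180, pi))
}

#' Fitness of an activation individual
#'
#' Settles the limb under the individual's activations with the task's
#' reference counter torque applied opposing extension, starting at the
#' target angle, and returns `cos(|a_current - a_target|)` with the angle
#' difference in radians, capped at pi.  Fitness is 1 exactly when the
#' settled angle equals the target.
#'
#' @param genes 7 activation genes in `[0, 1]`.
#' @param task An [evolution_task()].
#' @return Scalar fitness in `[-1, 1]`.
#' @export
ga_fitness <- function(genes, task) {
  stopifnot(inherits(task, "evolution_task"))
  s <- settle(genes, task$model,
              external_torque = task$reference_torque,
              state = model_state(task$target_angle),
              method = task$settle_method)
  angle_fitness(s$angle, task$target_angle)
}

#' Two-point crossover
#'
#' Chooses two distinct cut points and swaps the middle gene segment
#' between the parents.
#'
#' @param parent1,parent2 Gene vectors of equal length.
#' @param cuts Optional integer cut points `c(i, j)` with
#'   `0 <= i < j <= length(genes)` (gene positions after which to cut);
#'   drawn uniformly when `NULL`.
#' @return List with `child1` and `child2`.
#' @export
two_point_crossover <- function(parent1, parent2, cuts = NULL) {
  n <- length(parent1)
  stopifnot(length(parent2) == n, n >= 2)
  if (is.null(cuts)) cuts <- sort(sample.int(n + 1L, 2L) - 1L)
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2],
            cuts[1] >= 0, cuts[2] <= n)
  seg <- (cuts[1] + 1L):cuts[2]
  c1 <- parent1; c2 <- parent2
  c1[seg] <- parent2[seg]
  c2[seg] <- parent1[seg]
  list(child1 = c1, child2 = c2)
}

#' Gene mutation
#'
#' Each gene independently, with probability `indpb`, is flipped to
#' `1 - gene` (the continuous analogue of a bit flip, keeping genes in
#' `[0, 1]`), or resampled uniformly when `method = "uniform"`.
#'
#' @param genes Gene vector in `[0, 1]`.
#' @param indpb Per-gene mutation probability.
#' @param method `"flip"` or `"uniform"`.
#' @return Mutated gene vector.
#' @export
mutate_genes <- function(genes, indpb = 0.05, method = c("flip", "uniform")) {
  method <- match.arg(method)
  hit <- stats::runif(length(genes)) < indpb
  if (any(hit)) {
    genes[hit] <- switch(method,
                         flip = 1 - genes[hit],
                         uniform = stats::runif(sum(hit)))
  }
  genes
}

#' Tournament selection
#'
#' Each selection draws `tournament_size` individuals uniformly with
#' replacement and keeps the fittest; ties resolve to the lowest
#' population index.
#'
#' @param population Matrix `[individuals x genes]`.
#' @param fitnesses Fitness per individual.
#' @param tournament_size Tournament size.
#' @param n_select Number of individuals to select.
#' @return Integer vector of selected row indices (length `n_select`).
#' @export
tournament_select <- function(population, fitnesses, tournament_size = 3L,
                              n_select = nrow(population)) {
  npop <- nrow(population)
  stopifnot(npop >= 1L, tournament_size <= npop,
            length(fitnesses) == npop)
  vapply(seq_len(n_select), function(i) {
    cand <- sort(sample.int(npop, tournament_size, replace = TRUE))
    cand[which.max(fitnesses[cand])]
  }, integer(1))
}

#' Scale an individual so its maximal gene becomes 1
#'
#' Divides all genes by the maximum so the configuration represents
#' maximal voluntary effort: the largest activation becomes 1 and the
#' others increase proportionally.
#'
#' @param genes Gene vector with at least one positive entry.
#' @return Scaled gene vector with `max == 1`.
#' @export
scale_to_max <- function(genes) {
  m <- max(genes)
  if (m <= 0) stopf("cannot scale: all genes are zero")
  genes / m
}

#' Evolve an activation pattern matching a reference torque
#'
#' Generational genetic algorithm over 7-gene activation vectors: evaluate,
#' tournament-select, pair-wise two-point crossover, per-individual gene
#' mutation, re-evaluating only modified offspring.  Runs until the
#' generation limit or until the best fitness reaches
#' `config$fitness_stop`.  Fully reproducible from `config$seed`.
#'
#' @param task An [evolution_task()].
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best` (genes), `best_scaled`
#'   (max-scaled genes), `best_fitness`, `fitness_trajectory` (best-so-far
#'   per generation, index 0 = initial population), `converged_generation`
#'   (first generation reaching `fitness_stop`, `NA` if never),
#'   `evaluations`, `generations_run`, `seed` and the config echo.
#' @export
evolve <- function(task, config = ga_config()) {
  stopifnot(inherits(task, "evolution_task"), inherits(config, "ga_config"))
  npop <- config$population_size
  ngenes <- 7L
  with_seed(config$seed, {
    pop <- matrix(stats::runif(npop * ngenes), npop, ngenes)
    fit <- apply(pop, 1L, ga_fitness, task = task)
    nev <- npop
    best_i <- which.max(fit)
    best <- pop[best_i, ]
    best_fit <- fit[best_i]
    traj <- best_fit
    conv <- if (best_fit >= config$fitness_stop) 0L else NA_integer_
    gens <- 0L

    for (g in seq_len(config$generations)) {
      if (!is.na(conv)) break
      idx <- tournament_select(pop, fit, config$tournament_size, npop)
      off <- pop[idx, , drop = FALSE]
      ofit <- fit[idx]
      mod <- rep(FALSE, npop)
      for (i in seq(1L, npop - 1L, by = 2L)) {
        if (stats::runif(1) < config$crossover_probability) {
          ch <- two_point_crossover(off[i, ], off[i + 1L, ])
          off[i, ] <- ch$child1
          off[i + 1L, ] <- ch$child2
          mod[c(i, i + 1L)] <- TRUE
        }
      }
      for (i in seq_len(npop)) {
        if (stats::runif(1) < config$mutation_probability) {
          mutated <- mutate_genes(off[i, ],
                                  config$independent_gene_probability,
                                  config$mutation)
          if (!identical(mutated, off[i, ])) {
            off[i, ] <- mutated
            mod[i] <- TRUE
          }
        }
      }
      for (i in which(mod)) {
        ofit[i] <- ga_fitness(off[i, ], task)
        nev <- nev + 1L
      }
      pop <- off
      fit <- ofit
      gens <- g
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best <- pop[gi, ]
      }
      traj <- c(traj, best_fit)
      if (is.na(conv) && best_fit >= config$fitness_stop) conv <- g
    }

    structure(
      list(best = best,
           best_scaled = scale_to_max(best),
           best_fitness = best_fit,
           fitness_trajectory = traj,
           converged_generation = conv,
           evaluations = nev,
           generations_run = gens,
           seed = config$seed,
           config = config,
           task = list(target_angle = task$target_angle,
                       reference_torque = task$reference_torque)),
      class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.6f after %d generations (%d evaluations)\n",
              x$best_fitness, x$generations_run, x$evaluations))
  cat(sprintf("  converged at generation: %s\n",
              if (is.na(x$converged_generation)) "never"
              else x$converged_generation))
  cat("  best (max-scaled): ",
      paste(sprintf("%s=%.3f", knee_muscles, x$best_scaled), collapse = " "),
      "\n")
  invisible(x)
}
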