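#' Genetic algorithm and line-of-descent tracing
#'
#' Populations of 100 animats adapt by roulette-wheel selection on the
#' exponential score \eqn{S = 1.02^{F \cdot 128}} (each correct trial
#' multiplies the score by 1.02), followed by mutation of every selected
#' genome. Reproduction is asexual and without elitism, so each animat in
#' the final generation has a unique line of descent (LOD) back to
#' generation 0; different picks coalesce quickly.
#'
#' @param population_size Number of animats per generation.
#' @param generations Number of generations to evolve.
#' @param selection_base Base of the exponential fitness score.
#' @param mutation A [mutation_config()].
#' @param lod_sample_interval Spacing (in generations) of population
#'   snapshots kept for line-of-descent reconstruction and of the sampled
#'   LOD records.
#' @param genome_length Length of the ancestral (all-zero) genomes.
#' @return An `evolution_config` object.
#' @export
evolution_config <- function(population_size = 100L, generations = 1000L,
                             selection_base = 1.02,
                             mutation = mutation_config(),
                             lod_sample_interval = 512L,
                             genome_length = 5000L) {
  if (population_size < 2) stop("population_size must be at least 2")
  if (selection_base <= 1) stop("selection_base must exceed 1")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 selection_base = selection_base,
                 mutation = mutation,
                 lod_sample_interval = as.integer(lod_sample_interval),
                 genome_length = as.integer(genome_length)),
            class = "evolution_config")
}

#' Run one generation of selection and mutation
#'
#' @param population List of genomes.
#' @param task A [task_spec()].
#' @param config An [evolution_config()].
#' @param fitness Optional precomputed vector of per-animat fitness F; if
#'   missing, every genome is evaluated on the task.
#' @return List with `population` (mutated offspring), `parents` (1-based
#'   parent index per offspring) and `fitness` (of the parent generation).
#' @export
step_generation <- function(population, task, config = evolution_config(),
                            fitness = NULL) {
  stopifnot(inherits(task, "task_spec"))
  if (is.null(fitness)) {
    fitness <- vapply(population, function(g) {
      evaluate_brain(build_brain(decode_genome(g)), task)$F
    }, numeric(1))
  }
  s <- config$selection_base^(fitness * 128)
  u <- stats::runif(config$population_size) * sum(s)
  parents <- findInterval(u, cumsum(s)) + 1L
  parents[parents > length(population)] <- length(population)
  offspring <- lapply(parents, function(i)
    mutate_genome(population[[i]], config$mutation))
  list(population = offspring, parents = parents, fitness = fitness)
}

#' Run an evolutionary experiment
#'
#' Starts from a population of connectionless ancestral genomes and evolves
#' for the configured number of generations. The returned archive records
#' per-generation fitness and parent indices for every animat and full
#' genome snapshots every `lod_sample_interval` generations (plus the final
#' generation), which suffices to trace any final animat's line of descent.
#' All randomness comes from R's stream; call [set.seed()] first for a
#' reproducible run.
#'
#' @param task A [task_spec()].
#' @param config An [evolution_config()].
#' @return An `evolution_archive`: list with `fitness` (matrix, generations
#'   + 1 rows), `parents` (matrix), `snapshot_generations`, `snapshots`
#'   (list of genome lists), `task` and `config`.
#' @export
run_evolution <- function(task, config = evolution_config()) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "evolution_config"))
  m <- config$mutation
  res <- cpp_run_evolution(unclass(task), config$generations,
                           config$population_size, config$selection_base,
                           config$genome_length,
                           m$point_rate, m$deletion_prob, m$duplication_prob,
                           m$fragment_len_range[1], m$fragment_len_range[2],
                           m$genome_len_range[1], m$genome_len_range[2],
                           config$lod_sample_interval)
  structure(list(fitness = res$fitness, parents = res$parents,
                 snapshot_generations = res$snapshot_generations,
                 snapshots = res$snapshots,
                 task = task, config = config),
            class = "evolution_archive")
}

#' @export
print.evolution_archive <- function(x, ...) {
  g <- nrow(x$fitness) - 1
  cat(sprintf("evolution_archive: %d generations, population %d, task %d\n",
              g, ncol(x$fitness), x$task$task))
  cat(sprintf("  final mean fitness: %.3f (max %.3f)\n",
              mean(x$fitness[g + 1, ]), max(x$fitness[g + 1, ])))
  invisible(x)
}

#' Trace a line of descent
#'
#' Follows parent indices backwards from an animat in the final generation
#' and returns one record per archived (snapshot) generation.
#'
#' @param archive An `evolution_archive` from [run_evolution()].
#' @param pick Index of the final-generation animat to trace (the choice is
#'   nearly immaterial: lines of descent coalesce within few generations).
#' @return List of `lod_record`s: each has `generation`, `genome`,
#'   `fitness`, and `index` (position within its generation).
#' @export
trace_lod <- function(archive, pick = 1L) {
  stopifnot(inherits(archive, "evolution_archive"))
  gens <- nrow(archive$fitness) - 1L
  idx <- integer(gens + 1L)
  idx[gens + 1L] <- as.integer(pick)
  if (gens > 0) {
    for (g in gens:1) {
      p <- archive$parents[g, idx[g + 1L]]
      if (is.na(p) || p < 1 || p > ncol(archive$fitness))
        stop("archive integrity error: broken parent chain at generation ", g)
      idx[g] <- p
    }
  }
  lapply(seq_along(archive$snapshot_generations), function(k) {
    g <- archive$snapshot_generations[k]
    i <- idx[g + 1L]
    structure(list(generation = g,
                   genome = archive$snapshots[[k]][[i]],
                   fitness = archive$fitness[g + 1L, i],
                   index = i),
              class = "lod_record")
  })
}
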