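# Genetic-algorithm wrapper feature selection.
#
# A chromosome is a fixed-length set of distinct feature (column) indices;
# its fitness is the training mean squared error of the least-squares linear
# discriminant restricted to those features (lower is fitter). Each
# generation: rank the population by fitness, keep the top `parent_fraction`
# as parents, carry the best `elitism` individuals unchanged, refill the
# population by uniform random crossover of parent pairs, then mutate a
# fixed share of the non-elite gene slots. The search runs a fixed number of
# generations and returns the best chromosome ever seen.

#' Genetic-algorithm configuration
#'
#' Defaults follow the study's search settings: chromosome length 8,
#' population of 10 x L individuals, ranking selection of the best 10%,
#' mutation of 1% of the (non-elite) genes per generation, 100 generations.
#' Elitism (1 individual carried unchanged) is added so that best-so-far
#' fitness is non-increasing; set `elitism = 0` to disable.
#'
#' @param chromosome_length Number of features per chromosome (L).
#' @param population_size Number of chromosomes; default `10 * L`.
#' @param parent_fraction Fraction of the population kept as parents.
#' @param mutation_rate Fraction of non-elite gene slots mutated per
#'   generation.
#' @param generations Number of generations.
#' @param elitism Number of best individuals copied unchanged each
#'   generation.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(chromosome_length = 8,
                      population_size = NULL,
                      parent_fraction = 0.10,
                      mutation_rate = 0.01,
                      generations = 100,
                      elitism = 1,
                      seed = 1) {
  population_size_fixed <- !is.null(population_size)
  population_size <- population_size %||% (10L * chromosome_length)
  if (!is_count(chromosome_length)) stop_ganest("invalid chromosome_length")
  if (!is_count(population_size, min = 2)) {
    stop_ganest("population_size must be >= 2")
  }
  if (parent_fraction <= 0 || parent_fraction > 1) {
    stop_ganest("parent_fraction must be in (0, 1]")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop_ganest("mutation_rate must be in [0, 1]")
  }
  if (!is_count(generations) || !is_count(elitism, min = 0)) {
    stop_ganest("invalid generations/elitism")
  }
  structure(list(chromosome_length = as.integer(chromosome_length),
                 population_size = as.integer(population_size),
                 parent_fraction = parent_fraction,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 population_size_fixed = population_size_fixed,
                 seed = seed),
            class = "ga_config")
}

.check_chromosome <- function(genes, D, L) {
  length(genes) == L && !anyDuplicated(genes) &&
    all(genes >= 1) && all(genes <= D)
}

#' Initialize a random population of chromosomes
#'
#' Each chromosome is a uniform random subset of `config$chromosome_length`
#' distinct feature indices from `1:D`.
#'
#' @param D Total number of features.
#' @param config A [ga_config()]; its `seed` drives the draw.
#' @return A list of integer vectors.
#' @export
init_population <- function(D, config) {
  L <- config$chromosome_length
  if (L > D) stop_ganest("chromosome length ", L, " exceeds feature count ", D)
  set.seed(config$seed)
  replicate(config$population_size, sample.int(D, L), simplify = FALSE)
}

#' Chromosome fitness: training MSE of the LSLD on its features
#'
#' Lower is fitter. Equals `fit_lsld(X[, genes], y)$training_mse` and is
#' invariant to gene order.
#'
#' @param chromosome Integer vector of distinct column indices.
#' @param X_train,y_train Training rows and +/-1 labels.
#' @return Mean squared error (single numeric).
#' @export
ga_fitness <- function(chromosome, X_train, y_train) {
  if (any(chromosome < 1) || any(chromosome > ncol(X_train))) {
    stop_ganest("chromosome index out of range")
  }
  .lsld_core(X_train[, chromosome, drop = FALSE], y_train)$mse
}

#' Ranking selection of the parent pool
#'
#' Returns the `ceiling(parent_fraction * population_size)` chromosomes with
#' lowest MSE; ties are broken by stable population order.
#'
#' @param population List of chromosomes.
#' @param fitnesses Fitness (MSE) per individual.
#' @param config A [ga_config()].
#' @return List of parent chromosomes (best first).
#' @export
select_parents <- function(population, fitnesses, config) {
  if (!length(population)) stop_ganest("empty population")
  m <- ceiling(config$parent_fraction * length(population))
  population[order(fitnesses)[seq_len(m)]] # order() is stable on ties
}

#' Uniform random crossover of two chromosomes
#'
#' Each gene position is inherited from either parent with equal
#' probability; duplicate genes are repaired by resampling from the
#' unused union of both parents' genes (always sufficient, since each parent
#' already holds L distinct genes; a full-feature fallback is kept for
#' safety when `D` is supplied).
#'
#' @param parent_a,parent_b Chromosomes of equal length.
#' @param D Optional total feature count enabling the fallback repair pool.
#' @return A child chromosome with distinct genes.
#' @export
crossover <- function(parent_a, parent_b, D = NULL) {
  L <- length(parent_a)
  if (length(parent_b) != L) stop_ganest("parent length mismatch")
  pick <- stats::runif(L) < 0.5
  child <- ifelse(pick, parent_a, parent_b)
  dup <- duplicated(child)
  if (any(dup)) {
    pool <- setdiff(union(parent_a, parent_b), child[!dup])
    if (length(pool) < sum(dup) && !is.null(D)) {
      pool <- union(pool, setdiff(seq_len(D), child[!dup]))
    }
    child[dup] <- pool[sample.int(length(pool), sum(dup))]
  }
  as.integer(child)
}

#' Mutate a population
#'
#' Picks exactly `round(mutation_rate * total gene slots)` slots uniformly
#' without replacement across the whole population passed in (the caller
#' excludes elites), and replaces each with a uniform random feature not
#' currently in that chromosome. A chromosome already containing every
#' feature (`L = D`) is left unchanged.
#'
#' @param population List of chromosomes (non-elite individuals).
#' @param D Total feature count.
#' @param config A [ga_config()] (uses `mutation_rate`).
#' @return The mutated population.
#' @export
mutate_population <- function(population, D, config) {
  if (!length(population)) return(population)
  L <- length(population[[1]])
  total <- length(population) * L
  m <- round(config$mutation_rate * total)
  # a positive rate always mutates at least one slot, otherwise small
  # populations (round(rate * total) = 0) would lose exploration entirely
  if (m == 0 && config$mutation_rate > 0) m <- 1L
  if (m == 0 || total == 0) return(population)
  slots <- sample.int(total, m)
  saturated <- FALSE
  for (s in slots) {
    i <- ((s - 1L) %/% L) + 1L
    p <- ((s - 1L) %% L) + 1L
    candidates <- setdiff(seq_len(D), population[[i]])
    if (!length(candidates)) { # saturated chromosome: nothing to mutate to
      saturated <- TRUE
      next
    }
    population[[i]][p] <- sample_one(candidates)
  }
  if (saturated) {
    message("mutation skipped on saturated chromosome(s) (L = D)")
  }
  population
}

#' Run the genetic algorithm on a training partition
#'
#' @param X_train Training feature matrix (rows = subjects).
#' @param y_train +/-1 labels or an `outcome_labels` object.
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `best_chromosome`, `best_fitness`,
#'   and `history` (data.frame with per-generation best fitness and
#'   best-so-far fitness; generation 0 is the initial population).
#' @export
run_ga <- function(X_train, y_train, config = ga_config()) {
  X_train <- as.matrix(X_train)
  if (inherits(y_train, "outcome_labels")) y_train <- labels_pm1(y_train)
  if (length(unique(y_train)) < 2) stop_ganest("training labels single-class")
  D <- ncol(X_train)
  L <- config$chromosome_length
  pop <- init_population(D, config) # also seeds the generation loop below
  fit <- vapply(pop, ga_fitness, numeric(1), X_train, y_train)

  best_idx <- which.min(fit)
  best_chrom <- pop[[best_idx]]
  best_fit <- fit[best_idx]
  hist_gen <- data.frame(generation = 0L, best_fitness = best_fit,
                         best_so_far = best_fit)

  n_elite <- min(config$elitism, config$population_size)
  n_child <- config$population_size - n_elite
  for (g in seq_len(config$generations)) {
    parents <- select_parents(pop, fit, config)
    ord <- order(fit)
    elite_idx <- ord[seq_len(n_elite)]
    children <- vector("list", n_child)
    if (n_child > 0) {
      pair <- matrix(sample.int(length(parents), 2 * n_child, replace = TRUE),
                     ncol = 2)
      for (j in seq_len(n_child)) {
        children[[j]] <- crossover(parents[[pair[j, 1]]],
                                   parents[[pair[j, 2]]], D = D)
      }
      children <- mutate_population(children, D, config)
    }
    child_fit <- vapply(children, ga_fitness, numeric(1), X_train, y_train)
    pop <- c(pop[elite_idx], children)
    fit <- c(fit[elite_idx], child_fit)
    stopifnot(all(vapply(pop, .check_chromosome, logical(1), D, L)))

    gen_best <- which.min(fit)
    if (fit[gen_best] < best_fit) {
      best_fit <- fit[gen_best]
      best_chrom <- pop[[gen_best]]
    }
    hist_gen <- rbind(hist_gen,
                      data.frame(generation = g, best_fitness = fit[gen_best],
                                 best_so_far = best_fit))
  }
  structure(list(best_chromosome = sort(best_chrom),
                 best_fitness = best_fit,
                 history = hist_gen,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best MSE %.4g after %d generations; genes: %s\n",
              x$best_fitness, max(x$history$generation),
              paste(x$best_chromosome, collapse = ", ")))
  invisible(x)
}

#' Export a GA history as a delimited table
#'
#' @param result A [run_ga()] result.
#' @param path Output path.
#' @param feature_names Optional feature names used to spell out the final
#'   chromosome in a trailing comment-free column set.
#' @return Invisibly, `path`.
#' @export
write_ga_history <- function(result, path, feature_names = NULL) {
  h <- result$history
  genes <- if (is.null(feature_names)) {
    paste(result$best_chromosome, collapse = ";")
  } else {
    paste(feature_names[result$best_chromosome], collapse = ";")
  }
  h$final_chromosome <- genes
  data.table::fwrite(h, path)
  invisible(path)
}
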