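test_that("population initialization respects size, bounds and determinism", {
  cfg <- ga_config(chromosome_length = 8)
  pop <- init_population(100, cfg)
  expect_length(pop, 80) # 10 x L
  for (ch in pop) expect_valid_chromosome(ch, 100, 8)

  expect_identical(init_population(100, cfg), init_population(100, cfg))

  # L = D forces the full feature set
  cfg2 <- ga_config(chromosome_length = 5, population_size = 4)
  pop2 <- init_population(5, cfg2)
  for (ch in pop2) expect_setequal(ch, 1:5)

  expect_error(init_population(4, cfg2), "exceeds")
})

test_that("fitness equals LSLD training MSE and ignores gene order", {
  coh <- tiny_cohort(d = 10, planted = c(2, 7), effect = 2, seed = 3)
  X <- coh$table$values
  y <- ifelse(coh$labels$improver, 1, -1)
  chrom <- c(2, 7, 4)
  expect_equal(ga_fitness(chrom, X, y),
               fit_lsld(X[, chrom], y)$training_mse)
  expect_equal(ga_fitness(c(4, 2, 7), X, y), ga_fitness(c(7, 4, 2), X, y))
  expect_error(ga_fitness(c(1, 99), X, y), "out of range")

  # constant features only: balanced labels give MSE 1 under the
  # minimum-norm fit (w = 0, b = 0)
  Xc <- matrix(1, 20, 3)
  yb <- rep(c(-1, 1), 10)
  expect_equal(ga_fitness(c(1, 3), Xc, yb), 1)

  # an interpolating feature gives MSE 0
  Xp <- cbind(yb, rnorm(20))
  expect_equal(ga_fitness(1, Xp, yb), 0)
})

test_that("ranking selection takes the fittest fraction with stable ties", {
  cfg <- ga_config(chromosome_length = 2, population_size = 80)
  pop <- init_population(200, cfg)
  fit <- seq(0.8, 0.01, length.out = 80)
  parents <- select_parents(pop, fit, cfg)
  expect_length(parents, 8) # 10% of 80
  expect_identical(parents[[1]], pop[[80]]) # lowest MSE first

  # all-equal fitness: stable population order
  parents_tie <- select_parents(pop, rep(0.5, 80), cfg)
  expect_identical(parents_tie, pop[1:8])

  cfg$parent_fraction <- 1
  expect_length(select_parents(pop, fit, cfg), 80)
  expect_error(select_parents(list(), numeric(0), cfg), "empty")
})

test_that("crossover inherits from both parents and repairs duplicates", {
  set.seed(5)
  a <- 1:8
  b <- 9:16
  seen <- integer(0)
  for (i in 1:200) {
    child <- crossover(a, b, D = 20)
    expect_valid_chromosome(child, 16, 8)
    expect_true(all(child %in% union(a, b)))
    seen <- union(seen, child)
  }
  expect_setequal(seen, 1:16) # every union gene eventually appears

  expect_identical(crossover(a, a), a) # identical parents reproduce exactly
  expect_error(crossover(1:3, 1:4), "mismatch")

  # heavy overlap forces duplicate repair
  for (i in 1:100) {
    child <- crossover(c(1, 2, 3), c(3, 2, 9), D = 10)
    expect_valid_chromosome(child, 10, 3)
  }
})

test_that("mutation changes the specified number of gene slots", {
  cfg <- ga_config(chromosome_length = 8, population_size = 80,
                   mutation_rate = 0.01, seed = 1)
  pop <- init_population(500, cfg)
  mutated <- mutate_population(pop, 500, cfg)
  changed <- sum(mapply(function(a, b) sum(a != b), pop, mutated))
  expect_equal(changed, 6) # round(0.01 * 640)
  for (ch in mutated) expect_valid_chromosome(ch, 500, 8)

  cfg0 <- ga_config(chromosome_length = 8, mutation_rate = 0)
  expect_identical(mutate_population(pop, 500, cfg0), pop)

  # saturated chromosomes (L = D) cannot mutate
  cfgs <- ga_config(chromosome_length = 4, population_size = 4,
                    mutation_rate = 1)
  pops <- init_population(4, cfgs)
  expect_message(muts <- mutate_population(pops, 4, cfgs), "saturated")
  expect_identical(muts, pops)
})

test_that("a positive mutation rate always explores at least one slot", {
  cfg <- ga_config(chromosome_length = 2, population_size = 10,
                   mutation_rate = 0.01, seed = 2)
  pop <- init_population(50, cfg)
  mutated <- mutate_population(pop, 50, cfg)
  changed <- sum(mapply(function(a, b) sum(a != b), pop, mutated))
  expect_equal(changed, 1) # round(0.01 * 20) = 0 is floored to 1
})

test_that("the GA recovers the exhaustive optimum on a small instance", {
  set.seed(42)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- ifelse(X[, 3] - X[, 7] + rnorm(40, 0, 0.5) > 0, 1, -1)
  ga <- run_ga(X, y, ga_config(chromosome_length = 2, seed = 9))
  combos <- utils::combn(10, 2)
  exhaustive <- apply(combos, 2, ga_fitness, X, y)
  expect_equal(ga$best_fitness, min(exhaustive))
  expect_setequal(ga$best_chromosome,
                  combos[, which.min(exhaustive)])
})

test_that("best-so-far fitness is non-increasing with elitism", {
  coh <- tiny_cohort(d = 15, planted = c(1, 5), seed = 13)
  X <- coh$table$values
  y <- ifelse(coh$labels$improver, 1, -1)
  for (s in 1:5) {
    ga <- run_ga(X, y, ga_config(chromosome_length = 4, seed = s,
                                 generations = 30))
    expect_true(all(diff(ga$history$best_so_far) <= 0))
    expect_true(all(diff(ga$history$best_fitness) <= 0)) # elite retained
  }
})

test_that("GA runs are deterministic and degenerate cases converge", {
  coh <- tiny_cohort(d = 8, planted = 1, seed = 2)
  X <- coh$table$values
  y <- ifelse(coh$labels$improver, 1, -1)
  cfg <- ga_config(chromosome_length = 3, generations = 10, seed = 77)
  g1 <- run_ga(X, y, cfg)
  g2 <- run_ga(X, y, cfg)
  expect_identical(g1$history, g2$history)
  expect_identical(g1$best_chromosome, g2$best_chromosome)

  # L = D: only one chromosome exists; converged at generation 0
  cfgd <- ga_config(chromosome_length = 8, population_size = 4,
                    generations = 3, seed = 1)
  gd <- run_ga(X, y, cfgd)
  expect_setequal(gd$best_chromosome, 1:8)
  expect_equal(gd$best_fitness, gd$history$best_fitness[1])
})

test_that("feature relabelling maps the selected optimum accordingly", {
  set.seed(8)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- ifelse(X[, 2] + X[, 9] + rnorm(50, 0, 0.4) > 0, 1, -1)
  perm <- c(4, 7, 1, 10, 2, 8, 3, 6, 9, 5) # column j moves to position perm[j]
  Xp <- X
  Xp[, perm] <- X
  g <- run_ga(X, y, ga_config(chromosome_length = 2, seed = 3))
  gp <- run_ga(Xp, y, ga_config(chromosome_length = 2, seed = 3))
  expect_setequal(gp$best_chromosome, perm[g$best_chromosome])
})

test_that("GA history exports as a delimited table", {
  coh <- tiny_cohort(d = 6, planted = 1, seed = 4)
  y <- ifelse(coh$labels$improver, 1, -1)
  g <- run_ga(coh$table$values, y,
              ga_config(chromosome_length = 2, generations = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ga_history(g, path, feature_names = coh$table$schema$feature_names)
  h <- read.csv(path)
  expect_equal(nrow(h), 6) # generation 0 plus 5
  expect_true(all(c("generation", "best_fitness", "best_so_far") %in% names(h)))
})
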