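# Shared fixtures, built in code.

# a small generic schema for fast cohort tests
tiny_schema <- function(d = 12) {
  build_schema("clinical", clinical_names = sprintf("var%02d", seq_len(d)))
}

tiny_cohort <- function(d = 12, planted = integer(0), effect = 1.5,
                        n1 = 22, n0 = 32, seed = 1, rho = 0.3) {
  generate_cohort(cohort_config(tiny_schema(d), n_improvers = n1,
                                n_nonimprovers = n0,
                                planted_features = planted,
                                effect_size = effect,
                                block_correlation = rho, seed = seed))
}

# scaled-down GA settings used throughout the suite
quick_ga <- function(...) {
  args <- list(...)
  if (is.null(args$population_size)) args$population_size <- 40
  if (is.null(args$generations)) args$generations <- 20
  do.call(ga_config, args)
}

# linearly separable toy classification set
toy_separable <- function(n = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n, 2)
  y <- ifelse(x[, 1] > 0, 1, -1)
  x[, 1] <- x[, 1] + y # widen the margin
  list(x = x, y = y)
}

expect_valid_chromosome <- function(genes, D, L) {
  expect_length(genes, L)
  expect_false(any(duplicated(genes)))
  expect_true(all(genes >= 1 & genes <= D))
}
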