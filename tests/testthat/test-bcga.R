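test_that("initial chromosomes carry set-bit counts from the configured range", {
  cfg <- ga_config(population_size = 50, init_gene_range = c(20, 200))
  pop <- init_population(500, cfg, seed = 4)
  counts <- vapply(pop, sum, numeric(1))
  expect_length(pop, 50)
  expect_true(all(counts >= 20 & counts <= 200))
  expect_true(all(vapply(pop, length, integer(1)) == 500))
  # degenerate range
  cfg5 <- ga_config(population_size = 10, init_gene_range = c(5, 5))
  expect_true(all(vapply(init_population(100, cfg5, 1), sum, numeric(1)) == 5))
  # determinism
  expect_identical(init_population(500, cfg, seed = 4), pop)
  expect_error(init_population(100, cfg, 1), "exceeds")
})

test_that("initial set-bit counts are uniform over the range (chi-square)", {
  cfg <- ga_config(population_size = 10000, init_gene_range = c(20, 200))
  counts <- vapply(init_population(500, cfg, seed = 99), sum, numeric(1))
  tab <- table(factor(counts, levels = 20:200))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("normalized geometric ranking probabilities", {
  expect_equal(selection_probabilities(1, 0.3), 1.0)
  for (n in c(1, 10, 200)) for (q in c(0.005, 0.01, 0.1)) {
    p <- selection_probabilities(n, q)
    expect_lt(abs(sum(p) - 1), 1e-12)
    if (n > 1) expect_true(all(diff(p) < 0))
  }
  # direct arithmetic oracle for the published setting
  p200 <- selection_probabilities(200, 0.01)
  expect_equal(p200[1], 0.01 / (1 - 0.99^200))
  expect_equal(p200[7], 0.01 / (1 - 0.99^200) * 0.99^6)
  expect_error(selection_probabilities(10, 0), "\\(0, 1\\)")
  expect_error(selection_probabilities(10, 1), "\\(0, 1\\)")
})

test_that("uniform crossover preserves alleles and complements the mask", {
  a <- c(1L, 1L, 0L, 0L, 1L)
  kids <- uniform_crossover(a, a, seed = 1)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)
  k2 <- uniform_crossover(rep(0L, 4), rep(1L, 4), seed = 2)
  expect_identical(k2[[1]], 1L - k2[[2]]) # complementary mask
  expect_error(uniform_crossover(a, a[-1]), "length")
})

test_that("allele inheritance holds for both operators on random parents", {
  set.seed(7)
  for (i in 1:200) {
    L <- sample(2:40, 1)
    a <- sample(0:1, L, replace = TRUE)
    b <- sample(0:1, L, replace = TRUE)
    for (kids in list(uniform_crossover(a, b, seed = i),
                      two_point_crossover(a, b, seed = i))) {
      for (child in kids) {
        # each locus equals one parent's allele: AND(a,b) <= child <= OR(a,b)
        expect_true(all(child >= pmin(a, b) & child <= pmax(a, b)))
      }
      # the two children mirror each other: where one took a, the other took b
      expect_identical(kids[[1]] + kids[[2]], a + b)
    }
  }
})

test_that("two-point crossover swaps the half-open segment", {
  k <- two_point_crossover(rep(0L, 4), rep(1L, 4), cuts = c(1, 3))
  expect_identical(k[[1]], c(0L, 1L, 1L, 0L))
  expect_identical(k[[2]], c(1L, 0L, 0L, 1L))
  # whole-string segment = full swap
  a <- c(1L, 0L, 1L); b <- c(0L, 1L, 0L)
  k2 <- two_point_crossover(a, b, cuts = c(0, 3))
  expect_identical(k2[[1]], b)
  expect_identical(k2[[2]], a)
  k3 <- two_point_crossover(a, a, seed = 5)
  expect_identical(k3[[1]], a)
  expect_error(two_point_crossover(1L, 1L), "length >= 2")
  expect_error(two_point_crossover(a, b, cuts = c(2, 2)), "cuts")
})

test_that("hybrid crossover returns the best two of exactly four offspring", {
  a <- c(1L, 1L, 1L, 0L, 0L, 0L)
  hc_same <- hybrid_crossover(a, a, fitness_fn = sum, seed = 1)
  expect_identical(hc_same$chromosomes[[1]], a)
  expect_identical(hc_same$chromosomes[[2]], a)
  set.seed(20)
  for (i in 1:20) {
    p1 <- sample(0:1, 12, replace = TRUE)
    p2 <- sample(0:1, 12, replace = TRUE)
    hc <- hybrid_crossover(p1, p2, fitness_fn = sum, seed = i)
    expect_length(hc$offspring, 4)
    ones <- sort(vapply(hc$offspring, sum, numeric(1)), decreasing = TRUE)
    got <- sort(vapply(hc$chromosomes, sum, numeric(1)), decreasing = TRUE)
    expect_identical(got, ones[1:2]) # the two largest bit counts win
  }
})

test_that("mutation semantics: none, all, and expected Hamming distance", {
  bits <- c(0L, 1L, 0L, 1L, 1L)
  expect_identical(mutate(bits, 0, seed = 1), bits)
  expect_identical(mutate(bits, 1, seed = 1), 1L - bits)
  # rate 1 on an all-ones string yields all-zero, then repair sets one bit
  expect_equal(sum(mutate(rep(1L, 6), 1, seed = 2)), 1)
  expect_error(mutate(bits, 1.5), "\\[0, 1\\]")
  # binomial expectation oracle: per-bit rate 1/L gives mean distance 1
  L <- 50
  base <- rep(c(1L, 0L), length.out = L)
  d <- vapply(1:10000, function(i)
    sum(mutate(base, 1 / L, seed = i) != base), numeric(1))
  se <- sqrt(L * (1 / L) * (1 - 1 / L) / 10000)
  expect_lt(abs(mean(d) - 1), 3 * se)
})

test_that("config validation catches bad hyperparameters", {
  expect_error(ga_config(population_size = 7), "even")
  expect_error(ga_config(crossover_prob = 1.2), "\\[0, 1\\]")
  expect_error(ga_config(selection_q = 0), "\\(0, 1\\)")
  expect_error(ga_config(init_gene_range = c(10, 5)), "increasing")
})

test_that("zero generations returns the initial population's best", {
  onemax <- function(bits) mean(bits)
  cfg <- ga_config(population_size = 20, max_generations = 0,
                   init_gene_range = c(3, 15), master_seed = 5)
  st <- evolve(config = cfg, fitness_fn = onemax, n_genes = 30)
  expect_equal(st$generation, 0)
  pop0 <- init_population(30, cfg, seed = bcgaelm:::derive_seed(5, 1L))
  expect_equal(bcgaelm:::fitness_value(st$best_ever$fit),
               max(vapply(pop0, mean, numeric(1))))
})

test_that("selection pressure works on the OneMax surrogate", {
  onemax <- function(bits) mean(bits)
  for (seed in c(1, 2, 3)) {
    cfg <- ga_config(population_size = 20, max_generations = 40,
                     init_gene_range = c(3, 15), selection_q = 0.1,
                     master_seed = seed)
    st <- evolve(config = cfg, fitness_fn = onemax, n_genes = 30)
    h <- st$history
    expect_gt(bcgaelm:::fitness_value(st$best_ever$fit), h$best_fitness[1])
    expect_true(all(diff(h$best_ever_fitness) >= 0)) # elitism monotonicity
    expect_gt(h$mean_fitness[nrow(h)], h$mean_fitness[1])
    # population size constant, repair guarantee holds everywhere
    expect_length(st$population, 20)
    expect_true(all(vapply(st$population, function(p) sum(p$bits),
                           numeric(1)) >= 1))
  }
})

test_that("early stopping triggers on the accuracy target", {
  onemax <- function(bits) mean(bits)
  cfg <- ga_config(population_size = 10, max_generations = 50,
                   init_gene_range = c(2, 10), selection_q = 0.1,
                   target_accuracy = 0.5, master_seed = 2)
  st <- evolve(config = cfg, fitness_fn = onemax, n_genes = 20)
  expect_lt(st$generation, 50)
  expect_gte(bcgaelm:::fitness_accuracy(st$best_ever$fit), 0.5)
})

test_that("evolution on a real dataset is reproducible and self-consistent", {
  ds <- separable_dataset(n_per_class = 8, k = 2, n_noise_genes = 6, seed = 5)
  cfg <- ga_config(population_size = 10, max_generations = 3,
                   init_gene_range = c(1, 4), selection_q = 0.05,
                   master_seed = 31)
  params <- fitness_params(n_splits = 4)
  elm <- list(n_hidden = 8)
  st1 <- evolve(ds, cfg, params, elm)
  st2 <- evolve(ds, cfg, params, elm)
  expect_identical(best_solution(st1)$gene_ids, best_solution(st2)$gene_ids)
  expect_identical(st1$history, st2$history)
  # round-trip oracle: every cached fitness replays exactly from its seed
  for (p in st1$population[1:3]) {
    refit <- evaluate_subset(ds, p$bits, params, elm,
                             seed = attr(p$fit, "seed"))
    expect_equal(refit$fitness, p$fit$fitness)
    expect_identical(refit$per_split_accuracies,
                     p$fit$per_split_accuracies)
  }
  sol <- best_solution(st1)
  refit <- evaluate_subset(ds, sol$chromosome, params, elm,
                           seed = attr(sol$fitness, "seed"))
  expect_equal(refit$fitness, sol$fitness$fitness)
})

test_that("best_solution maps set bits to gene identifiers", {
  fit <- bcgaelm:::fitness_result(0.9, 2, c(0.9), fitness_params())
  st <- structure(list(best_ever = list(bits = c(0L, 1L, 0L, 1L, 0L),
                                        fit = fit),
                       gene_ids = paste0("g", 1:5)),
                  class = "ga_state")
  sol <- best_solution(st)
  expect_identical(sol$gene_ids, c("g2", "g4"))
  st_bad <- structure(list(best_ever = list(bits = c(1L), fit = NULL)),
                      class = "ga_state")
  expect_error(best_solution(st_bad), "evaluated")
})
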