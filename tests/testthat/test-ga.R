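test_that("initialization draws the configured number of uniform specimens", {
  set.seed(1)
  pop <- ga_initialize(ga_config(population_size = 100))
  expect_equal(dim(pop), c(100L, 5L))
  expect_true(all(pop >= -10 & pop <= 10))
  set.seed(2)
  expect_equal(dim(ga_initialize(ga_config(population_size = 1,
                                           elite_count = 1))), c(1L, 5L))
  set.seed(3); a <- ga_initialize(ga_config())
  set.seed(3); b <- ga_initialize(ga_config())
  expect_identical(a, b)
})

test_that("config invariants are enforced", {
  expect_error(ga_config(elite_count = 0), "elite_count")
  expect_error(ga_config(elite_count = 30, population_size = 20),
               "elite_count")
  expect_error(ga_config(crossover_prob = 1.2), "probabilities")
  expect_error(ga_config(init_low = 5, init_high = -5), "init_low")
})

test_that("fitness counts cohorts whose top-scored embryo has the top class", {
  # class-5 one-hot scores 2.8715555 > class-1's -10.01226347
  tab <- onehot_table(list(c(1, 5)))
  expect_equal(ga_fitness(published_weights(), tab), 1L)
  # a single-class cohort is topped by any weight vector
  tab3 <- onehot_table(list(c(3, 3, 3)))
  expect_equal(ga_fitness(c(0, 0, 0, 0, 0), tab3), 1L)
  expect_equal(ga_fitness(rnorm(5), tab3), 1L)
})

test_that("score ties resolve to the lowest embryo index", {
  # all-zero weights tie every embryo; contribution 1 iff first-listed
  # embryo carries the top class
  first_top <- onehot_table(list(c(5, 3)))
  first_not <- onehot_table(list(c(3, 5)))
  w0 <- rep(0, 5)
  expect_equal(ga_fitness(w0, first_top), 1L)
  expect_equal(ga_fitness(w0, first_not), 0L)
})

test_that("fitness rejects unusable inputs", {
  tab <- onehot_table(list(c(1, 5)))
  tab$true_class[1] <- NA
  expect_error(ga_fitness(published_weights(), tab), "true_class")
  expect_error(ga_fitness(published_weights(), tab[0, ]), "no training")
})

test_that("elite selection sorts by fitness with index tie-breaks", {
  pop <- matrix(1:15, nrow = 3, byrow = TRUE)   # rows tagged 1, 6, 11
  out <- ga_select_elite(pop, c(3L, 1L, 2L), 2L)
  expect_equal(out[, 1], c(1, 11))   # rows 1 then 3
  out_tie <- ga_select_elite(pop, c(2L, 2L, 2L), 2L)
  expect_equal(out_tie[, 1], c(1, 6))   # first two by index
  out_all <- ga_select_elite(pop, c(1L, 3L, 2L), 3L)
  expect_equal(sort(out_all[, 1]), c(1, 6, 11))
  expect_error(ga_select_elite(pop, NULL, 2L), "fitness")
})

test_that("crossover swaps exactly the masked components", {
  a <- rep(1, 5); b <- rep(2, 5)
  one_bit <- ga_crossover(a, b, mask = c(1, 0, 0, 0, 0))
  expect_equal(one_bit$a, c(2, 1, 1, 1, 1))
  expect_equal(one_bit$b, c(1, 2, 2, 2, 2))
  expect_true(one_bit$applied)
  none <- ga_crossover(a, b, mask = rep(0, 5))
  expect_equal(none$a, a); expect_equal(none$b, b)
  full <- ga_crossover(a, b, mask = rep(1, 5))
  expect_equal(full$a, b); expect_equal(full$b, a)
  set.seed(1)
  skipped <- ga_crossover(a, b, prob = 0)
  expect_false(skipped$applied)
  expect_equal(skipped$a, a)
})

test_that("mutation respects its probability and range", {
  w <- c(1, 2, 3, 4, 5)
  copies <- ga_mutate(w, ga_config(mutation_prob = 0))
  expect_equal(dim(copies), c(5L, 5L))
  expect_true(all(t(copies) == w))
  forced <- ga_mutate(w, ga_config(mutation_prob = 1, mutation_low = 1,
                                   mutation_high = 1))
  expect_true(all(t(forced) == w + 1))
  set.seed(7); m1 <- ga_mutate(w, ga_config())
  set.seed(7); m2 <- ga_mutate(w, ga_config())
  expect_identical(m1, m2)
})

test_that("evolution finds an exhaustive optimum on tiny one-hot instances", {
  # any w with w5 > w1 is optimal here; check the evolved weights attain
  # the brute-force maximum over all component orderings
  tab <- onehot_table(list(c(1, 5), c(1, 1, 5), c(5, 1)))
  fit <- ga_evolve(tab, ga_config(seed = 11, max_generations = 100))
  expect_equal(fit$fitness, brute_force_max_fitness(tab))
  expect_equal(fit$fitness, 3L)
  expect_gt(fit$weights[5], fit$weights[1])

  tab2 <- onehot_table(list(c(2, 3), c(4, 2, 3), c(3, 3)))
  fit2 <- ga_evolve(tab2, ga_config(seed = 12, max_generations = 100))
  expect_equal(fit2$fitness, brute_force_max_fitness(tab2))
})

test_that("a single one-embryo cohort converges in the first generation", {
  tab <- onehot_table(list(3))
  fit <- ga_evolve(tab, ga_config(seed = 5))
  expect_true(fit$converged)
  expect_equal(fit$generations, 1L)
  expect_equal(fit$fitness, 1L)
})

test_that("evolution is a pure function of the seed", {
  tab <- onehot_table(list(c(1, 5), c(2, 4, 3), c(3, 5, 1)))
  f1 <- ga_evolve(tab, ga_config(seed = 99, max_generations = 30))
  f2 <- ga_evolve(tab, ga_config(seed = 99, max_generations = 30))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("best fitness never exceeds the cohort count and is monotone under pure elitism", {
  tab <- synth_cohorts(fast_synth_config(n_cohorts = 30, seed = 21,
                                         eligibility = FALSE))
  fit <- ga_evolve(tab, ga_config(seed = 22, max_generations = 40))
  expect_true(all(fit$history <= 30))
  pure <- ga_evolve(tab, ga_config(seed = 23, crossover_prob = 0,
                                   mutation_prob = 0,
                                   max_generations = 40))
  expect_true(all(diff(pure$history) >= 0))
})
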