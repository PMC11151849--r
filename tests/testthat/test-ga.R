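test_that("GA recovers the known optimum of a concave bowl", {
  cfg <- ga_config(bounds = rbind(c(0, 0, 0), c(1, 1, 1)), encoding = "real",
                   generations = 200, seed = 1)
  res <- run_ga(function(x) -sum((x - 0.5)^2), cfg)
  expect_true(all(abs(res$best - 0.5) < 0.02))
  expect_gt(res$best_fitness, -0.003)
})

test_that("GA matches the exhaustive oracle on discrete problems", {
  oracle <- function(f, vals) vals[which.max(vapply(vals, f, numeric(1)))]
  f7 <- function(n) -abs(n - 7)
  cfg <- ga_config(bounds = rbind(1, 25), encoding = "integer",
                   generations = 50, seed = 3)
  expect_equal(as.integer(run_ga(function(x) f7(x[1]), cfg)$best), 7L)
  expect_equal(oracle(f7, 1:25), 7)

  # 5-point problem, 100 seeds, random target each time
  hits <- vapply(1:100, function(s) {
    target <- (s %% 5) + 1
    f <- function(x) -(x[1] - target)^2
    cfg <- ga_config(bounds = rbind(1, 5), encoding = "integer",
                     generations = 30, population_size = 20, seed = s)
    as.integer(run_ga(f, cfg)$best) == target
  }, logical(1))
  expect_equal(sum(hits), 100)
})

test_that("best-so-far trace is nondecreasing with elitism and runs are
           reproducible", {
  cfg <- ga_config(bounds = rbind(c(-2, -2), c(2, 2)), encoding = "real",
                   generations = 80, seed = 5)
  f <- function(x) -sum(x^2) + sin(3 * x[1])
  a <- run_ga(f, cfg)
  b <- run_ga(f, cfg)
  expect_identical(a$best, b$best)
  expect_true(all(diff(a$trace) >= 0))
  # constant fitness: flat trace, in-bounds solution
  flat <- run_ga(function(x) 1, cfg)
  expect_true(all(flat$trace == 1))
  expect_true(all(flat$best >= -2 & flat$best <= 2))
  # non-finite fitness is rejected with the chromosome named
  expect_error(run_ga(function(x) NaN, cfg), "non-finite")
})

test_that("roulette selection is fitness-proportional", {
  expect_equal(roulette_select(0.3), 1L)
  expect_error(roulette_select(numeric(0)), "empty")
  set.seed(1)
  draws <- replicate(3000, roulette_select(c(0, 0, 1)))
  expect_gt(mean(draws == 3), 0.8)
  draws2 <- replicate(3000, roulette_select(c(2, 2, 2)))
  freq <- tabulate(draws2, 3) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.04))
})

test_that("reproduction respects rates and bounds", {
  cfg0 <- ga_config(bounds = rbind(c(0, 0), c(1, 1)), encoding = "real",
                    crossover_rate = 0, mutation_rate = 0, seed = 1)
  set.seed(2)
  kids <- ga_reproduce(c(0.2, 0.8), c(0.6, 0.1), cfg0)
  expect_identical(kids[[1]], c(0.2, 0.8))
  expect_identical(kids[[2]], c(0.6, 0.1))

  # full mutation on an integer gene redraws uniformly
  cfgi <- ga_config(bounds = rbind(1, 25), encoding = "integer",
                    crossover_rate = 0, mutation_rate = 1, seed = 1)
  set.seed(3)
  vals <- replicate(5000, ga_reproduce(5, 5, cfgi)[[1]])
  expect_setequal(sort(unique(vals)), 1:25)
  expect_true(all(abs(tabulate(vals, 25) / 5000 - 1 / 25) < 0.02))

  # real offspring always within bounds
  cfgr <- ga_config(bounds = rbind(c(0, -1), c(1, 1)), encoding = "real",
                    crossover_rate = 0.9, mutation_rate = 0.5, seed = 1)
  set.seed(4)
  in_bounds <- vapply(1:2000, function(i) {
    ks <- ga_reproduce(runif(2, c(0, -1), c(1, 1)), runif(2, c(0, -1), c(1, 1)), cfgr)
    all(unlist(ks) >= c(0, -1) - 1e-12) && all(unlist(ks) <= c(1, 1) + 1e-12)
  }, logical(1))
  expect_true(all(in_bounds))
})
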