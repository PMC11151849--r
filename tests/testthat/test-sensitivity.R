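test_that("VSR ranks a planted relevant input first and a pure-noise input
           last", {
  set.seed(5)
  n <- 400
  d <- data.frame(x_active = runif(n, 0, 10), x_weak = runif(n, 0, 10),
                  x_noise = runif(n, 0, 10))
  d$y <- 3 * sin(d$x_active) + 0.3 * d$x_weak + 6 + rnorm(n, 0, 0.1)
  v <- compute_vsr(y ~ x_active + x_weak + x_noise, d, n_hidden = 8, seed = 1,
                   config = train_config(seed = 1, max_epochs = 1500,
                                         patience = 150))
  expect_equal(v$input[1], "x_active")
  expect_equal(v$vsr[1], 1)
  expect_equal(v$input[nrow(v)], "x_noise")
  expect_equal(v$vsr[nrow(v)], 0)
})

test_that("exchangeable inputs receive near-equal raw VSRs", {
  set.seed(6)
  n <- 300
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  d$y <- d$x1 + d$x2 + 2 + rnorm(n, 0, 0.05)  # x1 and x2 exchangeable
  v <- compute_vsr(y ~ x1 + x2 + x3, d, n_hidden = 6, seed = 2,
                   config = train_config(seed = 2, max_epochs = 1200,
                                         patience = 120))
  r1 <- v$vsr_raw[v$input == "x1"]
  r2 <- v$vsr_raw[v$input == "x2"]
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.25)
  expect_error(compute_vsr(y ~ x1, d), "2 inputs")
})

test_that("rescaled VSR endpoints are exact and the ablate mode agrees on the
           top input", {
  d <- simulate_rr(config = sim_config(seed = 3))
  cfg <- train_config(seed = 3, max_epochs = 1000, patience = 100)
  v1 <- compute_vsr(rr_form, d, n_hidden = 10, seed = 3, config = cfg)
  expect_equal(max(v1$vsr), 1)
  expect_equal(min(v1$vsr), 0)
  v2 <- compute_vsr(rr_form, d, n_hidden = 10, seed = 3, mode = "ablate",
                    config = cfg)
  expect_equal(v1$input[1], v2$input[1])
  # deterministic given the seed
  v3 <- compute_vsr(rr_form, d, n_hidden = 10, seed = 3, config = cfg)
  expect_identical(v1$vsr, v3$vsr)
})

test_that("GA input optimization recovers a known concave optimum and
           respects bounds and grid seeding", {
  d <- simulate_rl(config = sim_config(seed = 7, n_replicates = 1))
  fit <- mlpga(rl_form, d, n_hidden = 6, config = quick_train(7, 100))
  # a known concave bowl with an analytic optimum stands in for the surrogate
  target <- c(15, 45, 10, 28)
  bounds <- default_bounds(fit$feature_names)
  res <- run_ga(function(x) -sum(((x - target) / (bounds[2, ] - bounds[1, ]))^2),
                ga_config(bounds, "real", generations = 300, seed = 1))
  rel_err <- abs(res$best - target) / (bounds[2, ] - bounds[1, ])
  expect_true(all(rel_err < 0.02))

  # grid seeding: optimum at least as good as every design point
  opt <- optimize_inputs(fit, ga = ga_config(bounds, "real",
                                             generations = 60, seed = 2))
  tab <- shiitake_tables()
  grid <- data.frame(bagasse_pct = tab$bagasse_pct,
                     wheatbran_pct = tab$wheatbran_pct,
                     beechsawdust_pct = tab$beechsawdust_pct,
                     time_days = ifelse(is.na(tab$days_to_highest), 40,
                                        tab$days_to_highest))
  expect_gte(opt$predicted, max(predict(fit, grid)) - 1e-9)
  # bounds respected, time axis present and rendered
  expect_true(all(opt$optimum >= bounds[1, ] & opt$optimum <= bounds[2, ]))
  expect_match(opt$time_days_hours, "^\\d+ d \\d+ h$")
})

test_that("days-and-hours rendering rounds correctly", {
  expect_equal(format_days_hours(28.43), "28 d 10 h")
  expect_equal(format_days_hours(30), "30 d 0 h")
  expect_equal(format_days_hours(29.999), "30 d 0 h")
})
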