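test_that("fold assignments partition the rows into near-equal folds", {
  f <- make_folds(2048, k = 8, repeats = 10, seed = 1)
  expect_equal(dim(f), c(2048, 10))
  for (r in c(1, 10)) {
    sizes <- tabulate(f[, r], 8)
    expect_equal(sizes, rep(256, 8))
  }
  f2 <- make_folds(257, k = 8, repeats = 1, seed = 1)
  expect_lte(diff(range(tabulate(f2[, 1], 8))), 1)
  expect_error(make_folds(5, k = 8), "at least")
  expect_identical(make_folds(100, seed = 2), make_folds(100, seed = 2))
})

test_that("cross-validation pools out-of-fold predictions over 80 splits", {
  d <- simulate_rr(config = sim_config(seed = 1))
  mean_factory <- function(train) {
    structure(list(mu = mean(train$rr_cm_per_day)), class = "mu_model")
  }
  assign("predict.mu_model", function(object, newdata, ...) {
    rep(object$mu, nrow(newdata))
  }, envir = globalenv())
  on.exit(rm("predict.mu_model", envir = globalenv()))
  cv <- cross_validate(mean_factory, d, "rr_cm_per_day", k = 8, repeats = 10, seed = 1)
  expect_equal(cv$n_splits, 80)
  expect_equal(nrow(cv$splits), 80)
  expect_lt(abs(cv$pooled_test$r2), 0.02)  # null model explains nothing

  # oracle factory: the generator's own mean surface bounds the noise ceiling
  tab <- shiitake_tables()
  oracle_factory <- function(train) {
    structure(list(tab = tab), class = "oracle_model")
  }
  assign("predict.oracle_model", function(object, newdata, ...) {
    tab <- object$tab
    key <- function(d) paste(d$bagasse_pct, d$wheatbran_pct, d$beechsawdust_pct)
    i <- match(key(newdata), key(tab))
    ifelse(is.na(tab$days_to_highest[i]), 0,
           tab$rl_mean_cm[i] / ifelse(is.na(tab$days_to_highest[i]), 1,
                                      tab$days_to_highest[i]))
  }, envir = globalenv())
  on.exit(rm("predict.oracle_model", envir = globalenv()), add = TRUE)
  dr <- simulate_rr(config = sim_config(seed = 2))
  cv2 <- cross_validate(oracle_factory, dr, "rr_cm_per_day", k = 8, repeats = 1, seed = 2)
  # analytic ceiling: residual variance = mean over substrates of (sd/day)^2
  noise_var <- mean((0.30 / ifelse(is.na(tab$days_to_highest), 40,
                                   tab$days_to_highest))[-1]^2) * 63 / 64
  ceiling_r2 <- 1 - noise_var / var(dr$rr_cm_per_day)
  expect_equal(cv2$pooled_test$r2, ceiling_r2, tolerance = 0.02)
})

test_that("grouped folding keeps all rows of a substrate together", {
  d <- simulate_rl(config = sim_config(seed = 3))
  seen <- new.env()
  factory <- function(train) {
    key <- unique(paste(train$bagasse_pct, train$wheatbran_pct, train$beechsawdust_pct))
    assign(paste0("n", length(ls(seen))), length(key), envir = seen)
    structure(list(mu = mean(train$rl_cm)), class = "mu2")
  }
  assign("predict.mu2", function(object, newdata, ...) rep(object$mu, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.mu2", envir = globalenv()))
  cv <- cross_validate(factory, d, "rl_cm", k = 8, repeats = 1, seed = 1,
                       group_by_substrate = TRUE)
  expect_equal(cv$n_splits, 8)
  expect_true(all(unlist(mget(ls(seen), envir = seen)) == 56))  # 64 - 8 per fold
})

test_that("architecture search is cached and matches an exhaustive sweep", {
  d <- toy_surface(120, seed = 6, noise_sd = 0.05)
  d$y <- d$y + 1  # keep positive for the Box-Cox default offset
  rng <- 1:4
  cfg <- train_config(seed = 1, max_epochs = 120, patience = 20)
  s <- search_hidden_neurons(y ~ x1 + x2, d, gene_range = rng,
                             ga = ga_config(rbind(1, 4), "integer",
                                            population_size = 8,
                                            generations = 10, seed = 1),
                             k = 4, repeats = 1, seed = 1, config = cfg)
  expect_lte(s$n_cv_evaluations, length(rng))
  expect_equal(nrow(s$fitness_table), s$n_cv_evaluations)

  exhaustive <- vapply(rng, function(h) {
    cv <- cross_validate(function(dd) mlpga(y ~ x1 + x2, dd, n_hidden = h, config = cfg),
                         d, "y", k = 4, repeats = 1, seed = 1)
    mean(cv$splits$test_rmse)
  }, numeric(1))
  expect_equal(s$fitness_table$mean_test_rmse,
               exhaustive[match(s$fitness_table$n_hidden, rng)])
  # selection follows the one-standard-error parsimony rule over the sweep
  tab <- s$fitness_table
  thr <- min(tab$mean_test_rmse) + tab$se_test_rmse[which.min(tab$mean_test_rmse)]
  expect_equal(s$n_hidden, tab$n_hidden[which(tab$mean_test_rmse <= thr)[1]])
})

test_that("parsimonious widths win on linear truth", {
  set.seed(8)
  d <- data.frame(x1 = runif(150), x2 = runif(150))
  d$y <- 5 + 2 * d$x1 - d$x2 + rnorm(150, 0, 0.2)
  s <- search_hidden_neurons(y ~ x1 + x2, d, gene_range = 1:8,
                             ga = ga_config(rbind(1, 8), "integer",
                                            population_size = 10,
                                            generations = 8, seed = 2),
                             k = 4, repeats = 1, seed = 2,
                             config = train_config(seed = 2, max_epochs = 400,
                                                   patience = 60))
  # a small width ties the best within one standard error on linear truth
  tab <- s$fitness_table
  thr <- min(tab$mean_test_rmse) + tab$se_test_rmse[which.min(tab$mean_test_rmse)]
  expect_lte(min(tab$n_hidden[tab$mean_test_rmse <= thr]), 3)
  expect_equal(s$n_hidden, min(tab$n_hidden[tab$mean_test_rmse <= thr]))
})
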