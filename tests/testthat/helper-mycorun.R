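# shared shorthands: small training budgets for unit tests; the acceptance
# tests use the full-scale settings themselves

quick_train <- function(seed = 1L, epochs = 200L) {
  train_config(seed = seed, max_epochs = epochs, patience = 30L)
}

rl_form <- rl_cm ~ bagasse_pct + wheatbran_pct + beechsawdust_pct + time_days
rr_form <- rr_cm_per_day ~ bagasse_pct + wheatbran_pct + beechsawdust_pct

# deterministic nonlinear toy surface on [0,1]^2
toy_surface <- function(n, seed = 1, noise_sd = 0) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n)
  data.frame(x1 = x1, x2 = x2,
             y = sin(pi * x1) * cos(pi * x2 / 2) + 2 +
               rnorm(n, 0, noise_sd))
}
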