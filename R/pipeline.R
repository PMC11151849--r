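# End-to-end orchestration: simulate -> screen -> architecture search ->
# cross-validated comparison against the linear baselines -> sensitivity ->
# input optimization, for both responses.

rl_formula <- stats::as.formula(
  rl_cm ~ bagasse_pct + wheatbran_pct + beechsawdust_pct + time_days)
rr_formula <- stats::as.formula(
  rr_cm_per_day ~ bagasse_pct + wheatbran_pct + beechsawdust_pct)

baseline_methods <- c("mlr", "stepwise", "plsr", "pcr", "olsr")

run_one_kind <- function(kind, data, seed, k, repeats, gene_range, ga_search,
                         ga_opt, train_cfg, tables) {
  fmla <- if (kind == "rl") rl_formula else rr_formula
  response <- all.vars(fmla)[1]
  inputs <- attr(stats::terms(fmla), "term.labels")
  if (is.null(train_cfg)) train_cfg <- default_train_config(nrow(data), seed)

  screen <- pca_outlier_screen(cbind(data[inputs], data[response]))

  search <- search_hidden_neurons(fmla, data, gene_range = gene_range,
                                  ga = ga_search, k = k, repeats = 1L,
                                  seed = seed, config = train_cfg)
  n_hidden <- search$n_hidden

  cfg <- train_cfg; cfg$seed <- seed
  cv_rows <- list()
  cv_mlp <- cross_validate(
    function(d) mlpga(fmla, d, n_hidden = n_hidden, config = cfg),
    data, response, k = k, repeats = repeats, seed = seed)
  cv_rows[["mlpga"]] <- cv_mlp
  for (m in baseline_methods)
    cv_rows[[m]] <- cross_validate(
      function(d) fit_baseline(fmla, d, method = m),
      data, response, k = k, repeats = repeats, seed = seed)

  metrics_table <- do.call(rbind, lapply(names(cv_rows), function(m) {
    cv <- cv_rows[[m]]
    data.frame(model = m,
               train_r2 = cv$pooled_train$r2, train_rmse = cv$pooled_train$rmse,
               train_mape = cv$pooled_train$mape,
               test_r2 = cv$pooled_test$r2, test_rmse = cv$pooled_test$rmse,
               test_mape = cv$pooled_test$mape)
  }))

  final <- mlpga(fmla, data, n_hidden = n_hidden, config = cfg)
  vsr <- compute_vsr(fmla, data, n_hidden = n_hidden, seed = seed,
                     config = train_cfg)
  opt <- optimize_inputs(final, ga = ga_opt, tables = tables, seed = seed)

  list(kind = kind, n_rows = nrow(data), outlier_flags = as.integer(screen),
       n_hidden = n_hidden, architecture_search = search$fitness_table,
       metrics = metrics_table, cv = cv_rows, model = final, vsr = vsr,
       optimum = opt)
}

#' Run the full substrate-formulation analysis
#'
#' Orchestrates the whole pipeline for both responses: simulate (or accept)
#' replicate-level running-length and running-rate datasets, screen them for
#' outliers, select the hidden-layer width by GA architecture search,
#' cross-validate the perceptron surrogate against the five linear baselines
#' under the repeated 8-fold plan, rank the inputs by VSR, and GA-optimize the
#' substrate composition (and running time, for running length) on the final
#' surrogate. Every stage derives its randomness from \code{seed}; a rerun
#' with the same seed reproduces the report exactly.
#'
#' @param seed Master seed.
#' @param rl_data,rr_data Optional replicate-level datasets (schemas of
#'   [read_growth_data()]); simulated with [sim_config()] defaults when absent.
#' @param k,repeats Cross-validation plan (defaults 8, 10).
#' @param gene_range Hidden-width search range (default 1..25).
#' @param ga_search,ga_opt Optional [ga_config()] overrides for the
#'   architecture search and the input optimization.
#' @param train_cfg A [train_config()] for all network fits; when \code{NULL}
#'   each response uses [default_train_config()] scaled to its dataset size.
#' @param out_dir Optional directory; when given, writes
#'   \code{report.json} and \code{metrics.csv} there.
#' @return A list with elements \code{rl} and \code{rr} (per-response stage
#'   results) plus \code{seed}.
#' @export
run_full_pipeline <- function(seed = 1L, rl_data = NULL, rr_data = NULL,
                              k = 8L, repeats = 10L, gene_range = 1:25,
                              ga_search = NULL, ga_opt = NULL,
                              train_cfg = NULL, out_dir = NULL) {
  tables <- shiitake_tables()
  scfg <- sim_config(seed = seed)
  if (is.null(rl_data)) rl_data <- simulate_rl(tables, scfg)
  if (is.null(rr_data)) rr_data <- simulate_rr(tables, scfg)
  rl_data <- validate_growth_data(rl_data, "rl")
  rr_data <- validate_growth_data(rr_data, "rr")

  report <- list(
    seed = as.integer(seed),
    rl = run_one_kind("rl", rl_data, seed, k, repeats, gene_range,
                      ga_search, ga_opt, train_cfg, tables),
    rr = run_one_kind("rr", rr_data, seed, k, repeats, gene_range,
                      ga_search, ga_opt, train_cfg, tables))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    metrics <- rbind(cbind(response = "running_length", report$rl$metrics),
                     cbind(response = "running_rate", report$rr$metrics))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    slim <- function(x) list(
      kind = x$kind, n_rows = x$n_rows, n_hidden = x$n_hidden,
      outlier_flags = x$outlier_flags, metrics = x$metrics,
      vsr = as.data.frame(x$vsr),
      optimum = as.list(x$optimum$optimum),
      predicted_optimum = x$optimum$predicted)
    jsonlite::write_json(list(seed = report$seed, rl = slim(report$rl),
                              rr = slim(report$rr)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = I(10), pretty = TRUE)
  }
  report
}
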