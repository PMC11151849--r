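# Repeated k-fold cross-validation and the genetic-algorithm search over the
# hidden-layer width.

#' Fold assignments for repeated k-fold cross-validation
#'
#' Each repeat shuffles the rows and partitions them into \code{k} folds whose
#' sizes differ by at most one. Deterministic per seed.
#'
#' @param n_rows Number of rows.
#' @param k Folds per repeat (default 8).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @return Integer matrix (\code{n_rows} x \code{repeats}) of fold labels in
#'   \code{1..k}.
#' @export
make_folds <- function(n_rows, k = 8L, repeats = 10L, seed = 1L) {
  if (n_rows < k) stop_domain("need at least k rows")
  with_seed(seed, {
    sapply(seq_len(repeats), function(r) {
      sample(rep_len(seq_len(k), n_rows))
    })
  })
}

#' Repeated cross-validation of a model factory
#'
#' Runs \code{k x repeats} train/test splits. \code{factory(train_df)} must
#' return an object whose \code{predict(object, newdata)} yields predictions
#' in original units. Pooled testing metrics are computed on the concatenated
#' out-of-fold predictions across all splits; pooled training metrics on the
#' concatenated in-fold predictions.
#'
#' @param factory Function of a training data frame returning a fitted model.
#' @param data Full data frame.
#' @param response Name of the response column.
#' @param k,repeats,seed Cross-validation plan (defaults 8, 10).
#' @param group_by_substrate When \code{TRUE}, all replicates and time points
#'   of a substrate composition are kept in the same fold (guards against
#'   twin-row leakage; default \code{FALSE}, matching replicate-level folding).
#' @return An object of class \code{"cv_result"}: \code{splits} (per-split
#'   metrics data frame), \code{pooled_test}, \code{pooled_train},
#'   \code{n_splits}.
#' @export
cross_validate <- function(factory, data, response, k = 8L, repeats = 10L,
                           seed = 1L, group_by_substrate = FALSE) {
  n <- nrow(data)
  if (group_by_substrate) {
    key <- interaction(data$bagasse_pct, data$wheatbran_pct,
                       data$beechsawdust_pct, drop = TRUE)
    gf <- make_folds(nlevels(key), k, repeats, seed)
    folds <- apply(gf, 2, function(col) col[as.integer(key)])
  } else {
    folds <- make_folds(n, k, repeats, seed)
  }
  y_all <- data[[response]]
  split_rows <- list()
  test_obs <- test_pred <- train_obs <- train_pred <- list()
  si <- 0L
  for (r in seq_len(repeats)) {
    for (fold in seq_len(k)) {
      si <- si + 1L
      test_idx <- which(folds[, r] == fold)
      train_idx <- setdiff(seq_len(n), test_idx)
      model <- tryCatch(factory(data[train_idx, , drop = FALSE]),
                        error = function(e) stop_domain(
                          sprintf("training failed on repeat %d fold %d: %s",
                                  r, fold, conditionMessage(e))))
      p_te <- predict(model, data[test_idx, , drop = FALSE])
      p_tr <- predict(model, data[train_idx, , drop = FALSE])
      m_te <- fit_metrics(y_all[test_idx], p_te)
      m_tr <- fit_metrics(y_all[train_idx], p_tr)
      split_rows[[si]] <- data.frame(
        repeat_id = r, fold = fold,
        test_r2 = m_te$r2, test_rmse = m_te$rmse,
        test_mae = m_te$mae, test_mape = m_te$mape,
        train_r2 = m_tr$r2, train_rmse = m_tr$rmse,
        train_mae = m_tr$mae, train_mape = m_tr$mape)
      test_obs[[si]] <- y_all[test_idx]; test_pred[[si]] <- p_te
      train_obs[[si]] <- y_all[train_idx]; train_pred[[si]] <- p_tr
    }
  }
  structure(list(
    splits = do.call(rbind, split_rows),
    pooled_test = fit_metrics(unlist(test_obs), unlist(test_pred)),
    pooled_train = fit_metrics(unlist(train_obs), unlist(train_pred)),
    n_splits = si, k = k, repeats = repeats, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation, %d repeats (%d splits)\n",
              x$k, x$repeats, x$n_splits))
  cat(sprintf("  pooled test : R2 %.4f | RMSE %.4f | MAE %.4f\n",
              x$pooled_test$r2, x$pooled_test$rmse, x$pooled_test$mae))
  cat(sprintf("  pooled train: R2 %.4f | RMSE %.4f | MAE %.4f\n",
              x$pooled_train$r2, x$pooled_train$rmse, x$pooled_train$mae))
  invisible(x)
}

#' Genetic-algorithm search over the hidden-layer width
#'
#' Integer-coded GA maximising the negative mean cross-validated test RMSE of
#' the perceptron surrogate as a function of the hidden-neuron count. The
#' fitness of each distinct width is cached, so at most
#' \code{length(gene_range)} cross-validations are run regardless of the GA
#' budget. The reported width applies the one-standard-error parsimony rule
#' over the evaluated widths: the smallest hidden-layer width whose mean test
#' RMSE is within one standard error of the best, favouring the compact
#' architectures that generalise well on designed experiments of this size.
#' The search plan defaults to a single repeat of 8 folds; re-evaluate the
#' selected width under the full plan for reporting.
#'
#' @param formula,data Model specification, as in [mlpga()].
#' @param gene_range Candidate hidden-layer widths (default 1..25).
#' @param ga Optional [ga_config()]; bounds/encoding are imposed.
#' @param k,repeats,seed Cross-validation plan used for the fitness.
#' @param config A [train_config()] for the inner fits.
#' @return List with \code{n_hidden} (selected width), \code{fitness_table}
#'   (evaluated widths and mean test RMSE), \code{ga} (the \code{"ga_result"})
#'   and \code{n_cv_evaluations}.
#' @export
search_hidden_neurons <- function(formula, data, gene_range = 1:25,
                                  ga = NULL, k = 8L, repeats = 1L, seed = 1L,
                                  config = train_config()) {
  if (is.null(ga))
    ga <- ga_config(bounds = rbind(min(gene_range), max(gene_range)),
                    encoding = "integer", seed = seed)
  else {
    ga$bounds <- rbind(min(gene_range), max(gene_range))
    ga$encoding <- "integer"
  }
  cache <- new.env(parent = emptyenv())
  se_cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness <- function(chrom) {
    key <- as.character(chrom[1])
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    cfg <- config; cfg$seed <- seed
    cv <- cross_validate(
      function(d) mlpga(formula, d, n_hidden = chrom[1], config = cfg),
      data, response = all.vars(formula)[1], k = k, repeats = repeats,
      seed = seed)
    se_cache[[key]] <- stats::sd(cv$splits$test_rmse) / sqrt(nrow(cv$splits))
    cache[[key]] <- -mean(cv$splits$test_rmse)
    cache[[key]]
  }
  res <- run_ga(fitness, ga)
  keys <- ls(cache)
  tab <- data.frame(n_hidden = as.integer(keys),
                    mean_test_rmse = -unlist(mget(keys, envir = cache)),
                    se_test_rmse = unlist(mget(keys, envir = se_cache)))
  tab <- tab[order(tab$n_hidden), ]
  rownames(tab) <- NULL
  # one-standard-error parsimony: smallest width within 1 SE of the best mean
  best_i <- which.min(tab$mean_test_rmse)
  threshold <- tab$mean_test_rmse[best_i] + tab$se_test_rmse[best_i]
  chosen <- tab$n_hidden[which(tab$mean_test_rmse <= threshold)[1]]
  list(n_hidden = as.integer(chosen), fitness_table = tab,
       ga = res, n_cv_evaluations = n_eval)
}
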