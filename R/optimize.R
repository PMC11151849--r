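# GA optimization of substrate composition (and running time) over a trained
# surrogate.

#' Default optimization bounds
#'
#' Component ratios are confined to the design range [0, 100] (percent of a
#' 10 g aliquot); the running-time axis, present only for the running-length
#' surrogate, to the observation window [5, 40] days. Extrapolation outside
#' the design box is disallowed.
#'
#' @param feature_names Input names of the surrogate.
#' @return 2 x p bounds matrix (rows: lower, upper).
#' @export
default_bounds <- function(feature_names) {
  lo <- ifelse(feature_names == "time_days", 5, 0)
  hi <- ifelse(feature_names == "time_days", 40, 100)
  b <- rbind(lo, hi)
  colnames(b) <- feature_names
  b
}

#' Optimize the surrogate's inputs by genetic algorithm
#'
#' Maximises the trained surrogate's prediction (original units) over the
#' bounded input box with a real-coded GA. With \code{grid_seed = TRUE} the
#' initial population is seeded with the 64 design compositions (each at its
#' recorded plateau day for a running-length surrogate), ranked by predicted
#' response, plus random fill; with one elite individual this guarantees the
#' returned optimum is at least as good as every design point.
#'
#' @param model A fitted \code{"mlpga"}.
#' @param bounds 2 x p matrix of per-input bounds; default [default_bounds()].
#' @param ga A [ga_config()] (bounds/encoding are imposed); default paper
#'   settings.
#' @param grid_seed Seed the initial population with the design grid.
#' @param tables Design tables used for grid seeding.
#' @param seed Integer seed (used when \code{ga} is \code{NULL}).
#' @return An object of class \code{"running_optimum"}: \code{optimum} (named
#'   input values), \code{predicted} (response at the optimum),
#'   \code{time_days_hours} (d + h rendering when a time axis is present) and
#'   the underlying \code{"ga_result"}.
#' @export
optimize_inputs <- function(model, bounds = NULL, ga = NULL, grid_seed = TRUE,
                            tables = shiitake_tables(), seed = 1L) {
  feats <- model$feature_names
  if (is.null(bounds)) bounds <- default_bounds(feats)
  if (ncol(bounds) != length(feats))
    stop_domain("bounds must have one column per model input")
  if (is.null(ga)) ga <- ga_config(bounds = bounds, encoding = "real", seed = seed)
  else { ga$bounds <- as.matrix(bounds); ga$encoding <- "real" }

  fitness <- function(chrom) predict_matrix(model, matrix(chrom, nrow = 1))

  seed_pop <- NULL
  if (grid_seed) {
    grid <- tables[c("bagasse_pct", "wheatbran_pct", "beechsawdust_pct")]
    if ("time_days" %in% feats)
      grid$time_days <- ifelse(is.na(tables$days_to_highest), 40,
                               tables$days_to_highest)
    grid <- as.matrix(grid[, feats, drop = FALSE])
    pred <- predict_matrix(model, grid)
    keep <- order(pred, decreasing = TRUE)[seq_len(min(nrow(grid),
                                                       ga$population_size - 10L))]
    seed_pop <- grid[keep, , drop = FALSE]
  }

  res <- run_ga(fitness, ga, seed_population = seed_pop)
  optimum <- setNames(res$best, feats)
  out <- list(optimum = optimum, predicted = res$best_fitness, ga = res,
              grid_seeded = grid_seed)
  if ("time_days" %in% feats)
    out$time_days_hours <- format_days_hours(optimum[["time_days"]])
  structure(out, class = "running_optimum")
}

#' Render fractional days as days and hours
#'
#' @param days Fractional days.
#' @return Character string like \code{"28 d 10 h"}.
#' @export
format_days_hours <- function(days) {
  d <- floor(days)
  h <- round((days - d) * 24)
  if (h == 24) { d <- d + 1; h <- 0 }
  sprintf("%d d %d h", d, h)
}

#' @export
print.running_optimum <- function(x, ...) {
  cat("GA optimum of the running surrogate\n")
  for (nm in names(x$optimum))
    cat(sprintf("  %-18s %8.2f\n", nm, x$optimum[[nm]]))
  if (!is.null(x$time_days_hours))
    cat("  running time      ", x$time_days_hours, "\n")
  cat(sprintf("  predicted response %.4f\n", x$predicted))
  invisible(x)
}
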