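#' Simulation settings for the replicate-level generator
#'
#' The generator reproduces the structure of the designed experiment: 64
#' substrate compositions observed at 5-day intervals from day 5 to day 40
#' with four replicates, i.e. 2,048 running-length rows and 256 running-rate
#' rows. \code{noise_sd_cm} is the replicate standard deviation of the
#' running length at the plateau day, in cm.
#'
#' @param seed Integer seed; recorded in the output's \code{"seed"} attribute.
#' @param n_replicates Replicates per substrate (default 4).
#' @param noise_sd_cm Replicate-level SD in cm (default 0.30).
#' @param time_grid Observation days (default 5, 10, ..., 40).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_replicates = 4L, noise_sd_cm = 0.30,
                       time_grid = seq(5, 40, by = 5)) {
  stopifnot(n_replicates >= 1, noise_sd_cm >= 0, length(time_grid) >= 1,
            all(time_grid > 0))
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 noise_sd_cm = noise_sd_cm, time_grid = as.numeric(time_grid)),
            class = "sim_config")
}

#' Per-substrate growth-curve parameters calibrated to the published means
#'
#' Each substrate gets a plateau running length (the published mean RL) and
#' the day on which that plateau is reached (the published days-to-highest).
#' The non-growing control keeps a plateau of 0; its undefined plateau day is
#' stored as the last observation day so the curve is identically zero.
#'
#' @param tables Output of [shiitake_tables()].
#' @param config A [sim_config()]; supplies the replicate noise SD.
#' @return A 64-row data frame with columns \code{substrate}, the three
#'   composition percentages, \code{plateau_cm}, \code{plateau_day},
#'   \code{noise_sd_cm}.
#' @export
growth_params <- function(tables = shiitake_tables(), config = sim_config()) {
  data.frame(
    substrate = tables$substrate,
    bagasse_pct = tables$bagasse_pct,
    wheatbran_pct = tables$wheatbran_pct,
    beechsawdust_pct = tables$beechsawdust_pct,
    plateau_cm = tables$rl_mean_cm,
    plateau_day = ifelse(is.na(tables$days_to_highest),
                         max(config$time_grid), tables$days_to_highest),
    noise_sd_cm = config$noise_sd_cm)
}

#' Mean growth curve: linear ramp to a plateau
#'
#' The simplest curve consistent with a monotone increase that reaches its
#' substrate-specific maximum on the recorded day: RL rises linearly from 0
#' and stays at \code{plateau_cm} from \code{plateau_day} on.
#'
#' @param plateau_cm Plateau running length (cm).
#' @param plateau_day Day the plateau is reached.
#' @param t Time in days (vectorised).
#' @return Mean running length at \code{t}, in cm.
#' @examples
#' growth_curve_mean(10.60, 30, c(15, 30, 40))  # 5.30 10.60 10.60
#' @export
growth_curve_mean <- function(plateau_cm, plateau_day, t) {
  stopifnot(all(t >= 0), plateau_day > 0, plateau_cm >= 0)
  plateau_cm * pmin(t, plateau_day) / plateau_day
}

# replicate-level plateau draws; one Gaussian offset per substrate x replicate,
# consumed substrate-by-substrate then replicate-by-replicate
replicate_plateaus <- function(params, config) {
  with_seed(config$seed, {
    n <- nrow(params)
    out <- matrix(0, n, config$n_replicates)
    for (i in seq_len(n)) {
      delta <- stats::rnorm(config$n_replicates, 0, config$noise_sd_cm)
      out[i, ] <- pmax(0, params$plateau_cm[i] + delta)
    }
    # the control never grows, noise included
    out[params$plateau_cm == 0, ] <- 0
    out
  })
}

#' Simulate a replicate-level running-length dataset
#'
#' Draws one plateau offset per substrate-replicate
#' (\code{N(0, noise_sd_cm^2)}, clipped so plateaus stay nonnegative) and
#' scales the whole ramp by it, so each replicate's trajectory is nondecreasing
#' in time and equals its drawn plateau at the plateau day. With
#' \code{noise_sd_cm = 0} the dataset reproduces the published mean RL exactly
#' at every substrate's plateau day. The same seed yields a byte-identical
#' dataset.
#'
#' @param tables Output of [shiitake_tables()].
#' @param config A [sim_config()].
#' @return A data frame in the RL schema of [read_growth_data()] (default
#'   configuration: 2,048 rows), with the seed in \code{attr(x, "seed")}.
#' @export
simulate_rl <- function(tables = shiitake_tables(), config = sim_config()) {
  params <- growth_params(tables, config)
  plat <- replicate_plateaus(params, config)
  grid <- expand.grid(time_idx = seq_along(config$time_grid),
                      replicate = seq_len(config$n_replicates),
                      sub = seq_len(nrow(params)))
  sub <- grid$sub
  t <- config$time_grid[grid$time_idx]
  frac <- pmin(t, params$plateau_day[sub]) / params$plateau_day[sub]
  out <- data.frame(
    bagasse_pct = params$bagasse_pct[sub],
    wheatbran_pct = params$wheatbran_pct[sub],
    beechsawdust_pct = params$beechsawdust_pct[sub],
    time_days = t,
    replicate = grid$replicate,
    rl_cm = plat[cbind(sub, grid$replicate)] * frac)
  out <- out[order(sub, grid$replicate, t), ]
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  out
}

#' Simulate a replicate-level running-rate dataset
#'
#' Applies the running-rate definition (length over time) to each replicate's
#' running length at its substrate's plateau day; the control substrate has
#' rate 0. Plateau draws use the same stream layout as [simulate_rl()], so the
#' RR dataset for a seed is consistent with the RL dataset for that seed.
#'
#' @inheritParams simulate_rl
#' @return A data frame in the RR schema of [read_growth_data()] (default
#'   configuration: 256 rows), with the seed in \code{attr(x, "seed")}.
#' @export
simulate_rr <- function(tables = shiitake_tables(), config = sim_config()) {
  params <- growth_params(tables, config)
  plat <- replicate_plateaus(params, config)
  sub <- rep(seq_len(nrow(params)), each = config$n_replicates)
  rep_id <- rep(seq_len(config$n_replicates), times = nrow(params))
  rl_at_plateau <- plat[cbind(sub, rep_id)]
  out <- data.frame(
    bagasse_pct = params$bagasse_pct[sub],
    wheatbran_pct = params$wheatbran_pct[sub],
    beechsawdust_pct = params$beechsawdust_pct[sub],
    replicate = rep_id,
    rr_cm_per_day = compute_rr(rl_at_plateau, params$plateau_day[sub]))
  attr(out, "seed") <- config$seed
  out
}
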