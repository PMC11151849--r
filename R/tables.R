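#' In-paper substrate tables
#'
#' Loads the packaged copy of the published 64-substrate design: the three
#' component ratios (bagasse, wheat bran, beech sawdust; each a percentage of a
#' 10 g aliquot, so the three columns do not sum to 100), the day after
#' cultivation on which the highest statistically significant running length
#' (RL) was recorded, and the printed mean RL (cm) and running rate
#' (RR, cm d^-1). Significance letters from the mean-separation tests are kept
#' in separate annotation columns and are never part of the numeric values.
#'
#' The all-zero control substrate (row 1) has no growth: its mean RL is 0, its
#' days-to-highest is \code{NA}, and its RR is 0 by convention.
#'
#' @return A 64-row data frame with columns \code{substrate},
#'   \code{bagasse_pct}, \code{wheatbran_pct}, \code{beechsawdust_pct},
#'   \code{days_to_highest}, \code{rl_mean_cm}, \code{rl_letters},
#'   \code{rr_mean_cm_per_day}, \code{rr_letters}.
#' @examples
#' tab <- shiitake_tables()
#' subset(tab, wheatbran_pct == 100 & beechsawdust_pct == 100 & bagasse_pct == 0)
#' @export
shiitake_tables <- function() {
  path <- system.file("extdata", "shiitake_tables.csv", package = "mycorun")
  if (!nzchar(path) || !file.exists(path))
    stop_domain("packaged fixture 'shiitake_tables.csv' is missing or the package is corrupted")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(substrate = "character",
                                        rl_letters = "character",
                                        rr_letters = "character"))
  needed <- c("substrate", "bagasse_pct", "wheatbran_pct", "beechsawdust_pct",
              "days_to_highest", "rl_mean_cm", "rl_letters",
              "rr_mean_cm_per_day", "rr_letters")
  if (!identical(names(tab), needed) || nrow(tab) != 64L)
    stop_domain("packaged fixture 'shiitake_tables.csv' is corrupted")
  if (any(tab$rl_mean_cm < 0) || any(tab$rr_mean_cm_per_day < 0))
    stop_domain("packaged fixture contains negative means")
  control <- tab$bagasse_pct == 0 & tab$wheatbran_pct == 0 & tab$beechsawdust_pct == 0
  if (!identical(which(is.na(tab$days_to_highest)), which(control)))
    stop_domain("days-to-highest must be absent exactly for the all-zero control")
  tab
}

#' Running rate from running length
#'
#' The running rate is the running length divided by the running time
#' (cm d^-1). A zero running length has, by the control-substrate convention,
#' a zero rate regardless of the (possibly undefined) running time.
#'
#' @param rl_cm Running length in cm (nonnegative, vectorised).
#' @param time_days Running time in days; must be positive wherever
#'   \code{rl_cm > 0}. May be \code{NA} where \code{rl_cm == 0}.
#' @return Running rate in cm per day, same length as the longer input.
#' @examples
#' compute_rr(10.60, 30)  # 0.3533...
#' compute_rr(0, NA)      # 0
#' @export
compute_rr <- function(rl_cm, time_days) {
  n <- max(length(rl_cm), length(time_days))
  rl_cm <- rep_len(rl_cm, n)
  time_days <- rep_len(time_days, n)
  if (any(rl_cm < 0, na.rm = TRUE))
    stop_domain("rl_cm must be nonnegative")
  bad <- rl_cm > 0 & (is.na(time_days) | time_days <= 0)
  if (any(bad))
    stop_domain("time_days must be positive where rl_cm > 0")
  out <- numeric(n)
  pos <- rl_cm > 0
  out[pos] <- rl_cm[pos] / time_days[pos]
  out
}

#' Full factorial treatment grid
#'
#' Expands the 64 substrate compositions over the eight observation days
#' (5 to 40 in steps of 5), giving the 512 treatment combinations of the
#' designed experiment.
#'
#' @param tables Output of [shiitake_tables()].
#' @param time_grid Observation days.
#' @return A 512-row data frame of composition columns plus \code{time_days}.
#' @export
treatment_grid <- function(tables = shiitake_tables(), time_grid = seq(5, 40, by = 5)) {
  comps <- tables[c("substrate", "bagasse_pct", "wheatbran_pct", "beechsawdust_pct")]
  out <- merge(comps, data.frame(time_days = time_grid))
  out <- out[order(match(out$substrate, comps$substrate), out$time_days), ]
  rownames(out) <- NULL
  out
}

#' Export the packaged tables as CSV files
#'
#' Writes \code{table1.csv} (compositions and days-to-highest),
#' \code{table2_rl.csv} (mean running lengths) and \code{table3_rr.csv}
#' (mean running rates) into a directory.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
export_tables <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- shiitake_tables()
  f1 <- file.path(dir, "table1.csv")
  f2 <- file.path(dir, "table2_rl.csv")
  f3 <- file.path(dir, "table3_rr.csv")
  utils::write.csv(tab[c("substrate", "bagasse_pct", "wheatbran_pct",
                         "beechsawdust_pct", "days_to_highest")],
                   f1, row.names = FALSE, na = "")
  utils::write.csv(tab[c("substrate", "bagasse_pct", "wheatbran_pct",
                         "beechsawdust_pct", "rl_mean_cm", "rl_letters")],
                   f2, row.names = FALSE, na = "")
  utils::write.csv(tab[c("substrate", "bagasse_pct", "wheatbran_pct",
                         "beechsawdust_pct", "rr_mean_cm_per_day", "rr_letters")],
                   f3, row.names = FALSE, na = "")
  invisible(c(f1, f2, f3))
}
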