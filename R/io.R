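# CSV readers/writers for replicate-level growth datasets.
# Dialect: comma separator, '.' decimal, UTF-8, mandatory header row.

rl_columns <- c("bagasse_pct", "wheatbran_pct", "beechsawdust_pct",
                "time_days", "replicate", "rl_cm")
rr_columns <- c("bagasse_pct", "wheatbran_pct", "beechsawdust_pct",
                "replicate", "rr_cm_per_day")

check_numeric_col <- function(df, col) {
  v <- df[[col]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
    stop_domain(sprintf("column '%s' is not numeric (first bad row: %d)",
                        col, if (is.na(bad)) 1L else bad))
  }
  if (anyNA(v))
    stop_domain(sprintf("column '%s' has a missing value at row %d", col, which(is.na(v))[1]))
  v
}

check_range <- function(v, col, low, high = Inf) {
  bad <- which(v < low | v > high)[1]
  if (!is.na(bad))
    stop_domain(sprintf("column '%s' out of range [%s, %s] at row %d (value %g)",
                        col, format(low), format(high), bad, v[bad]))
}

validate_growth_data <- function(df, kind = c("rl", "rr")) {
  kind <- match.arg(kind)
  cols <- if (kind == "rl") rl_columns else rr_columns
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop_domain("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[cols]
  if (nrow(df) == 0) {
    df[] <- lapply(df, as.numeric)
    return(df)
  }
  for (col in cols) df[[col]] <- check_numeric_col(df, col)
  for (col in c("bagasse_pct", "wheatbran_pct", "beechsawdust_pct"))
    check_range(df[[col]], col, 0, 100)
  check_range(df$replicate, "replicate", 1)
  if (kind == "rl") {
    check_range(df$time_days, "time_days", 5, 40)
    off <- which(df$time_days %% 5 != 0)[1]
    if (!is.na(off))
      stop_domain(sprintf("column 'time_days' must be a multiple of 5 (row %d)", off))
    check_range(df$rl_cm, "rl_cm", 0)
  } else {
    check_range(df$rr_cm_per_day, "rr_cm_per_day", 0)
  }
  df
}

#' Read a replicate-level growth dataset
#'
#' Reads a CSV of running-length observations (columns \code{bagasse_pct},
#' \code{wheatbran_pct}, \code{beechsawdust_pct}, \code{time_days},
#' \code{replicate}, \code{rl_cm}) or running-rate observations (same
#' composition columns plus \code{replicate}, \code{rr_cm_per_day}) and
#' validates every row: composition percentages in [0, 100], observation days
#' on the 5..40 grid in steps of 5, nonnegative lengths/rates. Row order is
#' preserved; a violation raises an error naming the offending row and column.
#'
#' @param path CSV file path.
#' @param kind \code{"rl"} for running-length rows, \code{"rr"} for
#'   running-rate rows.
#' @return A validated data frame.
#' @seealso [write_growth_data()], [simulate_rl()], [simulate_rr()]
#' @export
read_growth_data <- function(path, kind = c("rl", "rr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_growth_data(df, kind)
}

#' Write a replicate-level growth dataset
#'
#' Writes a validated dataset back to CSV so that
#' \code{read_growth_data(write_growth_data(x, p))} reproduces \code{x}
#' (values round-trip through full double precision).
#'
#' @param df Data frame with the RL or RR schema.
#' @param path Output CSV path.
#' @param kind Dataset schema; inferred from the columns when missing.
#' @return Invisibly, \code{path}.
#' @export
write_growth_data <- function(df, path, kind = NULL) {
  if (is.null(kind)) kind <- if ("rl_cm" %in% names(df)) "rl" else "rr"
  df <- validate_growth_data(df, kind)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
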