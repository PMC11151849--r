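# Box-Cox response normalization, feature scaling and the PCA outlier screen.

boxcox_loglik <- function(lambda, z) {
  n <- length(z)
  y <- if (abs(lambda) < 1e-12) log(z) else (z^lambda - 1) / lambda
  s2 <- sum((y - mean(y))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(z))
}

#' Fit a Box-Cox power transform
#'
#' Estimates the power parameter by maximising the profile log-likelihood on a
#' coarse bracket followed by local refinement. Responses may contain exact
#' zeros (the non-growing control), hence the additive offset applied before
#' the transform; the default offset of 1 keeps all shifted values strictly
#' positive. Ties within numerical resolution are broken toward
#' \eqn{\lambda = 1} (no transform).
#'
#' @param x Numeric response values with \code{x + offset > 0}.
#' @param offset Additive shift applied before the power transform.
#' @param lambda Optional fixed power parameter; when \code{NULL} it is
#'   estimated.
#' @return An object of class \code{"boxcox_transform"} with elements
#'   \code{lambda} and \code{offset}.
#' @seealso [boxcox_forward()], [boxcox_inverse()]
#' @export
fit_boxcox <- function(x, offset = 1, lambda = NULL) {
  z <- x + offset
  if (any(z <= 0))
    stop_domain("all values must be strictly positive after the offset; increase `offset`")
  if (is.null(lambda)) {
    if (stats::var(x) == 0)
      stop_domain("cannot estimate lambda from a constant vector")
    grid <- seq(-2, 2, by = 0.1)
    ll <- vapply(grid, boxcox_loglik, numeric(1), z = z)
    best <- grid[which.max(ll)]
    opt <- stats::optimize(boxcox_loglik, interval = c(best - 0.1, best + 0.1),
                           z = z, maximum = TRUE, tol = 1e-7)
    lambda <- opt$maximum
    # prefer the identity transform when it is as good as the optimum
    if (boxcox_loglik(1, z) >= opt$objective - 1e-9) lambda <- 1
  }
  structure(list(lambda = lambda, offset = offset), class = "boxcox_transform")
}

#' @rdname fit_boxcox
#' @param t A \code{"boxcox_transform"}.
#' @export
boxcox_forward <- function(t, x) {
  z <- x + t$offset
  if (any(z <= 0)) stop_domain("value outside the transform's domain (x + offset <= 0)")
  if (abs(t$lambda) < 1e-12) log(z) else (z^t$lambda - 1) / t$lambda
}

#' @rdname fit_boxcox
#' @param y Transformed values.
#' @export
boxcox_inverse <- function(t, y) {
  z <- if (abs(t$lambda) < 1e-12) exp(y) else {
    base <- t$lambda * y + 1
    if (any(base <= 0))
      stop_domain("value outside the range of the forward transform")
    base^(1 / t$lambda)
  }
  z - t$offset
}

#' Fit a per-feature scaler
#'
#' \code{"minmax"} maps each feature's training minimum/maximum to -1/+1 (the
#' operating range of the tanh hidden layer); \code{"zscore"} centres and
#' scales to unit SD.
#'
#' @param X Numeric matrix or data frame of features (columns = features).
#' @param mode Scaling mode.
#' @return An object of class \code{"feature_scaler"}.
#' @export
fit_scaler <- function(X, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  constant <- which(hi - lo == 0)
  if (length(constant))
    stop_domain("constant feature(s): ",
                paste(colnames(X)[constant] %||% constant, collapse = ", "))
  structure(list(mode = mode, lo = lo, hi = hi,
                 mu = colMeans(X), sd = apply(X, 2, stats::sd),
                 features = colnames(X)),
            class = "feature_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_scaler
#' @param scaler A \code{"feature_scaler"}.
#' @export
scale_features <- function(scaler, X) {
  X <- as.matrix(X)
  if (!is.null(scaler$features) && all(scaler$features %in% colnames(X)))
    X <- X[, scaler$features, drop = FALSE]
  if (scaler$mode == "minmax")
    sweep(sweep(X, 2, scaler$lo), 2, (scaler$hi - scaler$lo) / 2, "/") - 1
  else
    sweep(sweep(X, 2, scaler$mu), 2, scaler$sd, "/")
}

#' @rdname fit_scaler
#' @export
unscale_features <- function(scaler, X) {
  X <- as.matrix(X)
  if (scaler$mode == "minmax")
    sweep(sweep(X + 1, 2, (scaler$hi - scaler$lo) / 2, "*"), 2, scaler$lo, "+")
  else
    sweep(sweep(X, 2, scaler$sd, "*"), 2, scaler$mu, "+")
}

#' PCA-based outlier screen
#'
#' Scales the supplied matrix (inputs plus output), retains the leading
#' principal components explaining at least \code{var_explained} of the
#' variance, and standardises each retained score by a robust SD
#' (1.4826 x MAD). A row is flagged when its score distance
#' \eqn{\sqrt{\sum_j z_j^2}} exceeds \code{sd_threshold} times
#' \eqn{\sqrt{m}} for \eqn{m} retained components.
#'
#' @param X Numeric matrix/data frame, rows = observations.
#' @param sd_threshold Robust-SD multiplier (default 3).
#' @param var_explained Minimum cumulative variance retained (default 0.90).
#' @return Integer vector of flagged row indices (empty when clean), with the
#'   per-row distances in \code{attr(x, "distance")}.
#' @export
pca_outlier_screen <- function(X, sd_threshold = 3, var_explained = 0.90) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stop_domain("need more rows than columns for the PCA screen")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_domain("degenerate covariance: constant column in the screened matrix")
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (all(pca$sdev < 1e-12))
    stop_domain("degenerate covariance")
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  m <- which(cum >= var_explained)[1]
  scores <- pca$x[, seq_len(m), drop = FALSE]
  robust_sd <- apply(scores, 2, function(s) {
    r <- stats::mad(s)
    if (r < 1e-12) stats::sd(s) else r
  })
  z <- sweep(scores, 2, robust_sd, "/")
  dist <- sqrt(rowSums(z^2))
  flags <- which(dist > sd_threshold * sqrt(m))
  attr(flags, "distance") <- dist
  attr(flags, "n_components") <- m
  flags
}
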