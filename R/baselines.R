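# Linear regression comparators: multiple linear regression (and its
# ordinary-least-squares alias), bidirectional stepwise selection by
# partial-F tests, principal component regression, and NIPALS partial least
# squares. All five operate on the same Box-Cox-transformed response as the
# perceptron surrogate; predictions are back-transformed to original units.

#' Fit a linear regression baseline
#'
#' @param formula Model formula (raw inputs, no expansion).
#' @param data Training data frame.
#' @param method One of \code{"mlr"}, \code{"olsr"} (the same least-squares
#'   estimator under the customary second label), \code{"stepwise"},
#'   \code{"pcr"}, \code{"plsr"}.
#' @param boxcox_lambda,boxcox_offset Response transform, as in [mlpga()].
#' @param n_components Components for \code{"pcr"}/\code{"plsr"}. Defaults:
#'   PCR keeps the smallest number explaining at least 95\% of the feature
#'   variance; PLSR picks the count minimising an internal 5-fold CV RMSE.
#' @param alpha_enter,alpha_remove Partial-F entry/removal thresholds for
#'   \code{"stepwise"} (defaults 0.05 / 0.10).
#' @return An object of class \code{"running_lm"}: affine coefficients on the
#'   original features (on the transformed-response scale), the response
#'   transform, and fit metadata. Supports \code{predict}, \code{print},
#'   \code{coef}.
#' @export
fit_baseline <- function(formula, data,
                         method = c("mlr", "olsr", "stepwise", "pcr", "plsr"),
                         boxcox_lambda = NULL, boxcox_offset = 1,
                         n_components = NULL,
                         alpha_enter = 0.05, alpha_remove = 0.10) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  bc <- fit_boxcox(y, offset = boxcox_offset, lambda = boxcox_lambda)
  z <- boxcox_forward(bc, y)
  p <- ncol(X)

  fit <- switch(method,
    mlr = , olsr = ls_fit(X, z),
    stepwise = stepwise_fit(X, z, alpha_enter, alpha_remove),
    pcr = pcr_fit(X, z, n_components),
    plsr = plsr_fit(X, z, n_components))

  structure(list(method = method, coefficients = fit$beta,
                 intercept = fit$intercept, detail = fit$detail,
                 boxcox = bc, terms = attr(mf, "terms"),
                 feature_names = colnames(X), call = match.call()),
            class = "running_lm")
}

ls_fit <- function(X, z) {
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) stop_domain("rank-deficient design matrix")
  cf <- qr.coef(qrX, z)
  list(beta = cf[-1], intercept = cf[1], detail = list())
}

# bidirectional stepwise from the empty model, partial-F p-values
stepwise_fit <- function(X, z, alpha_enter, alpha_remove) {
  p <- ncol(X)
  active <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * p + 10L) break   # guard against entry/removal cycling
    changed <- FALSE
    # entry step
    candidates <- setdiff(seq_len(p), active)
    if (length(candidates)) {
      pv <- vapply(candidates, function(j) {
        d <- data.frame(z = z, X[, c(active, j), drop = FALSE])
        f <- stats::lm(z ~ ., data = d)
        stats::coef(summary(f))[nrow(stats::coef(summary(f))), 4]
      }, numeric(1))
      ord <- order(pv, candidates)
      if (pv[ord[1]] < alpha_enter) {
        active <- c(active, candidates[ord[1]])
        changed <- TRUE
      }
    }
    # removal step
    if (length(active) > 1 || (length(active) == 1 && !changed)) {
      d <- data.frame(z = z, X[, active, drop = FALSE])
      f <- stats::lm(z ~ ., data = d)
      pv <- stats::coef(summary(f))[-1, 4]
      worst <- which.max(pv)
      if (length(pv) && pv[worst] > alpha_remove) {
        active <- active[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  beta <- setNames(numeric(p), colnames(X))
  if (length(active)) {
    d <- data.frame(z = z, X[, active, drop = FALSE])
    f <- stats::lm(z ~ ., data = d)
    beta[active] <- stats::coef(f)[-1]
    intercept <- stats::coef(f)[1]
  } else intercept <- mean(z)
  list(beta = beta, intercept = unname(intercept),
       detail = list(selected = colnames(X)[active]))
}

pcr_fit <- function(X, z, n_components) {
  p <- ncol(X)
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (is.null(n_components)) {
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    n_components <- which(cum >= 0.95)[1]
  }
  if (n_components > p) stop_domain("n_components exceeds the number of features")
  S <- pca$x[, seq_len(n_components), drop = FALSE]
  f <- stats::lm(z ~ S)
  gamma <- stats::coef(f)[-1]
  V <- pca$rotation[, seq_len(n_components), drop = FALSE]
  beta <- drop(V %*% gamma) / pca$scale
  intercept <- stats::coef(f)[1] - sum(beta * pca$center)
  list(beta = setNames(beta, colnames(X)), intercept = unname(intercept),
       detail = list(n_components = n_components))
}

# NIPALS partial least squares for a single response; deterministic since the
# first weight vector is the cross-covariance direction X'y itself
nipals_pls <- function(X, z, a) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  zc <- z - mean(z)
  p <- ncol(X)
  W <- P <- matrix(0, p, a); q <- numeric(a)
  Xk <- Xc; zk <- zc
  for (k in seq_len(a)) {
    w <- drop(crossprod(Xk, zk))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { a <- k - 1L; break }
    w <- w / nw
    t_ <- drop(Xk %*% w)
    tt <- sum(t_^2)
    pk <- drop(crossprod(Xk, t_)) / tt
    qk <- sum(zk * t_) / tt
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    Xk <- Xk - tcrossprod(t_, pk)
    zk <- zk - qk * t_
  }
  if (a == 0) return(list(beta = setNames(numeric(p), colnames(X)),
                          intercept = mean(z)))
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  list(beta = setNames(beta, colnames(X)),
       intercept = mean(z) - sum(beta * colMeans(X)))
}

plsr_fit <- function(X, z, n_components) {
  p <- ncol(X)
  if (is.null(n_components)) {
    if (stats::var(z) == 0) stop_domain("zero-variance response")
    # internal 5-fold CV over 1..p components (deterministic split)
    n <- nrow(X)
    fold <- rep_len(seq_len(5), n)
    rmse <- vapply(seq_len(p), function(a) {
      errs <- unlist(lapply(seq_len(5), function(f) {
        te <- which(fold == f); tr <- which(fold != f)
        m <- nipals_pls(X[tr, , drop = FALSE], z[tr], a)
        drop(X[te, , drop = FALSE] %*% m$beta) + m$intercept - z[te]
      }))
      sqrt(mean(errs^2))
    }, numeric(1))
    n_components <- which.min(rmse)
  }
  if (n_components > p) stop_domain("n_components exceeds the number of features")
  m <- nipals_pls(X, z, n_components)
  list(beta = m$beta, intercept = m$intercept,
       detail = list(n_components = n_components))
}

#' @export
predict.running_lm <- function(object, newdata = NULL, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  z <- drop(X %*% object$coefficients) + object$intercept
  lam <- object$boxcox$lambda
  if (lam >= 1e-12) z <- pmax(z, (1e-9 - 1) / lam)
  else if (lam <= -1e-12) z <- pmin(z, (1e-9 - 1) / lam)
  unname(boxcox_inverse(object$boxcox, z))
}

#' @export
coef.running_lm <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.running_lm <- function(x, ...) {
  cat(sprintf("Linear baseline (%s) on Box-Cox scale (lambda %.4f)\n",
              toupper(x$method), x$boxcox$lambda))
  print(signif(coef(x), 5))
  invisible(x)
}
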