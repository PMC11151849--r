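#' Fit a perceptron surrogate of mycelial running
#'
#' Fits the package's core model: a single-hidden-layer perceptron (tanh
#' hidden units, linear output) predicting a growth response -- running
#' length (cm) or running rate (cm d^-1) -- from substrate-component ratios
#' and, for running length, the running time. The response is Box-Cox
#' transformed (offset 1, power estimated by profile likelihood unless fixed)
#' and standardised; inputs are min-max scaled to [-1, 1]; training is
#' full-batch adaptive gradient descent with early stopping. Predictions are
#' returned in original units.
#'
#' @param formula Model formula, e.g.
#'   \code{rl_cm ~ bagasse_pct + wheatbran_pct + beechsawdust_pct + time_days}.
#' @param data Data frame of replicate-level observations.
#' @param n_hidden Number of hidden units. Use [search_hidden_neurons()] to
#'   choose it by genetic-algorithm architecture search.
#' @param boxcox_lambda Fixed Box-Cox power, or \code{NULL} to estimate it.
#' @param boxcox_offset Additive shift before the power transform (default 1,
#'   accommodating the non-growing control's exact zeros).
#' @param config A [train_config()].
#' @return An object of class \code{"mlpga"} supporting \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals} and \code{plot}.
#' @examples
#' d <- simulate_rr(config = sim_config(seed = 7))
#' fit <- mlpga(rr_cm_per_day ~ bagasse_pct + wheatbran_pct + beechsawdust_pct,
#'              d, n_hidden = 6, config = train_config(max_epochs = 150))
#' summary(fit)
#' @export
mlpga <- function(formula, data, n_hidden = 8L, boxcox_lambda = NULL,
                  boxcox_offset = 1, config = train_config()) {
  mf <- stats::model.frame(formula, data)
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]

  bc <- fit_boxcox(y, offset = boxcox_offset, lambda = boxcox_lambda)
  z <- boxcox_forward(bc, y)
  z_center <- mean(z); z_scale <- stats::sd(z)
  if (z_scale == 0) stop_domain("response is constant after transformation")
  scaler <- fit_scaler(X, "minmax")

  net <- init_mlp(ncol(X), n_hidden, seed = config$seed)
  net <- train_mlp(net, scale_features(scaler, X), (z - z_center) / z_scale, config)

  fit <- structure(list(
    net = net, scaler = scaler, boxcox = bc,
    z_center = z_center, z_scale = z_scale,
    n_hidden = as.integer(n_hidden), config = config,
    terms = attr(mf, "terms"), call = match.call(),
    feature_names = colnames(X), y = y), class = "mlpga")
  fit$fitted <- predict(fit, data)
  fit$metrics <- fit_metrics(y, fit$fitted)
  fit
}

#' Predict from a fitted running surrogate
#'
#' @param object An \code{"mlpga"} fit.
#' @param newdata Data frame with the model's input columns; when missing,
#'   the training data predictions are returned.
#' @param ... Unused.
#' @return Predictions in original units (cm or cm d^-1).
#' @export
predict.mlpga <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  z <- mlp_forward(object$net, scale_features(object$scaler, X)) *
    object$z_scale + object$z_center
  # clip into the image of the forward transform before inverting
  lam <- object$boxcox$lambda
  if (lam >= 1e-12) z <- pmax(z, (1e-9 - 1) / lam)
  else if (lam <= -1e-12) z <- pmin(z, (1e-9 - 1) / lam)
  unname(boxcox_inverse(object$boxcox, z))
}

# fast path used by the GA: X is a numeric matrix whose columns are already
# the model's inputs, in order
predict_matrix <- function(object, X) {
  colnames(X) <- object$feature_names
  z <- mlp_forward(object$net, scale_features(object$scaler, X)) *
    object$z_scale + object$z_center
  lam <- object$boxcox$lambda
  if (lam >= 1e-12) z <- pmax(z, (1e-9 - 1) / lam)
  else if (lam <= -1e-12) z <- pmin(z, (1e-9 - 1) / lam)
  boxcox_inverse(object$boxcox, z)
}

#' @export
fitted.mlpga <- function(object, ...) object$fitted

#' @export
residuals.mlpga <- function(object, ...) object$y - object$fitted

#' @export
coef.mlpga <- function(object, ...) {
  list(W1 = object$net$W1, b1 = object$net$b1,
       W2 = object$net$W2, b2 = object$net$b2)
}

#' @export
print.mlpga <- function(x, ...) {
  cat("Perceptron surrogate of mycelial running (MLP-GA pipeline)\n")
  cat("  inputs :", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  network: %d-%d-1 (tanh hidden, linear output)\n",
              x$net$n_inputs, x$net$n_hidden))
  cat(sprintf("  Box-Cox: lambda = %.4f, offset = %g\n",
              x$boxcox$lambda, x$boxcox$offset))
  cat(sprintf("  training R2 = %.4f, RMSE = %.4f\n", x$metrics$r2, x$metrics$rmse))
  invisible(x)
}

#' @export
summary.mlpga <- function(object, ...) {
  structure(list(call = object$call, feature_names = object$feature_names,
                 n_hidden = object$net$n_hidden, n_obs = length(object$y),
                 boxcox = object$boxcox, metrics = object$metrics,
                 epochs_run = length(object$net$loss_history),
                 seed = object$config$seed),
            class = "summary.mlpga")
}

#' @export
print.summary.mlpga <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d observations; inputs: %s\n", x$n_obs,
              paste(x$feature_names, collapse = ", ")))
  cat(sprintf("Hidden units: %d   epochs run: %d   seed: %d\n",
              x$n_hidden, x$epochs_run, x$seed))
  cat(sprintf("Box-Cox lambda %.4f (offset %g)\n", x$boxcox$lambda, x$boxcox$offset))
  cat(sprintf("Training fit: R2 %.4f | RMSE %.4f | MAE %.4f | MAPE %.2f%%\n",
              x$metrics$r2, x$metrics$rmse, x$metrics$mae, x$metrics$mape))
  invisible(x)
}

#' @export
plot.mlpga <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "observed", ylab = "predicted",
                 main = "Observed vs predicted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Save / load a fitted surrogate as JSON
#'
#' Serialises the network weights, scaler, Box-Cox parameters and training
#' seed to a JSON document at full double precision, so a reloaded model
#' reproduces the original's predictions exactly.
#'
#' @param object An \code{"mlpga"} fit.
#' @param path JSON file path.
#' @return \code{write_mlpga}: invisibly, \code{path}.
#' @export
write_mlpga <- function(object, path) {
  doc <- list(
    feature_names = object$feature_names,
    n_inputs = object$net$n_inputs, n_hidden = object$net$n_hidden,
    W1 = object$net$W1, b1 = object$net$b1,
    W2 = as.numeric(object$net$W2), b2 = object$net$b2,
    scaler = list(mode = object$scaler$mode, lo = object$scaler$lo,
                  hi = object$scaler$hi, mu = object$scaler$mu,
                  sd = object$scaler$sd, features = object$scaler$features),
    boxcox = list(lambda = object$boxcox$lambda, offset = object$boxcox$offset),
    z_center = object$z_center, z_scale = object$z_scale,
    seed = object$config$seed,
    response = deparse(object$terms[[2]]))
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlpga
#' @return \code{read_mlpga}: an \code{"mlpga"}-like predictor (class
#'   \code{"mlpga"}) restoring the saved weights and transforms.
#' @export
read_mlpga <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(
    n_inputs = as.integer(doc$n_inputs), n_hidden = as.integer(doc$n_hidden),
    W1 = matrix(doc$W1, doc$n_inputs, doc$n_hidden),
    b1 = as.numeric(doc$b1),
    W2 = matrix(doc$W2, doc$n_hidden, 1), b2 = doc$b2,
    activation = "tansig", seed = as.integer(doc$seed)), class = "mlp")
  scaler <- structure(list(mode = doc$scaler$mode, lo = doc$scaler$lo,
                           hi = doc$scaler$hi, mu = doc$scaler$mu,
                           sd = doc$scaler$sd, features = doc$scaler$features),
                      class = "feature_scaler")
  fmla <- stats::reformulate(doc$feature_names, response = doc$response)
  structure(list(net = net, scaler = scaler,
                 boxcox = structure(doc$boxcox, class = "boxcox_transform"),
                 z_center = doc$z_center, z_scale = doc$z_scale,
                 n_hidden = as.integer(doc$n_hidden),
                 config = train_config(seed = doc$seed),
                 terms = stats::terms(fmla),
                 call = call("read_mlpga", path),
                 feature_names = doc$feature_names, y = NULL, fitted = NULL),
            class = "mlpga")
}
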