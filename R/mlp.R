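# Single-hidden-layer perceptron: tanh hidden units, linear output, trained by
# full-batch gradient descent with adaptive moment estimates and early
# stopping on a held-out validation split.

#' Training settings for the perceptron
#'
#' @param seed Integer seed controlling weight initialisation and the
#'   validation split.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param learning_rate Step size of the adaptive-moment update.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   the validation MSE.
#' @param validation_fraction Fraction of rows held out for early stopping
#'   (0 disables early stopping).
#' @return An object of class \code{"train_config"}.
#' @export
train_config <- function(seed = 1L, max_epochs = 600L, learning_rate = 0.02,
                         patience = 40L, validation_fraction = 0.15) {
  stopifnot(max_epochs >= 0, learning_rate > 0, patience >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Data-size-scaled training settings
#'
#' Full-batch training cost grows linearly with the number of rows while
#' small datasets need more epochs to converge, so the default epoch budget
#' scales inversely with the dataset size: roughly one million row-epochs,
#' clamped to [600, 4000] epochs, with early-stopping patience at 7.5\% of
#' the budget. The replicate-level running-length table (2,048 rows) thus
#' trains for up to 600 epochs and the running-rate table (256 rows) to full
#' convergence at up to 4,000.
#'
#' @param n_rows Number of training rows.
#' @param seed Integer seed.
#' @return A [train_config()].
#' @export
default_train_config <- function(n_rows, seed = 1L) {
  epochs <- max(600L, min(4000L, as.integer(round(1e6 / n_rows))))
  train_config(seed = seed, max_epochs = epochs,
               patience = max(30L, as.integer(round(0.075 * epochs))))
}

#' Initialise a single-hidden-layer perceptron
#'
#' Weights are drawn uniformly on the Glorot interval
#' \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}, biases start at zero; the draw is
#' deterministic for a given seed.
#'
#' @param n_inputs Number of input units.
#' @param n_hidden Number of tanh hidden units (>= 1).
#' @param seed Integer seed.
#' @return An object of class \code{"mlp"} with weight matrices \code{W1}
#'   (inputs x hidden), \code{b1}, \code{W2} (hidden x 1) and \code{b2}.
#' @export
init_mlp <- function(n_inputs, n_hidden, seed = 1L) {
  if (n_inputs < 1 || n_hidden < 1)
    stop_domain("n_inputs and n_hidden must be positive")
  with_seed(seed, {
    r1 <- sqrt(6 / (n_inputs + n_hidden))
    r2 <- sqrt(6 / (n_hidden + 1))
    structure(list(
      n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
      W1 = matrix(stats::runif(n_inputs * n_hidden, -r1, r1), n_inputs, n_hidden),
      b1 = numeric(n_hidden),
      W2 = matrix(stats::runif(n_hidden, -r2, r2), n_hidden, 1),
      b2 = 0,
      activation = "tansig", seed = as.integer(seed)),
      class = "mlp")
  })
}

#' Forward pass of the perceptron
#'
#' Computes \eqn{y = W_2 \tanh(W_1 x + b_1) + b_2} on scaled inputs.
#'
#' @param model An \code{"mlp"}.
#' @param X Matrix of scaled inputs (rows = observations) or a single row.
#' @return Numeric vector of scaled outputs.
#' @export
mlp_forward <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != model$n_inputs)
    stop_domain(sprintf("input has %d columns; model expects %d", ncol(X), model$n_inputs))
  H <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  drop(H %*% model$W2 + model$b2)
}

#' Train the perceptron by full-batch adaptive gradient descent
#'
#' Minimises the mean squared error on (already scaled/transformed) targets.
#' A validation split is held out for early stopping; the weights achieving
#' the best validation MSE are restored at the end. Training is deterministic
#' given (model, data, config).
#'
#' @param model An initialised \code{"mlp"}.
#' @param X Scaled input matrix.
#' @param y Transformed target vector.
#' @param config A [train_config()].
#' @return The trained \code{"mlp"}, with the per-epoch training loss in
#'   \code{$loss_history} and the restored validation loss in \code{$val_loss}.
#' @export
train_mlp <- function(model, X, y, config = train_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_domain("X and y lengths differ")
  if (config$max_epochs == 0) {
    model$loss_history <- numeric(0)
    return(model)
  }
  if (length(y) < 10) stop_domain("need at least 10 rows to train")
  n <- length(y)
  n_val <- floor(config$validation_fraction * n)
  idx <- with_seed(config$seed, sample.int(n))
  val <- idx[seq_len(n_val)]
  tr <- if (n_val > 0) idx[-seq_len(n_val)] else idx
  Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
  Xv <- X[val, , drop = FALSE]; yv <- y[val]

  theta <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2)
  m <- lapply(theta, function(p) p * 0)
  v <- lapply(theta, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  best <- theta; best_val <- Inf; wait <- 0L
  loss_hist <- numeric(config$max_epochs)
  nt <- nrow(Xt)

  for (epoch in seq_len(config$max_epochs)) {
    A <- sweep(Xt %*% theta$W1, 2, theta$b1, "+")
    H <- tanh(A)
    pred <- drop(H %*% theta$W2 + theta$b2)
    err <- pred - yt
    loss <- mean(err^2)
    if (!is.finite(loss))
      stop_domain(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
    loss_hist[epoch] <- loss

    d_out <- 2 * err / nt                      # d loss / d pred
    g <- list(
      W1 = crossprod(Xt, (d_out %o% drop(theta$W2)) * (1 - H^2)),
      b1 = colSums((d_out %o% drop(theta$W2)) * (1 - H^2)),
      W2 = crossprod(H, d_out),
      b2 = sum(d_out))
    for (k in names(theta)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
      mhat <- m[[k]] / (1 - beta1^epoch)
      vhat <- v[[k]] / (1 - beta2^epoch)
      theta[[k]] <- theta[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }

    if (n_val > 0) {
      vpred <- drop(tanh(sweep(Xv %*% theta$W1, 2, theta$b1, "+")) %*% theta$W2 + theta$b2)
      vloss <- mean((vpred - yv)^2)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; best <- theta; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { loss_hist <- loss_hist[seq_len(epoch)]; break }
      }
    } else best <- theta
  }
  model$W1 <- best$W1; model$b1 <- best$b1; model$W2 <- best$W2; model$b2 <- best$b2
  model$loss_history <- loss_hist
  model$val_loss <- if (n_val > 0) best_val else NA_real_
  model
}

#' Regression fit metrics
#'
#' Standard goodness-of-fit statistics: coefficient of determination
#' \eqn{R^2}, root mean square error, mean absolute error, and the mean
#' absolute percentage error computed over rows with a nonzero observed value
#' (the non-growing control would otherwise divide by zero).
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values (same length).
#' @return List with elements \code{r2}, \code{rmse}, \code{mae}, \code{mape}.
#' @export
fit_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_domain("length mismatch")
  if (length(y_true) < 2) stop_domain("need at least 2 observations")
  err <- y_true - y_pred
  nz <- y_true != 0
  list(r2 = r2_score(y_true, y_pred),
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       mape = if (any(nz)) mean(abs(err[nz] / y_true[nz])) * 100 else NA_real_)
}
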