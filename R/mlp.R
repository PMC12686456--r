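#' Specification of a regularized MLP member
#'
#' The default architecture follows the input width: two ReLU hidden layers
#' of sizes `2 * n_in` and `n_in`, a single sigmoid output unit, L2 penalty
#' 0.001 on weights, inverted dropout 0.2 after each hidden layer, Adam
#' (lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8), batch size 16, up to 100
#' epochs with early-stopping patience 10 on a held-out validation split.
#'
#' @param n_in Input width (after any one-hot expansion).
#' @param hidden Integer vector of hidden layer sizes.
#' @param l2_lambda L2 coefficient.
#' @param dropout_rate Dropout rate in \[0, 1).
#' @param learning_rate,beta1,beta2,adam_eps Adam parameters.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping; `NULL` disables early stopping (no validation split).
#' @param validation_fraction Share of rows held out for validation.
#' @param seed Integer seed (weights, shuffling, dropout).
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(n_in, hidden = c(2 * n_in, n_in), l2_lambda = 0.001,
                     dropout_rate = 0.2, learning_rate = 0.001,
                     beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                     batch_size = 16, epochs = 100,
                     early_stopping_patience = 10,
                     validation_fraction = 0.2, seed = 1L) {
  if (n_in < 1 || any(hidden < 1)) stop("layer sizes must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_in = as.integer(n_in), hidden = as.integer(hidden),
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping_patience = early_stopping_patience,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Train a regularized MLP
#'
#' Mini-batch Adam on mean binary cross-entropy plus the L2 weight penalty,
#' with inverted dropout during training. When early stopping is active a
#' stratified validation split is carved from the data, training halts once
#' validation loss fails to improve for `early_stopping_patience` epochs,
#' and the parameters are restored to the best epoch. Fully deterministic
#' under `spec$seed`.
#'
#' @param spec An [mlp_spec()].
#' @param X Numeric matrix, n x `spec$n_in`.
#' @param y 0/1 labels, length n.
#' @return An object of class `trained_mlp` with fields `W`, `b`,
#'   `train_loss`, `val_loss`, `best_epoch`, `spec`.
#' @export
train_mlp <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != spec$n_in) stop("shape error: X width != spec$n_in")
  if (length(unique(y)) < 2) stop("training data contains a single class")
  use_val <- !is.null(spec$early_stopping_patience)
  if (use_val) {
    folds <- stratified_folds(y, max(2L, round(1 / spec$validation_fraction)),
                              seed = derive_seed(spec$seed, 77L))
    val <- folds == 1L
    if (length(unique(y[!val])) < 2) stop("training split lost a class")
    Xtr <- X[!val, , drop = FALSE]; ytr <- y[!val]
    Xval <- X[val, , drop = FALSE]; yval <- y[val]
    patience <- as.integer(spec$early_stopping_patience)
  } else {
    Xtr <- X; ytr <- y
    Xval <- matrix(0, 0, ncol(X)); yval <- numeric(0)
    patience <- spec$epochs
  }
  fit <- cpp_mlp_train(Xtr, ytr, Xval, yval, spec$hidden, spec$l2_lambda,
                       spec$dropout_rate, spec$learning_rate, spec$beta1,
                       spec$beta2, spec$adam_eps, spec$batch_size,
                       spec$epochs, patience, spec$seed)
  structure(list(W = fit$W, b = fit$b, train_loss = fit$train_loss,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch,
                 spec = spec),
            class = "trained_mlp")
}

#' Forward pass of a trained MLP
#'
#' Dropout is disabled at inference; output is the sigmoid class-1
#' probability.
#'
#' @param mlp A `trained_mlp`.
#' @param X Numeric matrix with `spec$n_in` columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
mlp_forward <- function(mlp, X) {
  as.numeric(cpp_mlp_forward(mlp$W, mlp$b, as.matrix(X)))
}

#' @export
predict.trained_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Binary cross-entropy with L2 penalty
#'
#' Mean BCE over the batch (predictions clipped to
#' \[1e-12, 1 - 1e-12\]) plus `lambda` times the sum of squared weights;
#' biases are not penalized.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param weights List of weight matrices entering the penalty (may be
#'   empty).
#' @param lambda L2 coefficient.
#' @return Scalar loss.
#' @export
bce_l2_loss <- function(y, p, weights = list(), lambda = 0) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  bce + lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
}

# Analytic loss + gradient for a parameter set; used by the
# finite-difference correctness tests. `masks` freezes dropout.
mlp_loss_grad <- function(W, b, X, y, lambda = 0, masks = NULL) {
  cpp_mlp_loss_grad(W, b, as.matrix(X), as.numeric(y), lambda, masks)
}

mlp_loss_value <- function(W, b, X, y, lambda = 0, masks = NULL) {
  cpp_mlp_loss(W, b, as.matrix(X), as.numeric(y), lambda, masks)
}

# He-normal initial parameters (exposed for the gradient tests).
mlp_init_params <- function(n_in, hidden, seed = 1L) {
  cpp_mlp_init(as.integer(c(n_in, hidden, 1L)), as.integer(seed))
}
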