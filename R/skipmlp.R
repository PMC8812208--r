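#' Training configuration
#'
#' Hyperparameters for the learned predictors.  Defaults follow the
#' reference training recipe: ADAM with learning rate 0.001 and global
#' gradient-norm clipping at 1.0, 25 epochs, batch size 128 for the
#' stochastic ridge solver and 32 for the network, ridge penalty 0.1, four
#' hidden layers of 50 ReLU units with dropout 0.25 on the hidden
#' activations, and five-member ensembles.
#'
#' @param learning_rate ADAM learning rate.
#' @param grad_norm_clip Global gradient-norm clip (0 disables).
#' @param epochs Training epochs (>= 0; 0 leaves the network at its random
#'   initialization).
#' @param batch_size_ridge Minibatch size for the SGD ridge solver.
#' @param batch_size_mlp Minibatch size for the network.
#' @param ridge_lambda Ridge penalty.
#' @param hidden_width Hidden-layer width.
#' @param n_hidden Number of hidden layers (the network "depth"; sweepable
#'   2-8).
#' @param dropout Dropout rate on hidden activations during training, in
#'   [0, 1).
#' @param weight_decay L2 penalty on the network weights during training
#'   (default 0: dropout is the only regularizer, as in the reference
#'   recipe).
#' @param ensemble_size Number of ensemble members.
#' @param target_transform \code{"none"} (train in raw Euros; default) or
#'   \code{"log1p"}.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.001, grad_norm_clip = 1.0,
                         epochs = 25, batch_size_ridge = 128,
                         batch_size_mlp = 32, ridge_lambda = 0.1,
                         hidden_width = 50, n_hidden = 4, dropout = 0.25,
                         weight_decay = 0, ensemble_size = 5,
                         target_transform = c("none", "log1p"),
                         seed = 1L) {
  target_transform <- match.arg(target_transform)
  if (learning_rate <= 0) stop_cfg("learning_rate must be positive")
  if (epochs < 0) stop_cfg("epochs must be >= 0")
  if (dropout < 0 || dropout >= 1) stop_cfg("dropout must be in [0, 1)")
  for (nm in c("batch_size_ridge", "batch_size_mlp", "hidden_width",
               "n_hidden", "ensemble_size"))
    if (get(nm) < 1) stop_cfg("%s must be >= 1", nm)
  structure(list(learning_rate = learning_rate,
                 grad_norm_clip = grad_norm_clip,
                 epochs = as.integer(epochs),
                 batch_size_ridge = as.integer(batch_size_ridge),
                 batch_size_mlp = as.integer(batch_size_mlp),
                 ridge_lambda = ridge_lambda,
                 hidden_width = as.integer(hidden_width),
                 n_hidden = as.integer(n_hidden),
                 dropout = dropout,
                 weight_decay = weight_decay,
                 ensemble_size = as.integer(ensemble_size),
                 target_transform = target_transform,
                 seed = as.integer(seed)), class = "train_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

as_sparse <- function(x) {
  methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

#' Fit the skip-connection multilayer perceptron
#'
#' Trains a multilayer perceptron on the sparse claims features:
#' \code{n_hidden} ReLU layers of \code{hidden_width} units, after which the
#' raw input is concatenated to the last hidden vector and fed to a linear
#' output layer with seven neurons (one per cost category).  The skip
#' concatenation means the network decomposes into an affine map of the
#' input plus a learned nonlinear correction.  Training minimizes the
#' squared error summed over the seven outputs with minibatch ADAM, global
#' gradient-norm clipping and inverted dropout on the hidden activations
#' (inference uses no dropout).  Given a seed the fit is deterministic
#' (single-threaded).
#'
#' Targets are internally centred and scaled per category (the inverse map
#' is applied at prediction time), and numeric design columns are scaled to
#' unit spread when column kinds are available from a \code{claims_design};
#' one-hot count columns are left untouched.
#'
#' @param x Sparse design matrix or \code{claims_design}.
#' @param y Target matrix (patients x 7, Euro); taken from \code{x} when a
#'   \code{claims_design} is given.
#' @param config A \code{\link{train_config}}.
#' @param standardize Standardize targets (and numeric columns) internally
#'   (default TRUE).
#' @return An object of class \code{skip_mlp}.
#' @export
fit_skip_mlp <- function(x, y = NULL, config = train_config(),
                         standardize = TRUE) {
  stopifnot(inherits(config, "train_config"))
  col_kind <- NULL
  if (inherits(x, "claims_design")) {
    if (is.null(y)) y <- x$Y
    col_kind <- x$columns$kind
    x <- x$X
  }
  X <- as_sparse(x)
  Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) stop_cfg("X and Y are not row-aligned")
  if (any(!is.finite(X@x)) || any(!is.finite(Y)))
    stop_cfg("non-finite values in X or Y")
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  h <- config$hidden_width; L <- config$n_hidden

  col_scale <- rep(1, p)
  if (standardize && !is.null(col_kind)) {
    num <- which(col_kind == "numeric")
    for (j in num) {
      cs <- sd(X[, j])
      if (is.finite(cs) && cs > 1e-8) col_scale[j] <- cs
    }
  }
  Xs <- if (any(col_scale != 1)) X %*% Matrix::Diagonal(x = 1 / col_scale) else X
  Xs <- as_sparse(Xs)

  if (config$target_transform == "log1p") Y <- log1p(Y)
  if (standardize) {
    y_center <- colMeans(Y)
    y_scale <- pmax(apply(Y, 2, sd), 1e-8)
  } else {
    y_center <- rep(0, k); y_scale <- rep(1, k)
  }
  Yt <- sweep(sweep(Y, 2, y_center), 2, y_scale, `/`)

  set.seed(config$seed)
  W_hidden <- vector("list", L)
  b_hidden <- vector("list", L)
  for (l in seq_len(L)) {
    W_hidden[[l]] <- if (l == 1) glorot(p, h) else glorot(h, h)
    b_hidden[[l]] <- rep(0, h)
  }
  init <- list(W_hidden = W_hidden, b_hidden = b_hidden,
               W_top = if (L > 0) glorot(h, k) else matrix(0, 0, 0),
               W_skip = glorot(p, k), b_out = rep(0, k))

  fit <- cpp_train_skipmlp(Matrix::t(Xs), Yt, init,
                           lr = config$learning_rate,
                           clip = config$grad_norm_clip,
                           epochs = config$epochs,
                           batch = config$batch_size_mlp,
                           dropout = config$dropout,
                           lambda = config$weight_decay %||% 0)

  structure(list(
    W_hidden = fit$W_hidden, b_hidden = lapply(fit$b_hidden, as.numeric),
    W_top = fit$W_top, W_skip = fit$W_skip, b_out = as.numeric(fit$b_out),
    n_hidden = L, hidden_width = h,
    col_scale = col_scale, y_center = y_center, y_scale = y_scale,
    target_transform = config$target_transform,
    categories = colnames(Y) %||% COST_CATEGORIES[seq_len(k)],
    feature_names = colnames(X),
    loss = as.numeric(fit$loss), config = config, n_train = n,
    p = p), class = "skip_mlp")
}

# forward pass without dropout; returns list of hidden activations and the
# output on the *standardized* scale
mlp_forward <- function(object, Xs) {
  L <- object$n_hidden
  H <- vector("list", L)
  prev <- NULL
  for (l in seq_len(L)) {
    Z <- if (l == 1) as.matrix(Xs %*% object$W_hidden[[l]])
         else prev %*% object$W_hidden[[l]]
    Z <- sweep(Z, 2, object$b_hidden[[l]], `+`)
    H[[l]] <- pmax(Z, 0)
    prev <- H[[l]]
  }
  out <- as.matrix(Xs %*% object$W_skip)
  if (L > 0) out <- out + H[[L]] %*% object$W_top
  out <- sweep(out, 2, object$b_out, `+`)
  list(H = H, out = out)
}

scale_input <- function(object, newdata) {
  X <- if (inherits(newdata, "claims_design")) newdata$X else newdata
  X <- as_sparse(X)
  if (ncol(X) != object$p)
    stop_cfg("input has %d features, model expects %d", ncol(X), object$p)
  if (any(object$col_scale != 1))
    X <- as_sparse(X %*% Matrix::Diagonal(x = 1 / object$col_scale))
  X
}

#' @export
predict.skip_mlp <- function(object, newdata, ...) {
  Xs <- scale_input(object, newdata)
  out <- mlp_forward(object, Xs)$out
  out <- sweep(sweep(out, 2, object$y_scale, `*`), 2, object$y_center, `+`)
  if (object$target_transform == "log1p") out <- expm1(out)
  colnames(out) <- object$categories
  rownames(out) <- rownames(newdata) %||% rownames(Xs)
  out
}

#' @export
print.skip_mlp <- function(x, ...) {
  cat(sprintf(
    "Skip-connection MLP: %d inputs -> %s -> 7 outputs (input concatenated into last layer)\n",
    x$p, paste(rep(x$hidden_width, x$n_hidden), collapse = "-")))
  cat(sprintf("  trained %d epochs on n = %d; final loss %.4f\n",
              length(x$loss), x$n_train,
              if (length(x$loss)) x$loss[length(x$loss)] else NA))
  invisible(x)
}

#' @export
summary.skip_mlp <- function(object, ...) {
  n_par <- sum(vapply(object$W_hidden, length, 0L)) +
    sum(vapply(object$b_hidden, length, 0L)) +
    length(object$W_top) + length(object$W_skip) + length(object$b_out)
  cat(sprintf("Skip-connection MLP (%d hidden layers x %d units, %d parameters)\n",
              object$n_hidden, object$hidden_width, n_par))
  cat(sprintf("  config: lr %.4g, clip %.3g, epochs %d, batch %d, dropout %.2f, seed %d\n",
              object$config$learning_rate, object$config$grad_norm_clip,
              object$config$epochs, object$config$batch_size_mlp,
              object$config$dropout, object$config$seed))
  if (length(object$loss)) {
    cat("  loss by epoch (standardized scale):\n")
    print(round(object$loss, 4))
  }
  invisible(object)
}

#' @export
coef.skip_mlp <- function(object, ...) {
  # affine (skip-path) component on the raw-input / Euro scale
  W <- object$W_skip * outer(1 / object$col_scale, object$y_scale)
  dimnames(W) <- list(object$feature_names, object$categories)
  W
}

#' @export
residuals.skip_mlp <- function(object, x, y = NULL, ...) {
  if (inherits(x, "claims_design")) y <- y %||% x$Y
  y - predict(object, x)
}

#' Fit an ensemble of skip-connection networks
#'
#' Trains the identical architecture \code{size} times on the same data
#' with different seeds; predictions of the members are averaged (see
#' \code{\link{ensemble_predict}}).
#'
#' @param x,y,config,standardize As in \code{\link{fit_skip_mlp}}.
#' @param size Number of members (default \code{config$ensemble_size}).
#' @return List of \code{skip_mlp} fits, class \code{mlp_ensemble}.
#' @export
fit_skip_mlp_ensemble <- function(x, y = NULL, config = train_config(),
                                  size = config$ensemble_size,
                                  standardize = TRUE) {
  members <- vector("list", size)
  for (s in seq_len(size)) {
    cfg <- config
    cfg$seed <- config$seed + (s - 1L) * 1000L
    members[[s]] <- fit_skip_mlp(x, y, cfg, standardize = standardize)
  }
  structure(members, class = "mlp_ensemble")
}

#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  preds <- lapply(unclass(object), function(m) predict(m, newdata))
  Reduce(`+`, preds) / length(preds)
}

#' Gradient of the model output with respect to the input
#'
#' Returns, for each row of \code{P}, the gradient of the weighted sum of
#' the model's category outputs (Euro scale) with respect to the raw input
#' features.  Used by integrated gradients.
#'
#' @param model A fitted \code{skip_mlp} or \code{ridge_cost}.
#' @param P Input matrix (rows are evaluation points).
#' @param weights Numeric weight per category output (default: 1 for every
#'   category not excluded from the assembled total).
#' @return Dense matrix with the same shape as \code{P}.
#' @export
input_gradient <- function(model, P, weights = NULL) UseMethod("input_gradient")

output_weights <- function(categories, weights = NULL,
                           excluded = EXCLUDED_DEFAULT) {
  if (is.null(weights)) weights <- as.numeric(!(categories %in% excluded))
  if (length(weights) != length(categories))
    stop_cfg("need %d output weights, got %d", length(categories),
             length(weights))
  weights
}

# mean (over rows of P) backpropagated deltas; shared by input_gradient and
# the integrated-gradients fast path
mlp_deltas <- function(object, Xs, w_eff) {
  fw <- mlp_forward(object, Xs)
  L <- object$n_hidden
  m <- nrow(Xs)
  d_out <- matrix(w_eff, m, length(w_eff), byrow = TRUE)
  dZ <- vector("list", L)
  if (L > 0) {
    dH <- d_out %*% t(object$W_top)
    for (l in rev(seq_len(L))) {
      dZ[[l]] <- dH * (fw$H[[l]] > 0)
      if (l > 1) dH <- dZ[[l]] %*% t(object$W_hidden[[l]])
    }
  }
  list(d_out = d_out, dZ = dZ)
}

#' @export
input_gradient.skip_mlp <- function(model, P, weights = NULL) {
  w <- output_weights(model$categories, weights)
  w_eff <- w * model$y_scale
  if (model$target_transform != "none")
    stop_cfg("input gradients are only defined for target_transform = 'none'")
  Xs <- scale_input(model, P)
  dl <- mlp_deltas(model, Xs, w_eff)
  G <- dl$d_out %*% t(model$W_skip)
  if (model$n_hidden > 0) G <- G + dl$dZ[[1]] %*% t(model$W_hidden[[1]])
  sweep(G, 2, model$col_scale, `/`)
}

#' @export
input_gradient.ridge_cost <- function(model, P, weights = NULL) {
  w <- output_weights(colnames(model$W), weights)
  g <- as.numeric(model$W %*% w)
  matrix(g, nrow(P), length(g), byrow = TRUE)
}
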