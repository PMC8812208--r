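#' Multivariate ridge regression for the seven cost categories
#'
#' Fits the two-stage linear predictor: a ridge regression mapping the
#' sparse claims features to the seven per-category evaluation costs, whose
#' predictions are then summed (minus the excluded category) into the total.
#' The objective is \deqn{\frac{1}{n}\|Y - XW - b\|_F^2 + \lambda\|W\|_F^2}
#' with the intercept unpenalized.  \code{solver = "closed_form"} solves the
#' penalized normal equations exactly (in the primal when the feature count
#' is at most the sample count, otherwise through the mathematically
#' identical dual/kernel form).  \code{solver = "sgd"} minimizes the same
#' objective with minibatch ADAM (learning rate, gradient-norm clipping,
#' epochs and the ridge batch size taken from \code{config}), mirroring how
#' the model is trained at population scale.
#'
#' @param x Sparse/dense design matrix (patients x features) or a
#'   \code{claims_design}.
#' @param y Target matrix (patients x categories); taken from \code{x} when
#'   a \code{claims_design} is given.
#' @param lambda Ridge penalty (default 0.1).
#' @param solver \code{"closed_form"} (default) or \code{"sgd"}.
#' @param config A \code{\link{train_config}} (used by the SGD solver).
#' @param intercept Fit an unpenalized intercept (default TRUE).
#' @return An object of class \code{ridge_cost} with weight matrix \code{W}
#'   (features x categories) and intercept \code{b}.
#' @export
fit_ridge <- function(x, y = NULL, lambda = 0.1,
                      solver = c("closed_form", "sgd"),
                      config = train_config(), intercept = TRUE) {
  solver <- match.arg(solver)
  if (inherits(x, "claims_design")) {
    if (is.null(y)) y <- x$Y
    x <- x$X
  }
  X <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) stop_cfg("X and Y are not row-aligned")
  if (any(!is.finite(X@x)) || any(!is.finite(Y)))
    stop_cfg("non-finite values in X or Y")
  if (lambda < 0) stop_cfg("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)

  if (solver == "sgd") {
    set.seed(config$seed)
    fit <- cpp_train_skipmlp(
      Matrix::t(X), Y,
      list(W_hidden = list(), b_hidden = list(),
           W_skip = matrix(0, p, k), b_out = rep(0, k)),
      lr = config$learning_rate, clip = config$grad_norm_clip,
      epochs = config$epochs, batch = config$batch_size_ridge,
      dropout = 0, lambda = lambda)
    W <- fit$W_skip
    b <- as.numeric(fit$b_out)
    loss <- fit$loss
  } else {
    if (intercept) {
      xbar <- Matrix::colMeans(X)
      ybar <- colMeans(Y)
    } else {
      xbar <- numeric(p); ybar <- numeric(k)
    }
    Yc <- sweep(Y, 2, ybar)
    if (p <= n) {
      G <- as.matrix(Matrix::crossprod(X)) - n * tcrossprod(xbar)
      R <- as.matrix(Matrix::crossprod(X, Yc)) -
        outer(xbar, colSums(Yc))  # == Xc' Yc
      W <- solve(G + n * lambda * diag(p), R)
    } else {
      K <- as.matrix(Matrix::tcrossprod(X))
      s <- as.numeric(X %*% xbar)
      Kc <- K - outer(s, rep(1, n)) - outer(rep(1, n), s) + sum(xbar^2)
      A <- solve(Kc + n * lambda * diag(n), Yc)
      W <- as.matrix(Matrix::crossprod(X, A)) - outer(xbar, colSums(A))
    }
    b <- ybar - as.numeric(crossprod(W, xbar))
    loss <- NULL
  }
  dimnames(W) <- list(colnames(X), colnames(Y) %||% COST_CATEGORIES[seq_len(k)])
  names(b) <- colnames(W)
  structure(list(W = W, b = b, lambda = lambda, solver = solver,
                 intercept = intercept, loss = loss,
                 n_train = n), class = "ridge_cost")
}

#' @export
predict.ridge_cost <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "claims_design")) newdata$X else newdata
  out <- as.matrix(X %*% object$W)
  out <- sweep(out, 2, object$b, `+`)
  colnames(out) <- colnames(object$W)
  out
}

#' @export
coef.ridge_cost <- function(object, ...) {
  rbind(`(intercept)` = object$b, object$W)
}

#' @export
print.ridge_cost <- function(x, ...) {
  cat(sprintf(
    "Multivariate ridge regression (lambda %.3g, %s solver): %d features -> %d categories, n = %d\n",
    x$lambda, x$solver, nrow(x$W), ncol(x$W), x$n_train))
  invisible(x)
}

#' @export
residuals.ridge_cost <- function(object, x, y = NULL, ...) {
  if (inherits(x, "claims_design")) { y <- y %||% x$Y }
  y - predict(object, x)
}
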