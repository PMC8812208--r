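library(Matrix)

linear_testdata <- function(n = 200, p = 50, k = 7, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- Matrix(rbinom(n * p, 3, 0.15), n, p, sparse = TRUE)
  W <- matrix(rnorm(p * k, 0, 0.5), p, k)
  Y <- as.matrix(X %*% W) + matrix(rnorm(n * k, 0, noise), n, k)
  colnames(Y) <- cost_categories()[seq_len(k)]
  list(X = X, Y = Y, W = W)
}

test_that("the last-year baseline sums the final four observation quarters", {
  pats <- toy_patients(2)
  costs <- data.frame(
    patient_id = "P001",
    quarter = 0:3,                       # 4-quarter observation window
    category = "practice", amount = 100, stringsAsFactors = FALSE)
  co <- toy_cohort(pats, costs = costs)
  pred <- predict_last_year(co)
  expect_equal(unname(pred$categories["P001", "practice"]), 400)
  expect_equal(unname(pred$categories["P002", ]), rep(0, 7))  # no costs
  expect_equal(unname(pred$total["P002"]), 0)
  # implied fold change is 1 for every patient: this baseline predicts
  # costs to stay constant, so it carries no change-detection signal
  cur <- cohort_totals(co, 0:3)
  fold <- (pred$total + 10) / (cur + 10)
  expect_equal(unname(fold), rep(1, 2))
})

test_that("the mean-of-previous baseline divides by the observed years", {
  pats <- toy_patients(1)
  co24 <- toy_cohort(pats, costs = data.frame(
    patient_id = "P001", quarter = 0:23, category = "practice",
    amount = 50, stringsAsFactors = FALSE),
    config = sim_config(n_patients = 1, n_obs_quarters = 24,
                        vocab_sizes = c(DIAG = 5)))
  expect_equal(unname(predict_mean_previous(co24)$categories[1, "practice"]),
               1200 / 6)
  # 12-quarter (3-year) configuration divides by 3
  co12 <- toy_cohort(pats, costs = data.frame(
    patient_id = "P001", quarter = 0:11, category = "practice",
    amount = 50, stringsAsFactors = FALSE),
    config = sim_config(n_patients = 1, n_obs_quarters = 12,
                        vocab_sizes = c(DIAG = 5)))
  expect_equal(unname(predict_mean_previous(co12)$categories[1, "practice"]),
               600 / 3)
  # equals the last-year baseline when every year is identical
  expect_equal(predict_mean_previous(co24)$categories,
               predict_last_year(co24)$categories)
})

test_that("total assembly excludes incapacity to work by default", {
  pred <- matrix(10, 2, 7, dimnames = list(NULL, cost_categories()))
  expect_equal(assemble_total(pred), c(60, 60))
  expect_equal(assemble_total(pred, excluded = character(0)), c(70, 70))
  expect_equal(assemble_total(pred * 0), c(0, 0))
  expect_error(assemble_total(pred, excluded = "nonsense"), "unknown category")
})

test_that("ridge shrinks to the column means as lambda grows", {
  d <- linear_testdata(seed = 2)
  fit <- fit_ridge(d$X, d$Y, lambda = 1e9)
  expect_lt(max(abs(fit$W)), 1e-5)
  pred <- predict(fit, d$X[1:5, ])
  for (j in 1:7) expect_equal(unname(pred[, j]),
                              rep(mean(d$Y[, j]), 5), tolerance = 1e-4)
})

test_that("duplicated feature columns share their ridge weight", {
  d <- linear_testdata(n = 100, p = 20, seed = 3)
  X2 <- cbind(d$X, d$X[, 1, drop = FALSE])
  fit <- fit_ridge(X2, d$Y, lambda = 0.5)
  expect_equal(fit$W[1, ], fit$W[21, ], tolerance = 1e-8)
})

test_that("primal and dual closed-form solutions agree", {
  d <- linear_testdata(n = 60, p = 30, seed = 4)
  # force the dual path by making p > n
  d2 <- linear_testdata(n = 25, p = 40, seed = 4)
  fit1 <- fit_ridge(d2$X, d2$Y, lambda = 0.3)      # dual (p > n)
  Yc <- sweep(d2$Y, 2, colMeans(d2$Y))
  Xc <- sweep(as.matrix(d2$X), 2, colMeans(as.matrix(d2$X)))
  W_direct <- solve(crossprod(Xc) + 25 * 0.3 * diag(40), crossprod(Xc, Yc))
  expect_equal(unname(fit1$W), unname(W_direct), tolerance = 1e-8)
  # primal path on the p < n problem matches the same formula
  fitp <- fit_ridge(d$X, d$Y, lambda = 0.3)
  Xc2 <- sweep(as.matrix(d$X), 2, colMeans(as.matrix(d$X)))
  Yc2 <- sweep(d$Y, 2, colMeans(d$Y))
  Wd <- solve(crossprod(Xc2) + 60 * 0.3 * diag(30), crossprod(Xc2, Yc2))
  expect_equal(unname(fitp$W), unname(Wd), tolerance = 1e-8)
})

test_that("the stochastic ridge solver converges to the closed form", {
  d <- linear_testdata(n = 200, p = 50, seed = 5)
  closed <- fit_ridge(d$X, d$Y, lambda = 0.1)
  sgd <- fit_ridge(d$X, d$Y, lambda = 0.1, solver = "sgd",
                   config = train_config(epochs = 4000, learning_rate = 0.005,
                                         seed = 6))
  pc <- predict(closed, d$X)
  ps <- predict(sgd, d$X)
  rel <- sqrt(mean((ps - pc)^2)) / sqrt(mean(pc^2))
  expect_lt(rel, 0.05)
})

test_that("ridge rejects non-finite input", {
  d <- linear_testdata(n = 30, p = 5, seed = 6)
  Ybad <- d$Y; Ybad[1, 1] <- NaN
  expect_error(fit_ridge(d$X, Ybad), "non-finite")
})

test_that("zero-epoch training returns the seeded random initialization", {
  d <- linear_testdata(n = 50, p = 10, seed = 7)
  m0a <- fit_skip_mlp(d$X, d$Y, config = train_config(epochs = 0, seed = 9))
  m0b <- fit_skip_mlp(d$X, d$Y, config = train_config(epochs = 0, seed = 9))
  expect_identical(m0a$W_skip, m0b$W_skip)
  p <- predict(m0a, d$X)
  expect_true(all(is.finite(p)))
  m1 <- fit_skip_mlp(d$X, d$Y, config = train_config(epochs = 1, seed = 9))
  expect_false(identical(m0a$W_skip, m1$W_skip))
})

test_that("training divergence is reported with the epoch", {
  d <- linear_testdata(n = 50, p = 10, seed = 12)
  expect_error(
    fit_skip_mlp(d$X, d$Y,
                 train_config(epochs = 5, learning_rate = 1e200,
                              grad_norm_clip = 0, seed = 1),
                 standardize = FALSE),
    "non-finite training loss at epoch")
})

test_that("training is deterministic given the seed", {
  d <- linear_testdata(n = 80, p = 15, seed = 8)
  cfg <- train_config(epochs = 3, seed = 42)
  a <- fit_skip_mlp(d$X, d$Y, cfg)
  b <- fit_skip_mlp(d$X, d$Y, cfg)
  expect_identical(a$W_hidden, b$W_hidden)
  expect_identical(a$W_skip, b$W_skip)
  expect_identical(a$loss, b$loss)
})

test_that("zeroing the hidden path leaves an affine map of the input", {
  d <- linear_testdata(n = 40, p = 8, seed = 9)
  m <- fit_skip_mlp(d$X, d$Y, config = train_config(epochs = 2, seed = 1))
  for (l in seq_len(m$n_hidden)) m$W_hidden[[l]] <- m$W_hidden[[l]] * 0
  m$W_top <- m$W_top * 0
  # second differences along arbitrary directions vanish for affine maps
  x0 <- as.numeric(d$X[1, ]); dir <- rnorm(8)
  f <- function(t) predict(m, Matrix(x0 + t * dir, 1, 8, sparse = TRUE))
  second_diff <- f(1) - 2 * f(0) + f(-1)
  expect_lt(max(abs(second_diff)), 1e-8)
})

test_that("ensembling averages member predictions", {
  d <- linear_testdata(n = 60, p = 10, seed = 10)
  cfg <- train_config(epochs = 2, seed = 3)
  m <- fit_skip_mlp(d$X, d$Y, cfg)
  # ensemble of one and of five identical members both equal the single fit
  single <- predict(m, d$X)
  e1 <- ensemble_predict(list(m), d$X)
  e5 <- ensemble_predict(rep(list(m), 5), d$X)
  expect_equal(e1$categories, single)
  expect_equal(e5$categories, single)
  # hand mean of two members
  m2 <- fit_skip_mlp(d$X, d$Y, train_config(epochs = 2, seed = 4))
  e <- ensemble_predict(list(m, m2), d$X)
  expect_equal(e$categories, (single + predict(m2, d$X)) / 2)
  # distinct-seed ensemble helper produces distinct members
  ens <- fit_skip_mlp_ensemble(d$X, d$Y, cfg, size = 2)
  expect_false(identical(ens[[1]]$W_skip, ens[[2]]$W_skip))
})

test_that("a depth sweep yields one metrics row per depth", {
  d <- linear_testdata(n = 150, p = 20, seed = 11)
  tr <- 1:100; te <- 101:150
  rows <- lapply(2:8, function(depth) {
    m <- fit_skip_mlp(d$X[tr, ], d$Y[tr, ],
                      train_config(epochs = 2, n_hidden = depth, seed = 5))
    mm <- compute_metrics(assemble_total(d$Y[te, ]),
                          assemble_total(predict(m, d$X[te, ])))
    cbind(depth = depth, as.data.frame(mm))
  })
  sweep_df <- do.call(rbind, rows)
  expect_equal(sweep_df$depth, 2:8)
  expect_true(all(is.finite(sweep_df$mae)))
})
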