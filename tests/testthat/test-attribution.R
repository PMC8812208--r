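library(Matrix)

fit_small_models <- function(seed = 1) {
  set.seed(seed)
  n <- 120; p <- 30
  X <- Matrix(rbinom(n * p, 2, 0.2), n, p, sparse = TRUE)
  W <- matrix(rnorm(p * 7, 0, 0.4), p, 7)
  Y <- as.matrix(X %*% W) + matrix(rnorm(n * 7, 0, 0.2), n, 7)
  colnames(Y) <- cost_categories()
  list(X = X, Y = Y,
       ridge = fit_ridge(X, Y, lambda = 0.1),
       mlp = fit_skip_mlp(X, Y, train_config(epochs = 5, dropout = 0,
                                             seed = seed)))
}

test_that("integrated gradients are exact for linear models", {
  d <- fit_small_models(1)
  x <- as.numeric(d$X[3, ])
  for (steps in c(1, 4, 64)) {
    ig <- integrated_gradients(d$ridge, x, n_steps = steps)
    oracle <- linear_attribution_oracle(d$ridge, x)
    expect_lt(max(abs(ig - oracle)) / max(abs(oracle)), 1e-10)
  }
  # zero-weight feature attributes zero; doubling the path doubles it
  w0 <- d$ridge; w0$W[5, ] <- 0
  expect_equal(linear_attribution_oracle(w0, x)[5], 0)
  expect_equal(linear_attribution_oracle(d$ridge, 2 * x),
               2 * linear_attribution_oracle(d$ridge, x))
  expect_error(linear_attribution_oracle(d$mlp, x), "linear")
})

test_that("attribution at the baseline is identically zero", {
  d <- fit_small_models(2)
  expect_equal(integrated_gradients(d$mlp, numeric(30)), numeric(30))
  x <- as.numeric(d$X[1, ])
  expect_equal(integrated_gradients(d$mlp, x, baseline = x), numeric(30))
})

test_that("completeness holds and sharpens with more steps", {
  d <- fit_small_models(3)
  x <- as.numeric(d$X[7, ])
  # independent endpoint evaluation of F (helper reimplements the forward
  # pass outside the package)
  gap <- eval_mlp_total(d$mlp, x) - eval_mlp_total(d$mlp, numeric(30))
  errs <- vapply(c(16, 64, 256), function(m)
    abs(sum(integrated_gradients(d$mlp, x, n_steps = m)) - gap), 0)
  expect_lt(errs[3], 0.01 * abs(gap))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("input gradients agree with finite differences", {
  d <- fit_small_models(4)
  x <- as.numeric(d$X[2, ]) + 0.3   # keep away from ReLU kinks
  G <- input_gradient(d$mlp, matrix(x, 1))
  eps <- 1e-5
  for (j in c(1, 11, 23)) {
    xp <- x; xm <- x; xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
    fd <- (eval_mlp_total(d$mlp, xp) - eval_mlp_total(d$mlp, xm)) / (2 * eps)
    expect_equal(G[1, j], fd, tolerance = 1e-5)
  }
})

test_that("summaries normalize safely and conserve quarter mass", {
  co <- simulate_cohort(sim_config(n_patients = 300, n_obs_quarters = 4,
                                   vocab_sizes = c(DIAG = 12, DRUG = 8),
                                   seed = 41))
  idx <- feature_index(co, min_count = 0)
  des <- design_matrix(co, idx)
  rg <- fit_ridge(des)
  res <- summarize_attributions(rg, des, subset = 1:25, n_steps = 8)
  # conservation: quarter sums add up to total attribution mass
  expect_equal(sum(res$quarters$importance), sum(res$features$mean_ig))
  # normalization only where the feature occurs
  expect_true(all(is.na(res$features$normalized[res$features$nonzero_n == 0])))
  expect_false(any(is.na(res$codes$importance)))
  # never-observed codes are excluded from the ranking
  never <- res$features$nonzero_n == 0
  if (any(never)) {
    gone <- paste(res$features$vocabulary[never], res$features$code[never])
    kept_keys <- paste(res$codes$vocabulary, res$codes$code)
    per_code_nz <- tapply(res$features$nonzero_n,
                          paste(res$features$vocabulary, res$features$code),
                          sum)
    expect_true(all(per_code_nz[kept_keys] > 0))
  }
  # a one-patient subset is that patient's own attribution
  res1 <- summarize_attributions(rg, des, subset = 3, n_steps = 8)
  ig3 <- integrated_gradients(rg, as.numeric(des$X[3, ]), n_steps = 8)
  expect_equal(res1$features$mean_ig, ig3)
  expect_error(summarize_attributions(rg, des, subset = rep(FALSE, 300)),
               "empty")
})

test_that("planted high-risk diagnosis codes dominate the ranking", {
  hits <- 0
  for (seed in 1:3) {
    co <- simulate_cohort(sim_config(n_patients = 1500, n_obs_quarters = 8,
                                     vocab_sizes = c(DIAG = 40, DRUG = 20,
                                                     FEE = 20, PROC = 10,
                                                     DRG = 5, PHYSGRP = 5),
                                     change_event_rate = 0, seed = seed))
    idx <- feature_index(co, min_count = 0)
    des <- design_matrix(co, idx)
    rg <- fit_ridge(des)
    res <- summarize_attributions(rg, des, subset = 1:200, n_steps = 8)
    top <- head(res$codes, 10)
    hr_codes <- co$vocabulary$code[co$vocabulary$group == "chronic_highrisk"]
    hits <- hits + (sum(top$code %in% hr_codes) >= 5)
  }
  expect_gte(hits, 2)
})

test_that("recency-weighted cost effects surface in quarter importance", {
  wins <- 0
  for (seed in 1:3) {
    co <- simulate_cohort(sim_config(n_patients = 1500, n_obs_quarters = 8,
                                     vocab_sizes = c(DIAG = 40, DRUG = 10),
                                     recency_weight = 0.6,
                                     change_event_rate = 0, seed = seed + 10))
    idx <- feature_index(co, min_count = 0)
    des <- design_matrix(co, idx)
    rg <- fit_ridge(des)
    res <- summarize_attributions(rg, des, subset = 1:300, n_steps = 8)
    qi <- quarter_importance(res)
    late <- mean(qi$importance[qi$quarter >= 4])
    early <- mean(qi$importance[qi$quarter < 4])
    wins <- wins + (late > early)
  }
  expect_gte(wins, 2)
})

test_that("quarters with no nonzero features carry zero importance", {
  pats <- toy_patients(3)
  ev <- data.frame(patient_id = "P001", quarter = 0L, vocabulary = "DIAG",
                   code = "D0001", stringsAsFactors = FALSE)
  co <- toy_cohort(pats, events = ev,
                   config = sim_config(n_patients = 3, n_obs_quarters = 2,
                                       vocab_sizes = c(DIAG = 3)))
  idx <- feature_index(co, min_count = 0)
  des <- design_matrix(co, idx)
  # strip the demographic columns so quarter 1 is entirely zero
  des$X[, des$columns$vocabulary %in% c("DEMO", "SEX")] <- 0
  rg <- fit_ridge(des, lambda = 1)
  res <- summarize_attributions(rg, des, subset = 1:3, n_steps = 4)
  q1 <- res$quarters$importance[res$quarters$quarter == 1]
  expect_equal(q1, 0)
})
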