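test_that("eligibility follows the death/coverage rules", {
  # default design: observation 0-23, gap 24-25, evaluation 26-29
  # enumerated timing fixture: death and coverage-end in each study phase
  pats <- toy_patients(
    8,
    death_quarter = c(NA, 10L, 24L, 27L, NA, NA, 31L, 27L),
    coverage_end_quarter = c(NA, NA, NA, NA, 12L, 25L, 20L, 24L))
  co <- toy_cohort(pats, config = sim_config(n_patients = 8,
                                             vocab_sizes = c(DIAG = 5)))
  got <- eligibility_filter(co)
  expect_equal(got, c(
    TRUE,   # covered throughout
    FALSE,  # died mid-observation
    FALSE,  # died in the gap, before evaluation
    TRUE,   # died during evaluation
    FALSE,  # coverage ended mid-observation, no death
    FALSE,  # coverage ended in the gap, no death
    TRUE,   # died after evaluation ended
    TRUE))  # died during evaluation even though coverage ended earlier
})

test_that("metric anchors hold exactly", {
  y <- c(3, 7, 1, 9, 5, 2)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$spearman_rho, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$cpm, 1)
  atmean <- compute_metrics(y, rep(mean(y), 6))
  expect_equal(atmean$r2, 0)
  expect_equal(atmean$cpm, 0)
})

test_that("the three-point fixture reproduces hand arithmetic", {
  m <- compute_metrics(c(0, 10, 20), c(5, 10, 15))
  expect_equal(m$mae, 10 / 3)
  expect_equal(m$cpm, 0.5)          # 1 - 10/20
  expect_equal(m$pearson_r, 1)
})

test_that("constant targets give NA markers, not errors", {
  m <- compute_metrics(rep(4, 5), 1:5)
  expect_true(is.na(m$pearson_r))
  expect_true(is.na(m$cpm))
  expect_equal(m$mae, mean(abs(rep(4, 5) - 1:5)))
  expect_error(compute_metrics(1:3, 1:4), "mismatch")
})

test_that("MAE is translation equivariant", {
  set.seed(1)
  y <- rgamma(50, 1, 0.01); p <- y + rnorm(50, 0, 30)
  for (c0 in c(-5, 17, 1000))
    expect_equal(compute_metrics(y + c0, p + c0)$mae,
                 compute_metrics(y, p)$mae)
})

test_that("fold-change labelling respects the offset and strict boundary", {
  lab <- label_cost_change(c(0, 0, 5), c(990, 1990, 5))
  # (990+10)/(0+10) = 100 exactly: NOT an increase under the strict rule
  expect_equal(as.character(lab$label), c("stable", "increase", "stable"))
  expect_equal(lab$fold_change[1:2], c(100, 200))
  expect_error(label_cost_change(-1, 5), ">= 0")
})

test_that("labelling is symmetric under swapping current and future", {
  set.seed(8)
  cur <- rgamma(300, 0.5, 0.001) * rbinom(300, 1, 0.7)
  fut <- rgamma(300, 0.5, 0.001) * rbinom(300, 1, 0.7)
  a <- label_cost_change(cur, fut)
  b <- label_cost_change(fut, cur)
  map <- c(increase = "decrease", decrease = "increase", stable = "stable")
  expect_equal(as.character(b$label), unname(map[as.character(a$label)]))
  expect_equal(b$fold_change, 1 / a$fold_change)
})

test_that("curve areas match exhaustive threshold enumeration", {
  # fixed 4-patient fixture
  s <- c(0.9, 0.8, 0.2, 0.1); y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(costnet:::auroc(s, y), 0.75)
  expect_equal(costnet:::auroc(s, y), brute_auroc(s, y))
  expect_equal(costnet:::auprc(s, y), brute_auprc(s, y))
  # random small fixtures, with ties
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- as.logical(rbinom(n, 1, 0.5))
    if (!any(y) || all(y)) next
    expect_equal(costnet:::auprc(s, y), brute_auprc(s, y), tolerance = 1e-12)
    expect_equal(costnet:::auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("perfect separation gives area 1; random scores track prevalence", {
  lab <- label_cost_change(c(rep(0, 5), rep(5000, 95)),
                           c(rep(5000, 5), rep(5000, 95)))
  expect_equal(as.character(lab$label[1:5]), rep("increase", 5))
  det <- change_detection_curves(lab, predicted_future =
                                   c(rep(5000, 5), rep(5000, 95)))
  expect_equal(det$increase$auprc, 1)
  expect_equal(det$increase$auroc, 1)
  # random uniform scores: auPRC close to prevalence, auROC close to 0.5
  set.seed(99)
  n <- 4000; prev <- 0.05
  pos <- as.logical(rbinom(n, 1, prev))
  reps <- replicate(20, {
    s <- runif(n)
    c(costnet:::auprc(s, pos), costnet:::auroc(s, pos))
  })
  se_roc <- sd(reps[2, ]) / sqrt(20)
  expect_lt(abs(mean(reps[1, ]) - mean(pos)), 3 * sd(reps[1, ]) / sqrt(20) + 0.005)
  expect_lt(abs(mean(reps[2, ]) - 0.5), 3 * se_roc + 0.005)
})

test_that("no positives in a direction yields an NA marker with counts", {
  lab <- label_cost_change(rep(100, 10), rep(100, 10))
  det <- change_detection_curves(lab, predicted_future = runif(10, 50, 150))
  expect_true(is.na(det$increase$auprc))
  expect_equal(det$increase$n_pos, 0)
})

test_that("error-by-cost profile matches hand-computed bin means", {
  y <- c(10, 20, 30, 1000, 2000, 3000)
  pa <- y + c(1, 2, 3, 100, 200, 300)
  pb <- y + c(2, 2, 2, 50, 50, 50)
  out <- error_by_cost_profile(y, pa, pb, breaks = c(1, 100, 10000))
  expect_equal(out$n, c(3L, 3L))
  expect_equal(out$mae_a, c(2, 200))
  expect_equal(out$mae_b, c(2, 50))
  expect_equal(out$diff, c(0, 150))
  # identical predictions: zero difference in every occupied bin
  same <- error_by_cost_profile(y, pa, pa, n_bins = 3)
  expect_true(all(same$diff[same$n > 0] == 0))
  expect_true(all(is.na(same$diff[same$n == 0])))
  # a single bin reproduces the overall MAE
  one <- error_by_cost_profile(y, pa, n_bins = 1)
  expect_equal(one$mae_a, mean(abs(y - pa)))
  # empty bins are reported as NA, not dropped
  gap <- error_by_cost_profile(y, pa, breaks = c(1, 100, 500, 10000))
  expect_equal(nrow(gap), 3)
  expect_true(is.na(gap$mae_a[2]))
})

test_that("a one-cell sensitivity grid equals a standard run", {
  co <- simulate_cohort(sim_config(n_patients = 500, n_obs_quarters = 8,
                                   vocab_sizes = c(DIAG = 15, DRUG = 10),
                                   seed = 31))
  cfg <- train_config(epochs = 2, dropout = 0, seed = 2)
  grid <- sensitivity_analysis(co, sizes = 400, history_years = 2,
                               config = cfg)
  expect_equal(nrow(grid), 1)
  run <- evaluate_model(co, model = "mlp", config = cfg, n_train = 400)
  expect_equal(grid$r2, run$metrics$r2)
  expect_equal(grid$mae, run$metrics$mae)
  # grid completeness over the axes
  grid4 <- sensitivity_analysis(co, sizes = c(200, 400),
                                history_years = c(1, 2), config = cfg,
                                model = "ridge")
  expect_equal(nrow(grid4), 4)
  expect_equal(sort(unique(grid4$size)), c(200, 400))
  expect_equal(sort(unique(grid4$years)), c(1, 2))
  expect_error(sensitivity_analysis(co, sizes = 10000, history_years = 1,
                                    config = cfg), "training pool")
  expect_error(sensitivity_analysis(co, sizes = 100, history_years = 10,
                                    config = cfg), "observation")
})
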