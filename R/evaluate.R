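#' Test-set eligibility filter
#'
#' A patient enters the evaluation only when alive through the observation
#' period and the gap, and either died from the start of the evaluation
#' period onward or was still insured for at least one day of the
#' evaluation period.  A patient whose coverage ends before the evaluation
#' period starts and who did not die is excluded.
#'
#' @param cohort A \code{claims_cohort}.
#' @return Logical vector aligned with \code{cohort$patients}.
#' @export
eligibility_filter <- function(cohort) {
  stopifnot(inherits(cohort, "claims_cohort"))
  ev0 <- eval_start_quarter(cohort$config)
  death <- cohort$patients$death_quarter
  cov <- cohort$patients$coverage_end_quarter
  died_in_or_after_eval <- !is.na(death) & death >= ev0
  covered_in_eval <- is.na(cov) | cov >= ev0
  alive_before_eval <- is.na(death) | death >= ev0
  alive_before_eval & (died_in_or_after_eval | covered_in_eval)
}

#' Prediction quality metrics
#'
#' Computes Pearson's r, Spearman's rho, the mean absolute error (Euro),
#' R-squared and Cumming's Prediction Measure
#' \deqn{CPM = 1 - \sum_i |y_i - \hat y_i| / \sum_i |y_i - \bar y|,}
#' the absolute-error analogue of R-squared: both equal 1 for perfect
#' prediction and 0 for the constant mean predictor.  When \code{y_true} is
#' constant the correlation and skill scores are undefined and reported as
#' \code{NA}.
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 2).
#' @return An object of class \code{metrics_report}.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_cfg("length mismatch")
  n <- length(y_true)
  if (n < 2) stop_cfg("need n >= 2")
  mae <- mean(abs(y_true - y_pred))
  if (sd(y_true) == 0) {
    r <- rho <- r2 <- cpm <- NA_real_
  } else {
    r <- if (sd(y_pred) == 0) NA_real_ else cor(y_true, y_pred)
    rho <- if (sd(y_pred) == 0) NA_real_
           else cor(y_true, y_pred, method = "spearman")
    r2 <- 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
    cpm <- 1 - sum(abs(y_true - y_pred)) / sum(abs(y_true - mean(y_true)))
  }
  structure(list(pearson_r = r, spearman_rho = rho, mae = mae, r2 = r2,
                 cpm = cpm, n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d:  r = %.3f  rho = %.3f  MAE = %.2f EUR  r2 = %.3f  CPM = %.3f\n",
              x$n, x$pearson_r, x$spearman_rho, x$mae, x$r2, x$cpm))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
             mae = x$mae, r2 = x$r2, cpm = x$cpm, n = x$n)
}

#' Label patients by >100-fold cost change
#'
#' Compares the last observation year's total against the evaluation year's
#' total.  To avoid classing overall-low-cost patients as changers, a fixed
#' offset (10 Euro by default) is added to both totals before the fold
#' change \eqn{(future + offset) / (current + offset)} is computed.  A
#' patient is an \code{increase} when the fold change strictly exceeds
#' \code{factor}, a \code{decrease} when it is strictly below
#' \code{1/factor}, and \code{stable} otherwise.
#'
#' @param current_annual,future_annual Non-negative annual Euro totals.
#' @param offset Euro offset (default 10).
#' @param factor Fold threshold (default 100; strict inequalities).
#' @return Data frame of class \code{change_labels} with \code{current},
#'   \code{future}, \code{fold_change} and \code{label}.
#' @export
label_cost_change <- function(current_annual, future_annual, offset = 10,
                              factor = 100) {
  if (any(current_annual < 0) || any(future_annual < 0))
    stop_cfg("annual totals must be >= 0")
  fold <- (future_annual + offset) / (current_annual + offset)
  label <- ifelse(fold > factor, "increase",
                  ifelse(fold < 1 / factor, "decrease", "stable"))
  structure(data.frame(current = current_annual, future = future_annual,
                       fold_change = fold,
                       label = base::factor(label,
                                            levels = c("increase", "decrease",
                                                       "stable")),
                       stringsAsFactors = FALSE),
            class = c("change_labels", "data.frame"),
            offset = offset, factor = factor)
}

# ranking internals: threshold-free curves with tied scores grouped
rank_groups <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- positive[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- as.numeric(rowsum(as.numeric(y), grp)[, 1])
  fp <- as.numeric(rowsum(as.numeric(!y), grp)[, 1])
  list(tp = cumsum(tp), fp = cumsum(fp), P = sum(y), N = sum(!y))
}

auroc <- function(score, positive) {
  g <- rank_groups(score, positive)
  tpr <- c(0, g$tp / g$P); fpr <- c(0, g$fp / g$N)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

auprc <- function(score, positive) {
  g <- rank_groups(score, positive)
  rec <- g$tp / g$P
  prec <- g$tp / (g$tp + g$fp)
  sum(diff(c(0, rec)) * prec)   # step-wise integration
}

#' Detection of patients with changing costs
#'
#' Scores each patient by the model-implied fold change
#' \eqn{(\hat F + offset)/(C + offset)} — predicted evaluation-year total
#' against the observed last-observation-year total — and evaluates how well
#' that score ranks the true \code{increase} patients ahead of everyone
#' else (and, using the reciprocal score, the true \code{decrease}
#' patients).  Areas under the precision-recall curve (step-wise
#' integration) and the ROC curve (trapezoid) are reported per direction,
#' with \code{NA} and a count report when a direction has no positives.
#'
#' @param labels A \code{change_labels} data frame (true labels, built from
#'   true costs).
#' @param predicted_future Predicted evaluation-year totals (Euro), aligned
#'   with \code{labels}.
#' @param offset Euro offset used in the score (default: the labels'
#'   offset).
#' @return List of class \code{change_detection} with elements
#'   \code{increase} and \code{decrease}, each holding \code{auprc},
#'   \code{auroc}, \code{n_pos}, \code{n} and \code{prevalence}.
#' @export
change_detection_curves <- function(labels, predicted_future,
                                    offset = attr(labels, "offset") %||% 10) {
  stopifnot(inherits(labels, "change_labels"))
  if (nrow(labels) != length(predicted_future)) stop_cfg("length mismatch")
  score <- (pmax(predicted_future, 0) + offset) / (labels$current + offset)
  one_direction <- function(positive, s) {
    n_pos <- sum(positive)
    if (n_pos == 0 || n_pos == length(positive))
      return(list(auprc = NA_real_, auroc = NA_real_, n_pos = n_pos,
                  n = length(positive), prevalence = mean(positive)))
    list(auprc = auprc(s, positive), auroc = auroc(s, positive),
         n_pos = n_pos, n = length(positive), prevalence = mean(positive))
  }
  structure(list(
    increase = one_direction(labels$label == "increase", score),
    decrease = one_direction(labels$label == "decrease", 1 / score),
    score = score), class = "change_detection")
}

#' @export
print.change_detection <- function(x, ...) {
  for (d in c("increase", "decrease")) {
    z <- x[[d]]
    cat(sprintf("%-9s auPRC = %s  auROC = %s  (%d/%d positives, prevalence %.4f)\n",
                d, format(round(z$auprc, 4)), format(round(z$auroc, 4)),
                z$n_pos, z$n, z$prevalence))
  }
  invisible(x)
}

#' Mean absolute error by true-cost bin
#'
#' Profiles model error as a function of the true cost: patients are
#' assigned to log-spaced bins of their positive true totals, and the mean
#' absolute error of each model, plus the A minus B difference, is reported
#' per bin.  Empty bins are reported as \code{NA}, not dropped.
#'
#' @param y_true True totals (Euro); only positive totals are binned.
#' @param y_pred_a,y_pred_b Predictions of the two models to compare
#'   (\code{y_pred_b} optional).
#' @param n_bins Number of log-spaced bins (ignored when \code{breaks}
#'   given).
#' @param breaks Optional explicit bin breaks on the Euro scale.
#' @return Data frame with one row per bin: bounds, \code{n},
#'   \code{mae_a}, \code{mae_b}, \code{diff} (A - B).
#' @export
error_by_cost_profile <- function(y_true, y_pred_a, y_pred_b = NULL,
                                  n_bins = 10, breaks = NULL) {
  pos <- y_true > 0
  if (!any(pos)) stop_cfg("no positive true totals to bin")
  if (is.null(breaks)) {
    rng <- range(y_true[pos])
    if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
    breaks <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
    # guard the extremes against floating-point exclusion at the boundaries
    breaks[1] <- breaks[1] * (1 - 1e-9)
    breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-9)
  }
  bin <- cut(y_true[pos], breaks, include.lowest = TRUE)
  ea <- abs(y_true - y_pred_a)[pos]
  eb <- if (!is.null(y_pred_b)) abs(y_true - y_pred_b)[pos] else NULL
  out <- data.frame(
    lower = breaks[-length(breaks)], upper = breaks[-1],
    n = as.integer(table(bin)),
    mae_a = as.numeric(tapply(ea, bin, mean)))
  if (!is.null(eb)) {
    out$mae_b <- as.numeric(tapply(eb, bin, mean))
    out$diff <- out$mae_a - out$mae_b
  }
  out
}

#' Full train/evaluate run on a cohort
#'
#' Convenience harness: splits the cohort into a training pool and a test
#' set, freezes the feature index on the training split, fits the requested
#' model and reports test-set metrics on the assembled totals of eligible
#' patients.
#'
#' @param cohort A \code{claims_cohort}.
#' @param model \code{"mlp"}, \code{"ridge"}, \code{"last_year"} or
#'   \code{"mean_previous"}.
#' @param config A \code{\link{train_config}}.
#' @param train_frac Fraction of patients in the training pool (leading
#'   block; default 0.8).
#' @param n_train Optional number of training patients drawn from the
#'   training pool (default: the whole pool).
#' @param quarters Observation quarters to featurize (default all).
#' @param excluded Categories excluded from assembled totals.
#' @return List with the fitted model, test metrics
#'   (\code{metrics_report}), predictions and the test patient ids.
#' @export
evaluate_model <- function(cohort, model = c("mlp", "ridge", "last_year",
                                             "mean_previous"),
                           config = train_config(), train_frac = 0.8,
                           n_train = NULL, quarters = NULL,
                           excluded = EXCLUDED_DEFAULT) {
  model <- match.arg(model)
  n <- nrow(cohort$patients)
  n_pool <- floor(train_frac * n)
  train_ids <- cohort$patients$patient_id[seq_len(n_pool)]
  if (!is.null(n_train)) {
    if (n_train > n_pool) stop_cfg("n_train (%d) exceeds training pool (%d)",
                                   n_train, n_pool)
    train_ids <- train_ids[seq_len(n_train)]
  }
  test_mask <- rep(TRUE, n); test_mask[seq_len(n_pool)] <- FALSE
  test_mask <- test_mask & eligibility_filter(cohort)

  if (model %in% c("last_year", "mean_previous")) {
    pred_all <- if (model == "last_year") predict_last_year(cohort, excluded)
                else predict_mean_previous(cohort, excluded)
    fitted <- NULL
    pred_total <- pred_all$total[test_mask]
  } else {
    idx <- feature_index(cohort, quarters = quarters,
                         patient_ids = train_ids)
    des <- design_matrix(cohort, idx)
    tr <- des$patient_id %in% train_ids
    fitted <- if (model == "ridge")
      fit_ridge(des$X[tr, , drop = FALSE], des$Y[tr, , drop = FALSE],
                lambda = config$ridge_lambda)
    else {
      d_tr <- des
      d_tr$X <- des$X[tr, , drop = FALSE]
      d_tr$Y <- des$Y[tr, , drop = FALSE]
      fit_skip_mlp(d_tr, config = config)
    }
    pred7 <- predict(fitted, des$X[test_mask, , drop = FALSE])
    pred_total <- assemble_total(pred7, excluded)
  }
  # costs are non-negative; negative predicted totals are truncated at zero
  # before assessment
  pred_total <- pmax(pred_total, 0)
  y_true <- cohort_totals(cohort,
                          with(cohort$config,
                               (n_obs_quarters + gap_quarters) +
                                 seq_len(n_eval_quarters) - 1),
                          excluded)[test_mask]
  list(model = fitted,
       metrics = compute_metrics(unname(y_true), unname(pred_total)),
       y_true = unname(y_true), y_pred = unname(pred_total),
       test_ids = cohort$patients$patient_id[test_mask])
}

#' Sensitivity grid: training size by observation length
#'
#' Re-runs featurization, training and evaluation for every combination of
#' training-set size and trailing observation window (in years), on a fixed
#' test set, and reports r-squared and the correlation metrics per cell.
#'
#' @param cohort A \code{claims_cohort}.
#' @param sizes Training-set sizes (each at most the training pool).
#' @param history_years Observation lengths in years (each at most the
#'   cohort's observation years); the trailing window up to the observation
#'   end is used.
#' @param config A \code{\link{train_config}}.
#' @param model \code{"mlp"} (default) or \code{"ridge"}.
#' @param train_frac Training-pool fraction (default 0.8).
#' @return Data frame of class \code{sensitivity_grid} with one row per
#'   (size, years) cell: \code{r2}, \code{pearson_r}, \code{spearman_rho},
#'   \code{mae}.
#' @export
sensitivity_analysis <- function(cohort, sizes, history_years,
                                 config = train_config(),
                                 model = c("mlp", "ridge"),
                                 train_frac = 0.8) {
  model <- match.arg(model)
  n_obs <- cohort$config$n_obs_quarters
  if (any(history_years * 4 > n_obs))
    stop_cfg("history_years exceeds the %d-quarter observation period", n_obs)
  if (any(sizes > floor(train_frac * nrow(cohort$patients))))
    stop_cfg("a requested size exceeds the training pool")
  rows <- list()
  for (yrs in history_years) {
    quarters <- (n_obs - 4 * yrs):(n_obs - 1)
    for (sz in sizes) {
      run <- evaluate_model(cohort, model = model, config = config,
                            train_frac = train_frac, n_train = sz,
                            quarters = quarters)
      m <- run$metrics
      rows[[length(rows) + 1]] <- data.frame(
        size = sz, years = yrs, r2 = m$r2, pearson_r = m$pearson_r,
        spearman_rho = m$spearman_rho, mae = m$mae, n_test = m$n)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_grid", "data.frame")
  out
}

#' @export
plot.sensitivity_grid <- function(x, metric = "r2", ...) {
  sizes <- sort(unique(x$size)); yrs <- sort(unique(x$years))
  z <- matrix(NA_real_, length(sizes), length(yrs))
  for (i in seq_len(nrow(x)))
    z[match(x$size[i], sizes), match(x$years[i], yrs)] <- x[[metric]][i]
  graphics::image(seq_along(sizes), seq_along(yrs), z, axes = FALSE,
                  xlab = "training size", ylab = "observation years",
                  main = sprintf("sensitivity grid (%s)", metric), ...)
  graphics::axis(1, seq_along(sizes), sizes)
  graphics::axis(2, seq_along(yrs), yrs)
  invisible(x)
}
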