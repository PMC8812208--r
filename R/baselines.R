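#' Assemble the total cost from seven category predictions
#'
#' The total used for model assessment sums the predicted categories except
#' compensation for incapacity to work (to keep totals comparable to
#' externally reported risk-adjustment figures).
#'
#' @param pred7 Numeric matrix (patients x 7) with the canonical category
#'   columns.
#' @param excluded Character vector of category names left out of the total.
#' @return Numeric vector of per-patient totals (Euro).
#' @export
assemble_total <- function(pred7, excluded = EXCLUDED_DEFAULT) {
  if (is.null(colnames(pred7))) colnames(pred7) <- COST_CATEGORIES
  if (ncol(pred7) != 7L) stop_cfg("expected 7 category columns, got %d",
                                  ncol(pred7))
  bad <- setdiff(excluded, colnames(pred7))
  if (length(bad))
    stop_cfg("unknown category in exclusion set: %s", paste(bad, collapse = ", "))
  keep <- setdiff(colnames(pred7), excluded)
  rowSums(pred7[, keep, drop = FALSE])
}

new_cost_prediction <- function(categories, excluded = EXCLUDED_DEFAULT,
                                patient_id = rownames(categories)) {
  structure(list(categories = categories,
                 total = assemble_total(categories, excluded),
                 excluded_categories = excluded,
                 patient_id = patient_id),
            class = "cost_prediction")
}

#' @export
print.cost_prediction <- function(x, ...) {
  cat(sprintf("Cost prediction for %d patients (7 categories; total excludes: %s)\n",
              nrow(x$categories),
              paste(x$excluded_categories, collapse = ", ")))
  cat(sprintf("  total: mean %.1f, median %.1f, max %.1f Euro\n",
              mean(x$total), stats::median(x$total), max(x$total)))
  invisible(x)
}

#' Baseline: last observation year as the prediction
#'
#' Predicts each category's evaluation-period cost as the cost accrued in
#' the final four observation quarters.  By construction this model predicts
#' costs to stay constant, so its implied fold change is 1 for every
#' patient and it is excluded from cost-change detection comparisons.
#'
#' @param cohort A \code{claims_cohort} with >= 4 observation quarters.
#' @param excluded Categories excluded from the assembled total.
#' @return A \code{cost_prediction}.
#' @export
predict_last_year <- function(cohort, excluded = EXCLUDED_DEFAULT) {
  stopifnot(inherits(cohort, "claims_cohort"))
  n_obs <- cohort$config$n_obs_quarters
  if (n_obs < 4) stop_cfg("need >= 4 observation quarters, have %d", n_obs)
  new_cost_prediction(category_totals(cohort, (n_obs - 4):(n_obs - 1)),
                      excluded)
}

#' Baseline: mean annual cost over the observation period
#'
#' Predicts each category's evaluation-period cost as the total observation
#' cost divided by the number of observed years (six under the default
#' 24-quarter design).
#'
#' @param cohort A \code{claims_cohort}.
#' @param excluded Categories excluded from the assembled total.
#' @return A \code{cost_prediction}.
#' @export
predict_mean_previous <- function(cohort, excluded = EXCLUDED_DEFAULT) {
  stopifnot(inherits(cohort, "claims_cohort"))
  n_obs <- cohort$config$n_obs_quarters
  if (n_obs < 1) stop_cfg("empty observation period")
  years <- n_obs / 4
  new_cost_prediction(category_totals(cohort, 0:(n_obs - 1)) / years,
                      excluded)
}

# patients x 7 matrix of per-category cost sums over the given quarters
category_totals <- function(cohort, quarters) {
  pts <- cohort$patients
  n <- nrow(pts)
  M <- matrix(0, n, 7L, dimnames = list(pts$patient_id, COST_CATEGORIES))
  cc <- cohort$costs
  sel <- cc$quarter %in% quarters
  if (any(sel)) {
    ci <- match(cc$patient_id[sel], pts$patient_id)
    cj <- match(cc$category[sel], COST_CATEGORIES)
    agg <- rowsum(cc$amount[sel], ci + (cj - 1L) * n)
    M[as.integer(rownames(agg))] <- agg[, 1]
  }
  M
}

#' Average the predictions of an ensemble of fitted models
#'
#' Implements prediction ensembling: the same model trained several times
#' with different seeds, with the elementwise mean of the member category
#' predictions taken as the final prediction before total assembly.
#'
#' @param models List of fitted models sharing a \code{predict} method and
#'   output dimension.
#' @param X Sparse design matrix (or \code{claims_design}).
#' @param excluded Categories excluded from the assembled total.
#' @return A \code{cost_prediction}.
#' @export
ensemble_predict <- function(models, X, excluded = EXCLUDED_DEFAULT) {
  if (!length(models)) stop_cfg("empty model list")
  preds <- lapply(models, function(m) predict(m, X))
  d <- dim(preds[[1]])
  for (p in preds)
    if (!identical(dim(p), d)) stop_cfg("ensemble members disagree on output dimensions")
  avg <- Reduce(`+`, preds) / length(preds)
  new_cost_prediction(avg, excluded)
}
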