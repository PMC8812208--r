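#' Integrated gradients for one patient
#'
#' Path-integral attribution: feature i receives
#' \deqn{(x_i - x'_i) \cdot \frac{1}{m}\sum_{k=1}^m
#'   \partial F/\partial x_i\big(x' + \alpha_k (x - x')\big)}
#' with midpoint Riemann points \eqn{\alpha_k = (k - 1/2)/m} between the
#' baseline \eqn{x'} and the input \eqn{x}.  The attributed quantity
#' \eqn{F} is a weighted sum of the model's category outputs (by default the
#' assembled total, i.e. every category except compensation for incapacity
#' to work).  The attributions satisfy the completeness axiom
#' \eqn{\sum_i a_i \to F(x) - F(x')} as the step count grows, and are exact
#' for linear models at any step count.  Dropout plays no role at
#' attribution time (gradients are evaluated in inference mode).
#'
#' @param model A fitted \code{skip_mlp} or \code{ridge_cost}.
#' @param x Input feature vector (raw scale).
#' @param baseline Baseline vector (default: all zeros — an empty medical
#'   history).
#' @param n_steps Riemann steps (default 64).
#' @param weights Category weights defining \eqn{F} (default: assembled
#'   total).
#' @return Numeric attribution vector, same length as \code{x}.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, n_steps = 64,
                                 weights = NULL) {
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  if (length(baseline) != length(x))
    stop_cfg("baseline length %d does not match input length %d",
             length(baseline), length(x))
  if (n_steps < 1) stop_cfg("n_steps must be >= 1")
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  diff <- x - baseline
  P <- outer(alphas, diff) + matrix(baseline, n_steps, length(x),
                                    byrow = TRUE)
  if (inherits(model, "skip_mlp")) {
    # mean gradient via averaged deltas: cheap in the feature dimension
    w <- output_weights(model$categories, weights)
    w_eff <- w * model$y_scale
    Xs <- scale_input(model, methods::as(P, "CsparseMatrix"))
    dl <- mlp_deltas(model, Xs, w_eff)
    g <- as.numeric(model$W_skip %*% colMeans(dl$d_out))
    if (model$n_hidden > 0)
      g <- g + as.numeric(model$W_hidden[[1]] %*% colMeans(dl$dZ[[1]]))
    g <- g / model$col_scale
  } else {
    g <- colMeans(input_gradient(model, P, weights = weights))
  }
  diff * g
}

#' Exact attribution for a linear model
#'
#' For a linear (ridge) model the integrated-gradients attribution has the
#' closed form \eqn{w_i (x_i - x'_i)}; this oracle computes it directly and
#' is used to validate the path-integral implementation to machine
#' precision.
#'
#' @param model A \code{ridge_cost} fit (error for any other class).
#' @param x Input vector.
#' @param baseline Baseline vector (default zeros).
#' @param weights Category weights (default: assembled total).
#' @return Numeric attribution vector.
#' @export
linear_attribution_oracle <- function(model, x, baseline = NULL,
                                      weights = NULL) {
  if (!inherits(model, "ridge_cost"))
    stop_cfg("linear_attribution_oracle requires a linear (ridge_cost) model")
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  w <- output_weights(colnames(model$W), weights)
  (x - baseline) * as.numeric(model$W %*% w)
}

#' Cohort-level attribution summary
#'
#' Computes per-feature mean integrated gradients over a patient subset
#' (typically the patients with a >100-fold true cost increase), divides
#' each mean by the number of subset patients in which the feature is
#' nonzero (abundance normalization), and aggregates the attributions per
#' quarter and per code (summed over quarters) into a ranked code table.
#'
#' @param model A fitted \code{skip_mlp} or \code{ridge_cost}.
#' @param design A \code{claims_design} (supplies the feature layout and
#'   descriptions).
#' @param subset Logical mask or patient ids selecting the attribution
#'   subset; must be nonempty.
#' @param n_steps Riemann steps per patient (default 64).
#' @param baseline Baseline vector (default zeros).
#' @param weights Category weights (default: assembled total).
#' @return An object of class \code{attribution_result}: per-feature table
#'   (\code{features}), per-quarter sums (\code{quarters}) and the ranked
#'   per-code table (\code{codes}).
#' @export
summarize_attributions <- function(model, design, subset, n_steps = 64,
                                   baseline = NULL, weights = NULL) {
  stopifnot(inherits(design, "claims_design"))
  if (is.logical(subset)) {
    if (length(subset) != nrow(design$X)) stop_cfg("subset mask length mismatch")
    rows <- which(subset)
  } else if (is.character(subset)) {
    rows <- match(subset, design$patient_id)
    rows <- rows[!is.na(rows)]
  } else {
    rows <- as.integer(subset)
  }
  if (!length(rows))
    stop_cfg("attribution subset is empty (selector matched no patients)")

  p <- ncol(design$X)
  acc <- numeric(p)
  for (r in rows) {
    xi <- as.numeric(design$X[r, ])
    acc <- acc + integrated_gradients(model, xi, baseline = baseline,
                                      n_steps = n_steps, weights = weights)
  }
  mean_ig <- acc / length(rows)
  nz <- Matrix::colSums(design$X[rows, , drop = FALSE] != 0)
  normalized <- ifelse(nz > 0, mean_ig / nz, NA_real_)

  feats <- design$columns
  feats$mean_ig <- mean_ig
  feats$nonzero_n <- as.integer(nz)
  feats$normalized <- normalized

  q_raw <- rowsum(mean_ig, feats$quarter)
  q_norm <- rowsum(ifelse(is.na(normalized), 0, normalized), feats$quarter)
  quarters <- data.frame(quarter = as.integer(rownames(q_raw)),
                         importance = q_raw[, 1],
                         importance_normalized = q_norm[, 1])
  rownames(quarters) <- NULL

  keep <- feats$nonzero_n > 0
  key <- paste(feats$vocabulary, feats$code, sep = "|")
  agg_n <- rowsum(ifelse(keep, feats$normalized, 0), key)
  agg_r <- rowsum(feats$mean_ig, key)
  first <- !duplicated(key)
  codes <- data.frame(vocabulary = feats$vocabulary[first],
                      code = feats$code[first],
                      description = feats$description[first],
                      importance = agg_n[key[first], 1],
                      mean_ig_sum = agg_r[key[first], 1],
                      stringsAsFactors = FALSE)
  ever_nz <- rowsum(as.numeric(keep), key)[key[first], 1] > 0
  codes <- codes[ever_nz, , drop = FALSE]
  codes <- codes[order(-codes$importance), , drop = FALSE]
  codes$rank <- seq_len(nrow(codes))
  rownames(codes) <- NULL

  structure(list(features = feats, quarters = quarters, codes = codes,
                 n_subset = length(rows), n_steps = n_steps),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, top = 10, ...) {
  cat(sprintf("Integrated-gradients attribution over %d patients (%d steps)\n",
              x$n_subset, x$n_steps))
  cat("Top codes by abundance-normalized importance:\n")
  print(head(x$codes[, c("rank", "vocabulary", "code", "description",
                         "importance")], top), row.names = FALSE)
  invisible(x)
}

#' Per-quarter importance series
#'
#' Sums the per-feature mean integrated gradients within each quarter; by
#' conservation the quarter sums add up to the total attribution mass.  A
#' normalized variant (summing abundance-normalized attributions) is
#' reported alongside.
#'
#' @param result An \code{attribution_result}.
#' @return Data frame with \code{quarter}, \code{importance} and
#'   \code{importance_normalized}.
#' @export
quarter_importance <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  result$quarters
}

#' @export
plot.attribution_result <- function(x, normalized = TRUE, ...) {
  q <- x$quarters
  y <- if (normalized) q$importance_normalized else q$importance
  graphics::barplot(y, names.arg = q$quarter,
                    xlab = "observation quarter",
                    ylab = if (normalized) "summed normalized IG" else
                      "summed IG", ...)
  invisible(x)
}
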