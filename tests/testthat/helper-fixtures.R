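# Shared fixtures and independent oracles.

# Hand-built minimal cohort: tables are supplied explicitly so featurization
# and baseline arithmetic can be checked against hand layouts.
toy_cohort <- function(patients, events = NULL, costs = NULL,
                       config = sim_config(n_patients = nrow(patients),
                                           n_obs_quarters = 4,
                                           vocab_sizes = c(DIAG = 5, DRUG = 3))) {
  if (is.null(events))
    events <- data.frame(patient_id = character(), quarter = integer(),
                         vocabulary = character(), code = character(),
                         stringsAsFactors = FALSE)
  if (is.null(costs))
    costs <- data.frame(patient_id = character(), quarter = integer(),
                        category = character(), amount = numeric(),
                        stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = patients$patient_id,
                      chronicity = 0, highrisk_flag = FALSE,
                      change_type = "none", stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, costs = costs,
                 truth = truth,
                 vocabulary = costnet:::build_catalogue(config$vocab_sizes),
                 config = config),
            class = "claims_cohort")
}

toy_patients <- function(n, sex = rep("F", n), birth_quarter = rep(-100L, n),
                         death_quarter = rep(NA_integer_, n),
                         coverage_end_quarter = rep(NA_integer_, n)) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), sex = sex,
             birth_quarter = as.integer(birth_quarter),
             death_quarter = as.integer(death_quarter),
             coverage_end_quarter = as.integer(coverage_end_quarter),
             stringsAsFactors = FALSE)
}

# Brute-force curve areas by exhaustive threshold enumeration (independent
# of the package's grouped-rank implementation).
brute_auroc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}

brute_auprc <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    called <- score >= t
    prec <- sum(positive & called) / sum(called)
    rec <- sum(positive & called) / sum(positive)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Dense forward pass of a fitted skip MLP, written independently of the
# package internals, for completeness checks of integrated gradients.
eval_mlp_total <- function(model, x, weights = NULL) {
  if (is.null(weights))
    weights <- as.numeric(model$categories != "incapacity_to_work")
  xs <- x / model$col_scale
  h <- NULL
  for (l in seq_len(model$n_hidden)) {
    z <- if (l == 1) as.numeric(xs %*% model$W_hidden[[l]])
         else as.numeric(h %*% model$W_hidden[[l]])
    h <- pmax(z + model$b_hidden[[l]], 0)
  }
  out <- as.numeric(xs %*% model$W_skip) + model$b_out
  if (model$n_hidden > 0) out <- out + as.numeric(h %*% model$W_top)
  out <- out * model$y_scale + model$y_center
  sum(weights * out)
}
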