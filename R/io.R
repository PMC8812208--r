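#' Write a cohort to a directory of CSV files
#'
#' Persists the cohort as plain CSV: \code{patients.csv}, \code{events.csv}
#' and \code{costs.csv} (the model-visible tables), plus \code{truth.csv}
#' (ground-truth labels, kept in a separate file so that modelling code can
#' be pointed at the first three only), \code{vocabulary.csv} (the code
#' catalogue with labels) and \code{config.csv} (key-value form of the
#' generating configuration).  \code{read_cohort} inverts the operation.
#'
#' @param cohort A \code{claims_cohort}.
#' @param directory Target directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "claims_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(directory, f), row.names = FALSE)
  w(cohort$patients, "patients.csv")
  w(cohort$events, "events.csv")
  w(cohort$costs, "costs.csv")
  w(cohort$truth, "truth.csv")
  w(cohort$vocabulary, "vocabulary.csv")
  cfg <- cohort$config
  kv <- data.frame(
    key = c("n_patients", "n_obs_quarters", "gap_quarters", "n_eval_quarters",
            "interaction_strength", "change_event_rate", "death_rate",
            "dropout_rate", "noise_dispersion", "recency_weight", "seed",
            paste0("vocab_", names(cfg$vocab_sizes))),
    value = c(cfg$n_patients, cfg$n_obs_quarters, cfg$gap_quarters,
              cfg$n_eval_quarters, cfg$interaction_strength,
              cfg$change_event_rate, cfg$death_rate, cfg$dropout_rate,
              cfg$noise_dispersion, cfg$recency_weight, cfg$seed,
              unname(cfg$vocab_sizes)),
    stringsAsFactors = FALSE)
  w(kv, "config.csv")
  invisible(directory)
}

check_columns <- function(df, expected, file) {
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop_cfg("%s: missing column(s) %s", file, paste(missing, collapse = ", "))
  df[, expected, drop = FALSE]
}

#' Read a cohort written by \code{write_cohort}
#'
#' Validates the schema and the basic invariants (non-negative amounts,
#' quarters are non-negative integers) and reports the offending column on
#' mismatch.
#'
#' @param directory Directory containing the cohort CSV files.
#' @return A \code{claims_cohort}.
#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  rd <- function(f, cls) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop_cfg("missing cohort file: %s", f)
    if (length(cls) > 1 || !is.na(cls[1])) {
      hdr <- names(read.csv(path, nrows = 0))
      cls <- cls[intersect(names(cls), hdr)]
      if (!length(cls)) cls <- NA
    }
    read.csv(path, stringsAsFactors = FALSE, colClasses = cls)
  }
  patients <- check_columns(
    rd("patients.csv", c(patient_id = "character", sex = "character",
                         birth_quarter = "integer", death_quarter = "integer",
                         coverage_end_quarter = "integer")),
    c("patient_id", "sex", "birth_quarter", "death_quarter",
      "coverage_end_quarter"), "patients.csv")
  events <- check_columns(
    rd("events.csv", c(patient_id = "character", quarter = "integer",
                       vocabulary = "character", code = "character")),
    c("patient_id", "quarter", "vocabulary", "code"), "events.csv")
  costs <- check_columns(
    rd("costs.csv", c(patient_id = "character", quarter = "integer",
                      category = "character", amount = "numeric")),
    c("patient_id", "quarter", "category", "amount"), "costs.csv")
  truth <- check_columns(
    rd("truth.csv", c(patient_id = "character", chronicity = "numeric",
                      highrisk_flag = "logical", change_type = "character")),
    c("patient_id", "chronicity", "highrisk_flag", "change_type"), "truth.csv")
  vocabulary <- check_columns(
    rd("vocabulary.csv", NA),
    c("vocabulary", "code", "group", "label", "effect"), "vocabulary.csv")
  kv <- rd("config.csv", c(key = "character", value = "numeric"))
  kv <- check_columns(kv, c("key", "value"), "config.csv")
  val <- function(k) kv$value[match(k, kv$key)]
  vs_rows <- grepl("^vocab_", kv$key)
  vocab_sizes <- kv$value[vs_rows]
  names(vocab_sizes) <- sub("^vocab_", "", kv$key[vs_rows])

  if (nrow(costs) && any(costs$amount < 0))
    stop_cfg("costs.csv: column 'amount' contains negative values")
  if (nrow(costs) && any(costs$quarter < 0))
    stop_cfg("costs.csv: column 'quarter' contains negative values")
  if (nrow(events) && any(events$quarter < 0))
    stop_cfg("events.csv: column 'quarter' contains negative values")
  bad_cat <- setdiff(unique(costs$category), COST_CATEGORIES)
  if (length(bad_cat))
    stop_cfg("costs.csv: column 'category' has unknown value(s) %s",
             paste(bad_cat, collapse = ", "))

  config <- sim_config(
    n_patients = val("n_patients"), n_obs_quarters = val("n_obs_quarters"),
    gap_quarters = val("gap_quarters"), n_eval_quarters = val("n_eval_quarters"),
    vocab_sizes = vocab_sizes,
    interaction_strength = val("interaction_strength"),
    change_event_rate = val("change_event_rate"),
    death_rate = val("death_rate"), dropout_rate = val("dropout_rate"),
    noise_dispersion = val("noise_dispersion"),
    recency_weight = val("recency_weight"), seed = val("seed"))

  structure(list(patients = patients, events = events, costs = costs,
                 truth = truth, vocabulary = vocabulary, config = config),
            class = "claims_cohort")
}
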