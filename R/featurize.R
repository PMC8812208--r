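#' Build the per-quarter feature index
#'
#' Determines the fixed per-quarter feature layout used to represent a
#' patient: a small demographic block (\code{birth_quarter} as a numeric
#' feature — dates are coded as quarter offsets from study start — and sex
#' as two one-hot columns), followed by one count column per retained
#' (vocabulary, code) pair.  A code is retained when its total occurrence
#' count over all counted patients and all indexed quarters is strictly
#' greater than \code{min_count}; the demographic block is always retained.
#' One-hot columns are ordered by vocabulary name then code
#' (lexicographically) so the layout is reproducible.
#'
#' @param cohort A \code{claims_cohort} with at least one patient.
#' @param min_count Strict occurrence threshold.  Defaults to the study
#'   threshold of 1000 entries scaled to the cohort size
#'   (\code{1000 * n_patients / 1.4e6}, floored at 5).
#' @param quarters 0-based observation quarters to index (default: the full
#'   observation period).  The per-quarter layout is replicated over these
#'   quarters, quarter-major.
#' @param patient_ids Patients whose events are counted for the threshold
#'   (default all).  Use the training split here so the index is frozen
#'   before the test split is seen.
#' @return An object of class \code{feature_index} with the per-quarter
#'   feature table, the quarter vector and \code{total_dim}.
#' @export
feature_index <- function(cohort, min_count = NULL, quarters = NULL,
                          patient_ids = NULL) {
  stopifnot(inherits(cohort, "claims_cohort"))
  if (nrow(cohort$patients) < 1) stop_cfg("cohort has no patients")
  if (is.null(quarters)) quarters <- 0:(cohort$config$n_obs_quarters - 1)
  quarters <- as.integer(quarters)
  if (is.null(min_count))
    min_count <- max(5, round(1000 * nrow(cohort$patients) / 1.4e6))
  if (min_count < 0) stop_cfg("min_count must be >= 0")

  ev <- cohort$events
  sel <- ev$quarter %in% quarters
  if (!is.null(patient_ids)) sel <- sel & ev$patient_id %in% patient_ids
  ev <- ev[sel, , drop = FALSE]
  key <- paste(ev$vocabulary, ev$code, sep = "|")
  counts <- table(key)
  kept <- names(counts)[counts > min_count]

  voc <- cohort$vocabulary
  voc_key <- paste(voc$vocabulary, voc$code, sep = "|")
  m <- match(kept, voc_key)
  onehot <- data.frame(
    kind = rep("onehot", length(kept)),
    vocabulary = sub("\\|.*$", "", kept),
    code = sub("^.*\\|", "", kept),
    description = ifelse(is.na(m), kept, voc$label[m]),
    stringsAsFactors = FALSE)
  onehot <- onehot[order(onehot$vocabulary, onehot$code), , drop = FALSE]

  demo <- data.frame(
    kind = c("numeric", "onehot", "onehot"),
    vocabulary = c("DEMO", "SEX", "SEX"),
    code = c("birth_quarter", "F", "M"),
    description = c("Birth date in quarters before study start",
                    "Female patient", "Male patient"),
    stringsAsFactors = FALSE)
  features <- rbind(demo, onehot)
  rownames(features) <- NULL

  structure(list(
    features = features,
    quarters = quarters,
    n_quarters = length(quarters),
    min_count = min_count,
    per_quarter = nrow(features),
    total_dim = length(quarters) * nrow(features)
  ), class = "feature_index")
}

#' Construct a feature index from an explicit descriptor table
#'
#' Low-level constructor for a \code{feature_index} given the per-quarter
#' feature descriptors directly (columns \code{kind}, \code{vocabulary},
#' \code{code}, optionally \code{description}) rather than deriving them
#' from a cohort; the layout is replicated over \code{quarters},
#' quarter-major.
#'
#' @param features Data frame of per-quarter feature descriptors.
#' @param quarters 0-based quarter indices.
#' @return A \code{feature_index}.
#' @export
new_feature_index <- function(features, quarters) {
  stopifnot(is.data.frame(features),
            all(c("kind", "vocabulary", "code") %in% names(features)))
  if (is.null(features$description)) features$description <- features$code
  structure(list(features = features, quarters = as.integer(quarters),
                 n_quarters = length(quarters), min_count = NA_integer_,
                 per_quarter = nrow(features),
                 total_dim = length(quarters) * nrow(features)),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf(
    "Feature index: %d features/quarter x %d quarters = %d columns (min_count %s)\n",
    x$per_quarter, x$n_quarters, x$total_dim, format(x$min_count)))
  tab <- table(x$features$vocabulary)
  cat("  per-quarter block:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

feature_keys <- function(index) {
  paste(index$features$vocabulary, index$features$code, sep = "|")
}

column_table <- function(index) {
  f <- index$features[rep(seq_len(index$per_quarter), index$n_quarters), ,
                      drop = FALSE]
  f$quarter <- rep(index$quarters, each = index$per_quarter)
  rownames(f) <- NULL
  f
}

column_names <- function(index) {
  ct <- column_table(index)
  sprintf("q%02d.%s.%s", ct$quarter, ct$vocabulary, ct$code)
}

#' Encode one patient-quarter as a feature vector
#'
#' One-hot slot j holds the number of times the indexed code was observed in
#' the quarter (repeated codes add up); codes absent from the index are
#' silently ignored.  Demographic slots are filled from \code{patient} when
#' supplied.
#'
#' @param events Event rows (columns \code{vocabulary}, \code{code}) for a
#'   single patient and quarter.
#' @param index A \code{feature_index}.
#' @param patient Optional single patient row (columns \code{sex},
#'   \code{birth_quarter}) for the demographic slots.
#' @return Named numeric vector of length \code{index$per_quarter}.
#' @export
encode_patient_quarter <- function(events, index, patient = NULL) {
  stopifnot(inherits(index, "feature_index"))
  v <- numeric(index$per_quarter)
  names(v) <- paste(index$features$vocabulary, index$features$code, sep = "|")
  if (nrow(events)) {
    pos <- match(paste(events$vocabulary, events$code, sep = "|"), names(v))
    pos <- pos[!is.na(pos)]
    if (length(pos)) {
      tab <- table(pos)
      v[as.integer(names(tab))] <- as.numeric(tab)
    }
  }
  if (!is.null(patient)) {
    v["DEMO|birth_quarter"] <- patient$birth_quarter
    v["SEX|F"] <- as.numeric(patient$sex == "F")
    v["SEX|M"] <- as.numeric(patient$sex == "M")
  }
  v
}

#' Assemble the sparse design matrix and the target matrix
#'
#' Concatenates each patient's per-quarter encodings over the indexed
#' quarters (quarter-major column order) into one sparse row per patient,
#' and sums each patient's per-category costs over the evaluation period
#' into the 7-column target matrix.  Rows of both matrices are aligned on
#' patient id.
#'
#' @param cohort A \code{claims_cohort}.
#' @param index A \code{feature_index} built on (a split of) the cohort.
#' @return An object of class \code{claims_design}: list with sparse
#'   \code{X} (patients x \code{total_dim}), dense \code{Y} (patients x 7,
#'   Euro), the per-column feature table \code{columns}, \code{patient_id}
#'   and the \code{index}.
#' @export
design_matrix <- function(cohort, index) {
  stopifnot(inherits(cohort, "claims_cohort"), inherits(index, "feature_index"))
  cfg <- cohort$config
  if (any(index$quarters < 0) || any(index$quarters >= cfg$n_obs_quarters))
    stop_cfg("index quarters outside the cohort's %d observation quarters",
             cfg$n_obs_quarters)
  pts <- cohort$patients
  n <- nrow(pts)
  pq <- index$per_quarter

  ev <- cohort$events
  qpos <- match(ev$quarter, index$quarters)
  fpos <- match(paste(ev$vocabulary, ev$code, sep = "|"), feature_keys(index))
  rpos <- match(ev$patient_id, pts$patient_id)
  ok <- !is.na(qpos) & !is.na(fpos) & !is.na(rpos)
  i <- rpos[ok]
  j <- (qpos[ok] - 1L) * pq + fpos[ok]

  # demographic block, replicated each quarter
  bq_col <- match("DEMO|birth_quarter", feature_keys(index))
  sexF_col <- match("SEX|F", feature_keys(index))
  sexM_col <- match("SEX|M", feature_keys(index))
  di <- integer(0); dj <- integer(0); dx <- numeric(0)
  for (q in seq_len(index$n_quarters)) {
    off <- (q - 1L) * pq
    if (!is.na(bq_col)) {
      di <- c(di, seq_len(n)); dj <- c(dj, rep(off + bq_col, n))
      dx <- c(dx, as.numeric(pts$birth_quarter))
    }
    if (!is.na(sexF_col)) {
      w <- which(pts$sex == "F")
      di <- c(di, w); dj <- c(dj, rep(off + sexF_col, length(w)))
      dx <- c(dx, rep(1, length(w)))
    }
    if (!is.na(sexM_col)) {
      w <- which(pts$sex == "M")
      di <- c(di, w); dj <- c(dj, rep(off + sexM_col, length(w)))
      dx <- c(dx, rep(1, length(w)))
    }
  }
  X <- Matrix::sparseMatrix(
    i = c(i, di), j = c(j, dj), x = c(rep(1, length(i)), dx),
    dims = c(n, index$total_dim),
    dimnames = list(pts$patient_id, column_names(index)))

  ev0 <- eval_start_quarter(cfg)
  ev_qs <- ev0:(ev0 + cfg$n_eval_quarters - 1)
  Y <- matrix(0, n, 7L, dimnames = list(pts$patient_id, COST_CATEGORIES))
  cc <- cohort$costs
  sel <- cc$quarter %in% ev_qs
  if (any(sel)) {
    ci <- match(cc$patient_id[sel], pts$patient_id)
    cj <- match(cc$category[sel], COST_CATEGORIES)
    agg <- rowsum(cc$amount[sel], ci + (cj - 1L) * n)
    Y[as.integer(rownames(agg))] <- agg[, 1]
  }

  structure(list(X = X, Y = Y, columns = column_table(index),
                 patient_id = pts$patient_id, index = index),
            class = "claims_design")
}

#' Persist a design to disk
#'
#' Writes the sparse design matrix in MatrixMarket format
#' (\code{matrix.mtx}) with a JSON sidecar manifest describing the columns
#' (\code{columns.json}: quarter, kind, vocabulary, code per column, plus
#' patient ids), and the target matrix as CSV (\code{targets.csv}).
#' \code{read_design} inverts the operation.
#'
#' @param design A \code{claims_design}.
#' @param directory Target directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_design <- function(design, directory) {
  stopifnot(inherits(design, "claims_design"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(design$X, file.path(directory, "matrix.mtx"))
  manifest <- list(patient_id = design$patient_id,
                   quarters = design$index$quarters,
                   min_count = design$index$min_count,
                   columns = design$columns[, c("quarter", "kind",
                                                "vocabulary", "code",
                                                "description")])
  jsonlite::write_json(manifest, file.path(directory, "columns.json"),
                       dataframe = "columns", na = "null")
  write.csv(data.frame(patient_id = design$patient_id, design$Y,
                       check.names = FALSE),
            file.path(directory, "targets.csv"), row.names = FALSE)
  invisible(directory)
}

#' @rdname write_design
#' @export
read_design <- function(directory) {
  X <- methods::as(Matrix::readMM(file.path(directory, "matrix.mtx")),
                   "CsparseMatrix")
  manifest <- jsonlite::read_json(file.path(directory, "columns.json"),
                                  simplifyVector = TRUE)
  cols <- as.data.frame(manifest$columns, stringsAsFactors = FALSE)
  tg <- read.csv(file.path(directory, "targets.csv"), check.names = FALSE)
  Y <- as.matrix(tg[, -1, drop = FALSE])
  rownames(Y) <- tg$patient_id
  per_q <- cols[cols$quarter == cols$quarter[1], c("kind", "vocabulary",
                                                   "code", "description")]
  idx <- new_feature_index(per_q, quarters = manifest$quarters)
  idx$min_count <- manifest$min_count
  dimnames(X) <- list(manifest$patient_id, column_names(idx))
  structure(list(X = X, Y = Y, columns = column_table(idx),
                 patient_id = manifest$patient_id, index = idx),
            class = "claims_design")
}

#' Row subset of a design
#'
#' Restricts a \code{claims_design} to a set of patients (train/test
#' splitting keeps \code{X} and \code{Y} aligned).
#'
#' @param design A \code{claims_design}.
#' @param rows Integer/logical row selector or patient ids.
#' @return A \code{claims_design} on the selected rows.
#' @export
subset_design <- function(design, rows) {
  stopifnot(inherits(design, "claims_design"))
  if (is.character(rows)) rows <- match(rows, design$patient_id)
  design$X <- design$X[rows, , drop = FALSE]
  design$Y <- design$Y[rows, , drop = FALSE]
  design$patient_id <- design$patient_id[if (is.logical(rows)) which(rows) else rows]
  design
}

#' @export
print.claims_design <- function(x, ...) {
  cat(sprintf("Design matrix: %d patients x %d features (%.3f%% nonzero)\n",
              nrow(x$X), ncol(x$X),
              100 * Matrix::nnzero(x$X) / prod(dim(x$X))))
  cat(sprintf("  targets: %d x %d cost categories (Euro)\n",
              nrow(x$Y), ncol(x$Y)))
  invisible(x)
}
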