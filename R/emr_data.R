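# EMR text dialect, feature vocabulary, binary encoding, fold plans and
# MCAR masking.
#
# Text dialect (tab-separated, UTF-8, "#" comment lines ignored):
#   patient_id \t class_label \t age \t gender \t code1;code2;...
# The 5th field may be empty (no recorded diagnoses). A code may carry an
# onset-age annotation as "code@age", which is stripped on parsing (onset
# ages are discarded by design).

#' Construct a table of patient records
#'
#' Patients are held in a data frame with one row per patient and a
#' list-column of ICD9 codes. Codes are de-duplicated and sorted; continuous
#' ages are floored to integer years.
#'
#' @param patient_id character vector of opaque identifiers
#' @param class_label one of `RE_CLASSES` or `"unknown"` per patient
#' @param age_years non-negative ages in years (floored to integers)
#' @param gender one of `GENDER_LEVELS` per patient
#' @param icd9_codes list of character vectors of ICD9 code strings
#' @return a data frame of class `emr_records`
#' @export
emr_records <- function(patient_id, class_label, age_years, gender, icd9_codes) {
  n <- length(patient_id)
  stopifnot(length(class_label) == n, length(age_years) == n,
            length(gender) == n, length(icd9_codes) == n)
  bad_class <- !class_label %in% c(RE_CLASSES, "unknown")
  if (any(bad_class))
    stop_("unknown class label(s): ", paste(unique(class_label[bad_class]), collapse = ", "),
          "; allowed: ", paste(c(RE_CLASSES, "unknown"), collapse = ", "))
  bad_gender <- !gender %in% GENDER_LEVELS
  if (any(bad_gender))
    stop_("unknown gender token(s): ", paste(unique(gender[bad_gender]), collapse = ", "),
          "; allowed: ", paste(GENDER_LEVELS, collapse = ", "))
  age <- floor(as.numeric(age_years))
  if (any(!is.finite(age)) || any(age < 0)) stop_("age_years must be finite and non-negative")
  codes <- lapply(icd9_codes, function(x) sort(unique(as.character(x)), method = "radix"))
  out <- data.frame(patient_id = as.character(patient_id),
                    class_label = as.character(class_label),
                    age_years = as.integer(age),
                    gender = as.character(gender),
                    stringsAsFactors = FALSE)
  out$icd9_codes <- codes
  class(out) <- c("emr_records", "data.frame")
  out
}

#' Parse an EMR text file into patient records
#'
#' Reads the tab-separated dialect described above. Empty lines and lines
#' starting with `#` are skipped. Duplicate ICD9 codes within a patient are
#' collapsed; `code@onset_age` annotations are stripped.
#'
#' @param path path to an existing EMR text file
#' @return an `emr_records` data frame, one row per non-empty data line
#' @export
parse_emr_file <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0)
    return(emr_records(character(), character(), integer(), character(), list()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad) > 0)
    stop_("malformed line ", keep[bad[1]], " in ", path,
          ": expected at least 4 tab-separated fields, got ", nf[bad[1]])
  get <- function(i) trimws(vapply(fields, function(f) if (length(f) >= i) f[i] else "", ""))
  age_raw <- get(3)
  age <- suppressWarnings(as.numeric(age_raw))
  if (any(is.na(age)))
    stop_("malformed line ", keep[which(is.na(age))[1]], " in ", path,
          ": age '", age_raw[which(is.na(age))[1]], "' is not numeric")
  codes <- lapply(get(5), function(s) {
    if (!nzchar(s)) return(character())
    x <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    sub("@.*$", "", x[nzchar(x)])  # strip onset-age annotations
  })
  emr_records(get(1), get(2), age, get(4), codes)
}

#' Write patient records in the EMR text dialect
#'
#' Inverse of [parse_emr_file()]: re-parsing the written file reproduces the
#' records exactly.
#'
#' @param records an `emr_records` data frame
#' @param path output file path
#' @export
write_emr_file <- function(records, path) {
  lines <- paste(records$patient_id, records$class_label, records$age_years,
                 records$gender,
                 vapply(records$icd9_codes, paste, "", collapse = ";"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build the feature vocabulary from a record corpus
#'
#' One binary feature per distinct ICD9 code, one per distinct observed
#' integer age (`age_<k>`), and the five gender features (`gender_<g>`).
#' Ordering is deterministic: gender features first, then ages ascending,
#' then ICD9 codes in lexicographic (byte) order — so column indices are
#' reproducible for a fixed corpus regardless of record order.
#'
#' @param records a non-empty `emr_records` data frame
#' @return an object of class `feature_vocab` with elements `feature_names`,
#'   `kind` (gender/age/icd9 per feature) and `index_of` (named integer map)
#' @export
build_vocabulary <- function(records) {
  if (nrow(records) == 0) stop_("cannot build a vocabulary from zero records")
  ages <- sort(unique(records$age_years))
  codes <- sort(unique(unlist(records$icd9_codes)), method = "radix")
  feature_names <- c(paste0("gender_", GENDER_LEVELS), paste0("age_", ages), codes)
  kind <- c(rep("gender", length(GENDER_LEVELS)), rep("age", length(ages)),
            rep("icd9", length(codes)))
  structure(list(feature_names = feature_names, kind = kind,
                 index_of = stats::setNames(seq_along(feature_names), feature_names)),
            class = "feature_vocab")
}

#' @export
print.feature_vocab <- function(x, ...) {
  cat("feature vocabulary:", length(x$feature_names), "features (",
      sum(x$kind == "gender"), "gender,", sum(x$kind == "age"), "age,",
      sum(x$kind == "icd9"), "ICD9 )\n")
  invisible(x)
}

#' Write / read a vocabulary as two-column TSV (index, feature_name)
#' @param vocab a `feature_vocab`
#' @param path file path
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(data.frame(index = seq_along(vocab$feature_names),
                                feature_name = vocab$feature_names,
                                kind = vocab$kind),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binary-encode a batch of patient records against a fixed vocabulary
#'
#' Row i carries a 1 exactly at the columns of patient i's ICD9 codes, its
#' age feature and its gender feature. Codes (or ages) absent from the
#' vocabulary — i.e. unseen at training time — are dropped, and the dropped
#' count is recorded in the `n_unseen` element and reported via `message()`.
#' Encoding is batch-invariant: encoding any row partition separately and
#' stacking equals one-shot encoding.
#'
#' @param records an `emr_records` data frame
#' @param vocab the `feature_vocab` fixed from the training corpus
#' @param quiet suppress the unseen-feature message
#' @return an `encoded_batch`: sparse 0/1 `matrix` (patients x features),
#'   integer `labels` (index into `RE_CLASSES`, NA for unknown), `row_ids`,
#'   the `vocab`, and `n_unseen`
#' @export
encode_batch <- function(records, vocab, quiet = FALSE) {
  n <- nrow(records)
  fi <- vocab$index_of
  per_row <- lapply(seq_len(n), function(i) {
    nm <- c(paste0("gender_", records$gender[i]),
            paste0("age_", records$age_years[i]),
            records$icd9_codes[[i]])
    unname(fi[nm])
  })
  cols <- unlist(per_row, use.names = FALSE)
  rows <- rep.int(seq_len(n), lengths(per_row))
  unseen <- is.na(cols)
  n_unseen <- sum(unseen)
  if (n_unseen > 0 && !quiet)
    message("encode_batch: dropped ", n_unseen, " feature observation(s) absent from the vocabulary")
  m <- Matrix::sparseMatrix(i = rows[!unseen], j = cols[!unseen], x = 1,
                            dims = c(n, length(vocab$feature_names)),
                            dimnames = list(records$patient_id, vocab$feature_names))
  labels <- match(records$class_label, RE_CLASSES)  # "unknown" -> NA
  structure(list(matrix = m, labels = labels, row_ids = records$patient_id,
                 vocab = vocab, n_unseen = n_unseen),
            class = "encoded_batch")
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat("encoded batch:", nrow(x$matrix), "patients x", ncol(x$matrix), "features;",
      sum(is.na(x$labels)), "unlabeled\n")
  invisible(x)
}

#' Plan a k-fold cross-validation partition with validation holdout
#'
#' Patients are shuffled (seeded) and dealt into k folds whose sizes differ
#' by at most one; across the k experiments the test folds tile the dataset.
#' `validation_fraction` of each training split is later held out for early
#' stopping and tuning (see [fold_split()]).
#'
#' @param n patient count
#' @param k number of folds (>= 2)
#' @param validation_fraction fraction of each training split held out
#' @param seed integer seed
#' @return a `fold_plan` with per-patient fold `assignments`
#' @export
make_fold_plan <- function(n, k = 10, validation_fraction = 0.1, seed = 1) {
  if (k < 2) stop_("k must be >= 2")
  if (k > n) stop_("k (", k, ") exceeds patient count (", n, ")")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop_("validation_fraction must be in [0, 1)")
  assignments <- integer(n)
  withr::with_seed(seed, {
    assignments[sample.int(n)] <- rep_len(seq_len(k), n)
  })
  structure(list(n = n, k = k, assignments = assignments,
                 validation_fraction = validation_fraction, seed = seed),
            class = "fold_plan")
}

#' Split patient indices into train / validation / test for one experiment
#'
#' @param plan a `fold_plan`
#' @param test_fold which fold (1..k) is the held-out test set
#' @return list with integer index vectors `train`, `val`, `test`
#' @export
fold_split <- function(plan, test_fold) {
  stopifnot(test_fold >= 1, test_fold <= plan$k)
  test <- which(plan$assignments == test_fold)
  rest <- which(plan$assignments != test_fold)
  n_val <- round(plan$validation_fraction * length(rest))
  val <- withr::with_seed(derive_seed(plan$seed, "val", test_fold),
                          sort(sample(rest, n_val)))
  list(train = setdiff(rest, val), val = val, test = test)
}

#' Write a fold plan as TSV (patient_id, fold, split) for one experiment
#' @param plan a `fold_plan`
#' @param row_ids patient identifiers, length `plan$n`
#' @param test_fold experiment index defining the train/val/test split
#' @param path output path
#' @export
write_fold_plan <- function(plan, row_ids, test_fold, path) {
  sp <- fold_split(plan, test_fold)
  split <- character(plan$n)
  split[sp$train] <- "train"; split[sp$val] <- "val"; split[sp$test] <- "test"
  utils::write.table(data.frame(patient_id = row_ids, fold = plan$assignments,
                                split = split),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mask feature observations completely at random (MCAR)
#'
#' Each eligible 1-entry of the encoded matrix is independently flipped to 0
#' with probability `rate`, emulating records with randomly missing feature
#' observations. Whole features (columns) are never removed and 0-entries are
#' never touched. With `protect_demographics = TRUE` the age and gender
#' columns are ineligible; by default all feature observations are eligible.
#'
#' @param batch an `encoded_batch`
#' @param rate masking probability in [0, 1)
#' @param seed integer seed
#' @param protect_demographics exclude age/gender columns from masking
#' @return a new `encoded_batch` with the same shape
#' @export
mask_observations <- function(batch, rate, seed = 1, protect_demographics = FALSE) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop_("rate must be in [0, 1)")
  if (rate == 0) return(batch)
  trip <- Matrix::summary(Matrix::drop0(batch$matrix))
  eligible <- rep(TRUE, nrow(trip))
  if (protect_demographics) {
    demo_cols <- which(batch$vocab$kind %in% c("gender", "age"))
    eligible <- !(trip$j %in% demo_cols)
  }
  drop <- rep(FALSE, nrow(trip))
  drop[eligible] <- withr::with_seed(derive_seed(seed, "mask"),
                                     stats::runif(sum(eligible)) < rate)
  keep <- trip[!drop, , drop = FALSE]
  out <- batch
  out$matrix <- Matrix::sparseMatrix(i = keep$i, j = keep$j, x = 1,
                                     dims = dim(batch$matrix),
                                     dimnames = dimnames(batch$matrix))
  out
}

#' Class composition of a labeled dataset
#'
#' Per-class counts and percentages (one decimal place), in canonical class
#' order.
#'
#' @param records an `emr_records` data frame with known labels
#' @return data frame with columns `class`, `count`, `percent`
#' @export
summarize_dataset <- function(records) {
  if (any(records$class_label == "unknown"))
    stop_("summarize_dataset requires known class labels")
  counts <- vapply(RE_CLASSES, function(cl) sum(records$class_label == cl), 0)
  class_composition(counts)
}

#' Class composition from a vector of per-class counts
#'
#' @param counts numeric vector named by class (any subset order), or an
#'   unnamed length-4 vector in canonical class order
#' @return data frame with columns `class`, `count`, `percent`
#' @export
class_composition <- function(counts) {
  if (is.null(names(counts))) {
    stopifnot(length(counts) == length(RE_CLASSES))
    names(counts) <- RE_CLASSES
  }
  counts <- counts[RE_CLASSES]
  total <- sum(counts)
  data.frame(class = RE_CLASSES, count = as.numeric(counts),
             percent = round(100 * as.numeric(counts) / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
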