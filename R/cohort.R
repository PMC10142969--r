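#' Classify the treatment protocol of eye records
#'
#' Labels each eye by its loading-phase timing: `standard` when the therapy
#' course (first injection to final observation) lies in 105--135 days and
#' the third-injection-to-observation gap in 49--70 days (about 8 weeks);
#' `short` when the course lies in 75--104 days and the gap in 21--48 days
#' (about 4 weeks); `excluded` otherwise.
#'
#' @param records data frame with columns `injection_date_1..3` and
#'   `final_date` (Date).
#' @return character vector of `"standard"`, `"short"`, `"excluded"`.
#' @examples
#' rec <- data.frame(injection_date_1 = as.Date("2020-01-01"),
#'                   injection_date_2 = as.Date("2020-01-30"),
#'                   injection_date_3 = as.Date("2020-02-28"),
#'                   final_date = as.Date("2020-04-27"))
#' classify_protocol(rec)   # course 117 d, gap 59 d -> standard
#' @export
classify_protocol <- function(records) {
  ok <- valid_dates(records)
  if (!all(ok))
    stop_config("missing or unordered dates in records: ",
                paste(utils::head(which(!ok), 5), collapse = ", "))
  course <- as.integer(records$final_date - records$injection_date_1)
  gap <- as.integer(records$final_date - records$injection_date_3)
  out <- rep("excluded", nrow(records))
  out[course >= 105 & course <= 135 & gap >= 49 & gap <= 70] <- "standard"
  out[course >= 75 & course <= 104 & gap >= 21 & gap <= 48] <- "short"
  out
}

# strictly increasing injections and final observation after the third
valid_dates <- function(records) {
  d1 <- records$injection_date_1; d2 <- records$injection_date_2
  d3 <- records$injection_date_3; df <- records$final_date
  ok <- !is.na(d1) & !is.na(d2) & !is.na(d3) & !is.na(df)
  ok & (ifelse(ok, d1 < d2 & d2 < d3 & d3 < df, FALSE))
}

#' Apply study exclusions
#'
#' Drops eyes without an outcome, without an imaging reference, with missing
#' or unordered dates, or whose timing falls outside both protocol windows,
#' and reports per-reason counts. The first applicable reason (in that order)
#' is recorded per dropped eye.
#'
#' @param records an eye-record data frame (see [generate_synthetic_cohort()]).
#' @return list with `kept` (records plus a `protocol` column), `dropped`
#'   (data frame `eye_id`, `reason`) and `counts` (named integer vector).
#' @export
apply_exclusions <- function(records) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  no_outcome <- is.na(records$outcome)
  reason[no_outcome] <- "no outcome"
  has_img <- if ("has_imaging" %in% names(records)) records$has_imaging else TRUE
  miss_img <- is.na(reason) & !(has_img %in% TRUE)
  reason[miss_img] <- "no imaging"
  bad_dates <- is.na(reason) & !valid_dates(records)
  reason[bad_dates] <- "invalid dates"

  prot <- rep(NA_character_, n)
  ok <- is.na(reason)
  if (any(ok)) prot[ok] <- classify_protocol(records[ok, , drop = FALSE])
  out_window <- ok & prot == "excluded"
  reason[out_window] <- "protocol excluded"

  kept <- records[is.na(reason), , drop = FALSE]
  kept$protocol <- prot[is.na(reason)]
  dropped <- data.frame(eye_id = records$eye_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  counts <- if (nrow(dropped)) table(dropped$reason) else table(character(0))
  list(kept = kept, dropped = dropped,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

# one row per patient; stratum attributes taken from the first eye (by
# eye_id order) so that a patient always belongs to exactly one stratum
patient_table <- function(records) {
  ord <- order(records$patient_id, records$eye_id)
  first <- records[ord, ][!duplicated(records$patient_id[ord]), ]
  data.frame(patient_id = first$patient_id,
             protocol = first$protocol,
             outcome = first$outcome,
             scan_bucket = as.character(first$n_scans),
             clinic = first$clinic,
             stringsAsFactors = FALSE)
}

#' Patient-level stratified train/validation/test split
#'
#' Samples patients (never single eyes) into partitions, stratified by
#' protocol, outcome and scan-count bucket. Within each stratum about 20% of
#' patients go to test and 20% of the remainder to validation. Because the
#' short-protocol subcohort is small, its non-training patients are merged
#' into a single hold-out test set. If any stratum holds fewer than
#' `min_stratum` patients, stratification degrades to protocol + outcome
#' with a warning.
#'
#' @param records kept eye records (must carry a `protocol` column, see
#'   [apply_exclusions()]).
#' @param seed integer seed for patient sampling.
#' @param test_frac,val_frac partition fractions (defaults 0.2 and 0.2).
#' @param min_stratum smallest stratum size tolerated before degrading.
#' @return data frame of class `split_assignment`: `eye_id`, `patient_id`,
#'   `partition` (`train`/`validation`/`test`), `protocol`.
#' @export
split_cohort <- function(records, seed, test_frac = 0.2, val_frac = 0.2,
                         min_stratum = 5L) {
  if (!"protocol" %in% names(records))
    stop_config("records must carry a 'protocol' column; run apply_exclusions() first")
  pt <- patient_table(records)
  for (p in unique(pt$protocol))
    if (sum(pt$protocol == p) < 5)
      stop_config("fewer than 5 patients in protocol '", p, "'")

  key <- paste(pt$protocol, pt$outcome, pt$scan_bucket, sep = "|")
  if (min(table(key)) < min_stratum) {
    warning("small strata: degrading stratification to protocol + outcome",
            call. = FALSE)
    key <- paste(pt$protocol, pt$outcome, sep = "|")
  }

  set.seed(seed)
  part <- stats::setNames(rep("train", nrow(pt)), pt$patient_id)
  for (k in sort(unique(key))) {
    ids <- sort(pt$patient_id[key == k])
    ids <- sample(ids)
    n <- length(ids)
    n_test <- round_half_up(test_frac * n)
    n_val <- round_half_up(val_frac * (n - n_test))
    if (n_test > 0) part[ids[seq_len(n_test)]] <- "test"
    if (n_val > 0) part[ids[n_test + seq_len(n_val)]] <- "validation"
  }
  # merge short-protocol non-training patients into one hold-out test set
  short_ids <- pt$patient_id[pt$protocol == "short"]
  part[short_ids][part[short_ids] == "validation"] <- "test"

  out <- data.frame(eye_id = records$eye_id,
                    patient_id = records$patient_id,
                    partition = unname(part[records$patient_id]),
                    protocol = records$protocol,
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Patient-level five-fold assignment, stratified by clinic and outcome
#'
#' Randomly samples training patients into `n_folds` folds within each
#' clinic-by-outcome stratum, so fold sizes differ by at most one patient
#' per stratum and all eyes of one patient share a fold.
#'
#' @param train_records eye records of the training partition.
#' @param seed integer seed.
#' @param n_folds number of folds (default 5).
#' @return data frame: `eye_id`, `patient_id`, `fold`.
#' @export
assign_folds <- function(train_records, seed, n_folds = 5L) {
  if (!"protocol" %in% names(train_records)) train_records$protocol <- "standard"
  pt <- patient_table(train_records)
  if (nrow(pt) < n_folds)
    stop_config("need at least ", n_folds, " training patients")
  set.seed(seed)
  fold <- stats::setNames(integer(nrow(pt)), pt$patient_id)
  key <- paste(pt$clinic, pt$outcome, sep = "|")
  for (k in sort(unique(key))) {
    ids <- sample(sort(pt$patient_id[key == k]))
    fold[ids] <- rep(seq_len(n_folds), length.out = length(ids))
  }
  data.frame(eye_id = train_records$eye_id,
             patient_id = train_records$patient_id,
             fold = unname(fold[train_records$patient_id]),
             stringsAsFactors = FALSE)
}
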