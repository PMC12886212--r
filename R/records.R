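#' Trial dataset container
#'
#' An `fbi_trial` object is a data frame with one row per participant and the
#' columns of the interchange schema: `participant_id`, `cohort_id`,
#' `cohort_order`, `target_dose_min`, `achieved_dose_min`, `completed`,
#' `nrs_t1`, `nrs_t2`, `nrs_t3` (11-point pain-intensity ratings taken
#' pre-intervention, immediately post, and at 24-h follow-up),
#' `ppt_left_t1`, `ppt_left_t2`, `ppt_right_t1`, `ppt_right_t2` (pressure pain
#' thresholds in kPa, each already the mean of three algometer readings),
#' `ownership` (the body-ownership questionnaire item, -3 to +3), and
#' `symptoms_24h` (free text, `"; "`-separated).
#'
#' @param participants data frame with the columns above (`nrs_t3`,
#'   `ownership` and `symptoms_24h` may be omitted; missing optional columns
#'   are filled with `NA`).
#' @return validated `fbi_trial` data frame, rows ordered by `cohort_order`.
#' @export
trial_dataset <- function(participants) {
  df <- as.data.frame(participants, stringsAsFactors = FALSE)
  for (opt in c("nrs_t3", "ownership", "symptoms_24h")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df <- df[order(df$cohort_order, df$participant_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fbi_trial", "data.frame")
  validate_trial(df)
  df
}

trial_columns <- c(
  "participant_id", "cohort_id", "cohort_order", "target_dose_min",
  "achieved_dose_min", "completed", "nrs_t1", "nrs_t2", "nrs_t3",
  "ppt_left_t1", "ppt_left_t2", "ppt_right_t1", "ppt_right_t2",
  "ownership", "symptoms_24h")

#' Validate a trial dataset
#'
#' Enforces the record invariants: integer pain ratings in 0-10, ownership in
#' -3..+3, positive pressure pain thresholds, achieved dose never above the
#' target, and completion exactly when the full target duration was achieved.
#' Cohorts must have two or three members sharing one target dose. Errors name
#' the offending participant row and field.
#'
#' @param x `fbi_trial` or plain data frame in the interchange schema.
#' @return `x` invisibly, if valid.
#' @export
validate_trial <- function(x) {
  missing_cols <- setdiff(trial_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) stop("dataset contains no participants", call. = FALSE)
  if (anyDuplicated(x$participant_id)) {
    stop("duplicated participant_id", call. = FALSE)
  }
  fail <- function(i, field, why) {
    stop(sprintf("participant %s: %s %s", x$participant_id[i], field, why),
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    for (field in c("nrs_t1", "nrs_t2", "nrs_t3")) {
      v <- x[[field]][i]
      if (is.na(v)) {
        if (field != "nrs_t3") fail(i, field, "is missing")
        next
      }
      if (v != round(v)) fail(i, field, "must be an integer")
      if (v < 0 || v > 10) fail(i, field, "out of range 0-10")
    }
    ow <- x$ownership[i]
    if (!is.na(ow) && (ow != round(ow) || ow < -3 || ow > 3)) {
      fail(i, "ownership", "out of range -3..3 or non-integer")
    }
    for (field in c("ppt_left_t1", "ppt_left_t2", "ppt_right_t1",
                    "ppt_right_t2")) {
      v <- x[[field]][i]
      if (!is.na(v) && v <= 0) fail(i, field, "must be positive")
    }
    if (x$target_dose_min[i] <= 0) fail(i, "target_dose_min", "must be positive")
    if (x$achieved_dose_min[i] > x$target_dose_min[i] + 1e-9) {
      fail(i, "achieved_dose_min", "exceeds target_dose_min")
    }
    comp <- abs(x$achieved_dose_min[i] - x$target_dose_min[i]) < 1e-9
    if (isTRUE(x$completed[i]) != comp) {
      fail(i, "completed", "inconsistent with achieved vs target dose")
    }
  }
  ct <- split(x, x$cohort_order)
  for (co in ct) {
    if (!nrow(co) %in% c(2L, 3L)) {
      stop(sprintf("cohort %s has %d member(s); cohorts have 2 or 3",
                   co$cohort_id[1], nrow(co)), call. = FALSE)
    }
    if (length(unique(co$target_dose_min)) != 1L) {
      stop(sprintf("cohort %s members disagree on target dose",
                   co$cohort_id[1]), call. = FALSE)
    }
    if (length(unique(co$cohort_id)) != 1L) {
      stop(sprintf("cohort order %s maps to several cohort ids",
                   co$cohort_order[1]), call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' The file dialect is comma-separated UTF-8 with a header row and `.` decimal
#' separator; see [trial_dataset()] for the column schema.
#'
#' @param path file path.
#' @return validated `fbi_trial` data frame.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character",
                                cohort_id = "character"))
  if ("symptoms_24h" %in% names(df)) {
    df$symptoms_24h <- as.character(df$symptoms_24h)
    df$symptoms_24h[is.na(df$symptoms_24h)] <- ""
  }
  trial_dataset(df)
}

#' Write a trial dataset
#'
#' `write_trial()` writes the interchange CSV; `trial_to_json()` writes the
#' same records as a JSON array for programmatic use.
#'
#' @param x `fbi_trial` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path) {
  validate_trial(x)
  out <- as.data.frame(x)[, trial_columns]
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_trial
#' @export
trial_to_json <- function(x, path) {
  validate_trial(x)
  jsonlite::write_json(as.data.frame(x)[, trial_columns], path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' The packaged duration-finding study dataset
#'
#' Per-participant records of the 20-participant, seven-cohort adaptive
#' duration-finding study of the cardio-visual full-body illusion in
#' fibromyalgia: target and achieved durations, completion flags, pain
#' intensity at the three timepoints, pressure pain thresholds for both
#' shoulders pre/post, the body-ownership item, and 24-h symptom reports.
#' Durations are decimal minutes ("22 min 12 s" is stored as 22.2). Six
#' cohorts had three participants; the 32-min cohort had two, neither of whom
#' completed the session (aborting at 22.2 and 18.05 min).
#'
#' @return `fbi_trial` data frame with 20 rows.
#' @seealso [fbi_cohort_demographics()] for cohort-level questionnaire
#'   summaries.
#' @export
fbi_trial <- function() {
  read_trial(system.file("extdata", "fbi_trial.csv", package = "fbidose",
                         mustWork = TRUE))
}

#' Cohort-level demographic and questionnaire summaries
#'
#' Per-cohort means of age, Widespread Pain Index, Symptom Severity Index,
#' small-fibre-neuropathy and pain-catastrophizing questionnaire totals, and
#' counts of participants meeting the ACR 2016 fibromyalgia criteria.
#' Item-level questionnaire responses were not recorded per participant, so
#' these summaries are the finest questionnaire resolution available for the
#' packaged study.
#'
#' @return data frame with one row per cohort.
#' @export
fbi_cohort_demographics <- function() {
  read.csv(system.file("extdata", "fbi_cohort_demographics.csv",
                       package = "fbidose", mustWork = TRUE),
           stringsAsFactors = FALSE,
           colClasses = c(cohort_id = "character"))
}

#' Per-cohort view of a trial dataset
#'
#' @param x `fbi_trial` data frame.
#' @return data frame with one row per cohort: id, enrolment order, target
#'   dose, size, and member ids (`"; "`-separated).
#' @export
trial_cohorts <- function(x) {
  validate_trial(x)
  sp <- split(as.data.frame(x), x$cohort_order)
  out <- do.call(rbind, lapply(sp, function(co) {
    data.frame(cohort_id = co$cohort_id[1],
               cohort_order = co$cohort_order[1],
               target_dose_min = co$target_dose_min[1],
               n = nrow(co),
               participant_ids = paste(co$participant_id, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cohort_order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.fbi_trial <- function(x, ...) {
  cat(sprintf("<fbi_trial> %d participants in %d cohorts\n",
              nrow(x), length(unique(x$cohort_order))))
  print(as.data.frame(x), ...)
  invisible(x)
}
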