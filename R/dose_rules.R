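#' Cohort outcome
#'
#' Bundles the per-member results of one cohort that the escalation rules
#' consume: completion of the target duration, the duration actually achieved,
#' and pain-intensity ratings immediately before and after the session.
#'
#' @param target_dose target duration in minutes.
#' @param completed logical vector, one per member (2 or 3 members).
#' @param achieved_dose achieved durations in minutes; must equal
#'   `target_dose` where `completed` and be below it otherwise.
#' @param nrs_t1,nrs_t2 integer pain ratings (0-10) pre and post.
#' @return `cohort_outcome` object.
#' @export
cohort_outcome <- function(target_dose, completed, achieved_dose, nrs_t1,
                           nrs_t2) {
  n <- length(completed)
  if (n < 2 || n > 3) stop("cohorts have 2 or 3 members", call. = FALSE)
  stopifnot(length(achieved_dose) == n, length(nrs_t1) == n,
            length(nrs_t2) == n, target_dose > 0)
  if (any(achieved_dose > target_dose + 1e-9)) {
    stop("achieved dose exceeds target dose", call. = FALSE)
  }
  if (any(completed & abs(achieved_dose - target_dose) > 1e-9)) {
    stop("completed members must achieve the full target dose", call. = FALSE)
  }
  structure(list(
    target_dose = target_dose,
    members = data.frame(completed = as.logical(completed),
                         achieved_dose = achieved_dose,
                         nrs_t1 = nrs_t1, nrs_t2 = nrs_t2)),
    class = "cohort_outcome")
}

#' Cohort-level tolerability and benefit verdicts
#'
#' A duration is *tolerable* when two or more cohort members completed the
#' full target duration. It is *beneficial* when two or more members showed an
#' immediate pain-intensity reduction of at least one point on the 11-point
#' rating scale (pre minus post >= 1).
#'
#' @param outcome `cohort_outcome` object.
#' @return logical verdict.
#' @export
assess_tolerable <- function(outcome) {
  stopifnot(inherits(outcome, "cohort_outcome"))
  sum(outcome$members$completed) >= 2
}

#' @rdname assess_tolerable
#' @export
assess_beneficial <- function(outcome) {
  stopifnot(inherits(outcome, "cohort_outcome"))
  sum(outcome$members$nrs_t1 - outcome$members$nrs_t2 >= 1) >= 2
}

#' Rule-engine configuration
#'
#' @param strict_3b logical; the rule-3b trigger compares the de-escalation
#'   candidate against the shortest early-termination duration observed so
#'   far. `FALSE` (default) treats a candidate equal to that duration as
#'   triggering (`>=`); `TRUE` requires it to be strictly longer.
#' @param after_deescalation how to increase the dose after a plain (rule-3a)
#'   de-escalated dose proves tolerable and beneficial; `"double"` (default)
#'   doubles it.
#' @param max_cohorts hard stop on the number of cohorts a simulated trial may
#'   enrol, guaranteeing termination.
#' @return `dose_rules_config` list.
#' @export
dose_rules_config <- function(strict_3b = FALSE,
                              after_deescalation = c("double"),
                              max_cohorts = 12L) {
  after_deescalation <- match.arg(after_deescalation)
  stopifnot(max_cohorts >= 1)
  structure(list(strict_3b = isTRUE(strict_3b),
                 after_deescalation = after_deescalation,
                 max_cohorts = as.integer(max_cohorts)),
            class = "dose_rules_config")
}

new_decision <- function(action, rule_id, next_dose = NULL,
                         recommended_dose = NULL) {
  structure(list(action = action, rule_id = rule_id,
                 next_dose = next_dose, recommended_dose = recommended_dose),
            class = "dose_decision")
}

#' @export
print.dose_decision <- function(x, ...) {
  cat(sprintf("<dose_decision> rule %s: %s%s\n", x$rule_id, x$action,
              if (!is.null(x$next_dose))
                sprintf(" -> %g min", x$next_dose) else ""))
  invisible(x)
}

# One history step as consumed by next_decision().
as_history_step <- function(step) {
  stopifnot(is.list(step), !is.null(step$target_dose),
            !is.null(step$tolerable), !is.null(step$beneficial))
  list(target_dose = step$target_dose,
       tolerable = isTRUE(step$tolerable),
       beneficial = isTRUE(step$beneficial),
       mean_reduction = step$mean_reduction %||% NA_real_,
       aborted_durations = step$aborted_durations %||% numeric(0))
}

# Core decision function operating on a prefix of steps whose origins
# (how each dose was arrived at) are already known.
decide_step <- function(steps, origins, config) {
  n <- length(steps)
  last <- steps[[n]]
  dose <- last$target_dose
  doses <- vapply(steps, `[[`, numeric(1), "target_dose")
  tol <- vapply(steps, `[[`, logical(1), "tolerable")
  ben <- vapply(steps, `[[`, logical(1), "beneficial")
  mred <- vapply(steps, `[[`, numeric(1), "mean_reduction")

  # Rule 5: a confirmation cohort found the dose tolerable and beneficial.
  if (origins[n] == "confirm" && last$tolerable && last$beneficial) {
    return(new_decision("terminate", "5", recommended_dose = dose))
  }

  # Rule 6: at least one earlier beneficial dose, and the two most recent
  # target doses were tolerable without improving on the best cohort-mean
  # pain reduction seen before each of them.
  if (n >= 3 && any(ben[seq_len(n - 2)]) && tol[n - 1] && tol[n] &&
      !anyNA(mred[seq_len(n)])) {
    no_further <- function(i) mred[i] <= max(mred[seq_len(i - 1)]) + 1e-12
    if (no_further(n - 1) && no_further(n)) {
      best <- which(tol & ben)
      rec <- if (length(best) > 0) doses[best[which.max(mred[best])]] else NULL
      return(new_decision("terminate", "6", recommended_dose = rec))
    }
  }

  if (last$tolerable) {
    # Rule 4, confirmation branch: a tolerated midpoint dose is repeated in a
    # fresh cohort (a tolerated confirmation that was not also beneficial is
    # re-confirmed).
    if (origins[n] %in% c("midpoint", "confirm")) {
      return(new_decision("confirm_same_dose", "4", next_dose = dose))
    }
    # Rule 4, escalation branch: a plain de-escalated dose that proved
    # tolerable and beneficial is increased (doubled).
    if (origins[n] == "deescalate" && last$beneficial) {
      return(new_decision("escalate_double", "4", next_dose = 2 * dose))
    }
    # Rules 1 and 2: tolerable doses escalate geometrically.
    return(new_decision("escalate_double", if (last$beneficial) "1" else "2",
                        next_dose = 2 * dose))
  }

  # Rule 3: the dose was not tolerated. The 3a candidate removes half of the
  # previous dose increment; for a first-cohort failure the increment is
  # defined as the starting dose itself.
  inc <- dose
  if (n > 1) {
    for (j in rev(seq_len(n - 1))) {
      if (abs(doses[j] - doses[j + 1]) > 1e-9) {
        inc <- abs(doses[j + 1] - doses[j])
        break
      }
    }
  }
  candidate <- dose - inc / 2
  aborts <- unlist(lapply(steps, `[[`, "aborted_durations"))
  trigger <- length(aborts) > 0 &&
    (if (config$strict_3b) candidate > min(aborts) + 1e-9
     else candidate >= min(aborts) - 1e-9)
  if (trigger) {
    tol_doses <- sort(unique(doses[tol]), decreasing = TRUE)
    if (length(tol_doses) >= 2) {
      # Rule 3b: probe the midpoint of the two highest tolerated doses.
      return(new_decision("midpoint_probe", "3b",
                          next_dose = mean(tol_doses[1:2])))
    }
  }
  new_decision("deescalate_half_increment", "3a", next_dose = candidate)
}

action_origin <- c(escalate_double = "escalate",
                   deescalate_half_increment = "deescalate",
                   midpoint_probe = "midpoint",
                   confirm_same_dose = "confirm")

# Walk a history, inferring how each dose was assigned and checking that the
# observed dose ladder matches what the rules prescribe.
infer_origins <- function(steps, config) {
  n <- length(steps)
  origins <- character(n)
  origins[1] <- "start"
  if (n == 1) return(origins)
  for (i in seq_len(n - 1)) {
    d <- decide_step(steps[seq_len(i)], origins[seq_len(i)], config)
    if (d$action == "terminate") {
      stop(sprintf(
        "inconsistent history: the rules terminate the trial after step %d (rule %s) but the history continues",
        i, d$rule_id), call. = FALSE)
    }
    if (abs(steps[[i + 1]]$target_dose - d$next_dose) > 1e-9) {
      stop(sprintf(
        "inconsistent history: step %d should have target dose %g (rule %s), found %g",
        i + 1, d$next_dose, d$rule_id, steps[[i + 1]]$target_dose),
        call. = FALSE)
    }
    origins[i + 1] <- action_origin[[d$action]]
  }
  origins
}

#' Next dose decision under the preset rules
#'
#' Applies the preset escalation/de-escalation rules to a chronological cohort
#' history and returns the action for the next cohort:
#' rules 1-2 double a tolerable dose (whether or not it was beneficial);
#' rule 3a answers intolerance by removing half of the previous dose
#' increment; rule 3b replaces the 3a candidate with the midpoint of the two
#' highest tolerated doses when the candidate would be at least as long as a
#' duration at which some participant already had to stop early; rule 4
#' increases a de-escalated dose that proved tolerable and beneficial, or
#' recruits a confirmation cohort at a tolerated midpoint dose; rule 5
#' terminates the study when a confirmation cohort finds the dose tolerable
#' and beneficial; rule 6 terminates after at least one beneficial dose when
#' two consecutive tolerable target doses bring no further reduction in mean
#' pain intensity.
#'
#' @param history list of steps, each a list with `target_dose`, `tolerable`,
#'   `beneficial`, and optionally `mean_reduction` (cohort mean of pre-minus-
#'   post pain, needed for rule 6) and `aborted_durations` (minutes at which
#'   members stopped early, needed for rule 3b).
#' @param config [dose_rules_config()].
#' @return `dose_decision` with `action`, `rule_id`, `next_dose` (absent for
#'   terminations) and `recommended_dose` (rule 5/6 terminations only).
#' @export
next_decision <- function(history, config = dose_rules_config()) {
  if (length(history) == 0) stop("history is empty", call. = FALSE)
  steps <- lapply(history, as_history_step)
  origins <- infer_origins(steps, config)
  decide_step(steps, origins, config)
}

#' Replay a trial through the rule engine
#'
#' Recomputes every cohort's tolerability and benefit verdict from the raw
#' member records and re-derives the dose ladder decision by decision,
#' checking that the observed target doses are exactly those the preset rules
#' prescribe.
#'
#' @param dataset `fbi_trial` data frame with cohorts in enrolment order.
#' @param config [dose_rules_config()].
#' @return `fbi_trace` object: a per-cohort `steps` data frame (verdicts,
#'   action, rule id, next dose), the maximal tolerated dose, the recommended
#'   dose (rule 5/6 terminations), termination status and rule, and any
#'   consistency warnings (e.g. a dose below a tolerated dose being assessed
#'   intolerable).
#' @export
replay_trial <- function(dataset, config = dose_rules_config()) {
  validate_trial(dataset)
  sp <- split(as.data.frame(dataset), dataset$cohort_order)
  sp <- sp[order(as.numeric(names(sp)))]
  steps <- list()
  rows <- list()
  terminated <- FALSE
  termination_rule <- NA_character_
  recommended <- NA_real_
  for (i in seq_along(sp)) {
    co <- sp[[i]]
    out <- cohort_outcome(co$target_dose_min[1], co$completed,
                          co$achieved_dose_min, co$nrs_t1, co$nrs_t2)
    tol <- assess_tolerable(out)
    ben <- assess_beneficial(out)
    steps[[i]] <- list(
      target_dose = out$target_dose, tolerable = tol, beneficial = ben,
      mean_reduction = mean(co$nrs_t1 - co$nrs_t2),
      aborted_durations = co$achieved_dose_min[!co$completed])
    if (terminated) {
      stop(sprintf(
        "inconsistent history: the rules terminate the trial after cohort %d (rule %s) but the dataset continues",
        i - 1, termination_rule), call. = FALSE)
    }
    dec <- next_decision(steps[seq_len(i)], config)
    if (dec$action == "terminate") {
      terminated <- TRUE
      termination_rule <- dec$rule_id
      recommended <- dec$recommended_dose %||% NA_real_
    }
    rows[[i]] <- data.frame(
      cohort_order = co$cohort_order[1], cohort_id = co$cohort_id[1],
      target_dose_min = out$target_dose, n = nrow(co),
      n_completed = sum(co$completed),
      n_responders = sum(co$nrs_t1 - co$nrs_t2 >= 1),
      tolerable = tol, beneficial = ben,
      mean_reduction = mean(co$nrs_t1 - co$nrs_t2),
      action = dec$action, rule_id = dec$rule_id,
      next_dose_min = dec$next_dose %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  steps_df <- do.call(rbind, rows)
  rownames(steps_df) <- NULL
  warnings <- character(0)
  tol_doses <- steps_df$target_dose_min[steps_df$tolerable]
  bad <- steps_df$target_dose_min[!steps_df$tolerable &
                                    steps_df$target_dose_min <
                                      max(c(tol_doses, -Inf))]
  if (length(bad) > 0) {
    warnings <- sprintf(
      "dose %g min assessed intolerable although a higher dose (%g min) was tolerated",
      bad, max(tol_doses))
  }
  structure(list(
    steps = steps_df,
    maximal_tolerated_dose = if (any(steps_df$tolerable))
      max(tol_doses) else NA_real_,
    recommended_dose = recommended,
    terminated = terminated,
    termination_rule = termination_rule,
    warnings = warnings), class = "fbi_trace")
}

#' Maximal tolerated dose of a trial trace
#'
#' The highest target duration assessed tolerable; `NA` when no dose was
#' tolerable.
#'
#' @param trace `fbi_trace` from [replay_trial()] or [simulate_trial()].
#' @return minutes, or `NA`.
#' @export
mtd <- function(trace) {
  stopifnot(inherits(trace, "fbi_trace"))
  trace$maximal_tolerated_dose
}

#' Export a trial trace as JSON
#'
#' One object per cohort step plus a summary block (maximal tolerated dose,
#' recommended dose, termination rule).
#'
#' @param trace `fbi_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
trace_to_json <- function(trace, path) {
  stopifnot(inherits(trace, "fbi_trace"))
  obj <- list(
    steps = trace$steps,
    summary = list(mtd_min = trace$maximal_tolerated_dose,
                   recommended_min = trace$recommended_dose,
                   terminated = trace$terminated,
                   termination_rule = trace$termination_rule,
                   warnings = trace$warnings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.fbi_trace <- function(x, ...) {
  cat(sprintf("<fbi_trace> %d cohorts; ladder: %s\n", nrow(x$steps),
              paste(x$steps$target_dose_min, collapse = " -> ")))
  cat(sprintf("  MTD: %s min; recommended: %s min; terminated: %s (rule %s)\n",
              format(x$maximal_tolerated_dose),
              format(x$recommended_dose), x$terminated,
              x$termination_rule))
  if (length(x$warnings) > 0) cat("  warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}
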