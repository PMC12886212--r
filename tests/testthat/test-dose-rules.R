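test_that("tolerability needs two completers; benefit needs two one-point responders", {
  all_done <- cohort_outcome(2, c(TRUE, TRUE, TRUE), c(2, 2, 2),
                             nrs_t1 = c(8, 3, 3), nrs_t2 = c(8, 3, 6))
  expect_true(assess_tolerable(all_done))
  expect_false(assess_beneficial(all_done))  # deltas 0, 0, +3

  none_done <- cohort_outcome(32, c(FALSE, FALSE), c(22.2, 18.05),
                              nrs_t1 = c(5, 5), nrs_t2 = c(5, 5))
  expect_false(assess_tolerable(none_done))

  two_of_three <- cohort_outcome(8, c(TRUE, TRUE, FALSE), c(8, 8, 5),
                                 nrs_t1 = c(7, 4, 5), nrs_t2 = c(7, 3, 3))
  expect_true(assess_tolerable(two_of_three))
  expect_true(assess_beneficial(two_of_three))  # deltas 0, -1, -2

  one_responder <- cohort_outcome(4, c(TRUE, TRUE, TRUE), c(4, 4, 4),
                                  nrs_t1 = c(5, 5, 5), nrs_t2 = c(4, 5, 5))
  expect_false(assess_beneficial(one_responder))

  expect_error(cohort_outcome(2, TRUE, 2, 5, 5), "2 or 3")
})

test_that("single-step decisions follow the preset rules", {
  tol_only <- list(list(target_dose = 2, tolerable = TRUE,
                        beneficial = FALSE))
  d <- next_decision(tol_only)
  expect_equal(d$action, "escalate_double")
  expect_equal(d$rule_id, "2")
  expect_equal(d$next_dose, 4)

  # first-cohort intolerance: the increment is defined as the starting dose
  first_fail <- list(list(target_dose = 2, tolerable = FALSE,
                          beneficial = FALSE,
                          aborted_durations = c(1.2, 1.5)))
  d <- next_decision(first_fail)
  expect_equal(d$action, "deescalate_half_increment")
  expect_equal(d$rule_id, "3a")
  expect_equal(d$next_dose, 1)
})

test_that("the observed escalation history reproduces the 3b midpoint and rule-5 stop", {
  h <- list(
    list(target_dose = 2, tolerable = TRUE, beneficial = FALSE,
         mean_reduction = -1),
    list(target_dose = 4, tolerable = TRUE, beneficial = FALSE,
         mean_reduction = -1 / 3),
    list(target_dose = 8, tolerable = TRUE, beneficial = TRUE,
         mean_reduction = 1),
    list(target_dose = 16, tolerable = TRUE, beneficial = TRUE,
         mean_reduction = 4 / 3),
    list(target_dose = 32, tolerable = FALSE, beneficial = FALSE,
         mean_reduction = 0, aborted_durations = c(22.2, 18.05)))
  # 3a candidate 24 is longer than the 18.05-min abort -> midpoint of 16, 8
  d <- next_decision(h)
  expect_equal(d$action, "midpoint_probe")
  expect_equal(d$rule_id, "3b")
  expect_equal(d$next_dose, 12)

  h[[6]] <- list(target_dose = 12, tolerable = TRUE, beneficial = TRUE,
                 mean_reduction = 4 / 3)
  d <- next_decision(h)
  expect_equal(d$action, "confirm_same_dose")
  expect_equal(d$rule_id, "4")
  expect_equal(d$next_dose, 12)

  h[[7]] <- list(target_dose = 12, tolerable = TRUE, beneficial = TRUE,
                 mean_reduction = 2)
  d <- next_decision(h)
  expect_equal(d$action, "terminate")
  expect_equal(d$rule_id, "5")
  expect_equal(d$recommended_dose, 12)
})

test_that("inconsistent histories raise state errors", {
  # a repeat of the same dose without a preceding midpoint probe
  h <- list(list(target_dose = 2, tolerable = TRUE, beneficial = TRUE),
            list(target_dose = 2, tolerable = TRUE, beneficial = TRUE))
  expect_error(next_decision(h), "inconsistent history")
  # continuing past a termination
  h <- list(
    list(target_dose = 2, tolerable = TRUE, beneficial = TRUE,
         mean_reduction = 2),
    list(target_dose = 4, tolerable = TRUE, beneficial = FALSE,
         mean_reduction = 0.1),
    list(target_dose = 8, tolerable = TRUE, beneficial = FALSE,
         mean_reduction = 0.1),
    list(target_dose = 16, tolerable = TRUE, beneficial = TRUE,
         mean_reduction = 3))
  expect_error(next_decision(h), "terminate")
  expect_error(next_decision(list()), "empty")
})

test_that("replaying the packaged study reproduces the dose ladder, MTD and recommendation", {
  trace <- replay_trial(fbi_trial())
  expect_equal(trace$steps$target_dose_min, c(2, 4, 8, 16, 32, 12, 12))
  expect_equal(trace$steps$rule_id, c("2", "2", "1", "1", "3b", "4", "5"))
  expect_equal(trace$maximal_tolerated_dose, 16)
  expect_equal(mtd(trace), 16)
  expect_equal(trace$recommended_dose, 12)
  expect_true(trace$terminated)
  expect_equal(trace$termination_rule, "5")
  expect_length(trace$warnings, 0)
  # determinism: a pure function of the dataset
  expect_equal(replay_trial(fbi_trial()), trace)
})

test_that("decisions agree with a brute-force rule encoding over all assessment sequences", {
  checked <- 0L
  walk <- function(history, dose, depth) {
    for (type in c("TB", "T", "I")) {
      steps <- c(history, list(make_step(dose, type)))
      dec <- next_decision(steps)
      orc <- oracle_decide(steps)
      expect_identical(dec$action, orc$action)
      expect_identical(dec$rule_id, orc$rule)
      checked <<- checked + 1L
      if (dec$action != "terminate") {
        expect_equal(dec$next_dose, orc$next_dose)
        if (depth < 6) walk(steps, dec$next_dose, depth + 1)
      }
    }
  }
  walk(list(), 2, 1)
  expect_gte(checked, 3 + 9 + 27)  # every prefix up to depth 6 was compared
})

test_that("ladder steps obey the arithmetic the rules prescribe", {
  # independent recomputation from the trace prefix
  check_ladder <- function(trace) {
    st <- trace$steps
    for (i in seq_len(nrow(st) - 1)) {
      nxt <- st$target_dose_min[i + 1]
      prefix <- st[seq_len(i), ]
      if (st$action[i] == "escalate_double") {
        expect_equal(nxt, 2 * st$target_dose_min[i])
      } else if (st$action[i] == "deescalate_half_increment") {
        deltas <- abs(diff(prefix$target_dose_min))
        inc <- if (any(deltas > 1e-9)) deltas[max(which(deltas > 1e-9))] else
          prefix$target_dose_min[1]
        expect_equal(nxt, st$target_dose_min[i] - inc / 2)
      } else if (st$action[i] == "midpoint_probe") {
        td <- sort(unique(prefix$target_dose_min[prefix$tolerable]),
                   decreasing = TRUE)
        expect_equal(nxt, mean(td[1:2]))
      } else if (st$action[i] == "confirm_same_dose") {
        expect_equal(nxt, st$target_dose_min[i])
      }
    }
  }
  check_ladder(replay_trial(fbi_trial()))
  set.seed(21)
  cfg <- sim_config()
  for (r in 1:10) check_ladder(simulate_trial(population_model(), cfg)$trace)
})

test_that("an intolerable dose below a tolerated one is flagged, not fatal", {
  cohort_rows <- function(ord, dose, achieved, n1, n2) {
    data.frame(participant_id = sprintf("%d%02d", ord, seq_along(achieved)),
               cohort_id = paste0("K", ord), cohort_order = ord,
               target_dose_min = dose, achieved_dose_min = achieved,
               completed = abs(achieved - dose) < 1e-9,
               nrs_t1 = n1, nrs_t2 = n2, nrs_t3 = n2,
               ppt_left_t1 = 100, ppt_left_t2 = 100, ppt_right_t1 = 100,
               ppt_right_t2 = 100, ownership = 0, symptoms_24h = "",
               stringsAsFactors = FALSE)
  }
  # 2 (tol), 4 (tol), 8 (intolerable; 3a candidate 6 >= abort 4.4 -> 3b
  # midpoint of 4 and 2 = 3), then 3 intolerable although 4 was tolerated
  dat <- trial_dataset(rbind(
    cohort_rows(1, 2, c(2, 2, 2), c(5, 5, 5), c(5, 5, 5)),
    cohort_rows(2, 4, c(4, 4, 4), c(5, 5, 5), c(5, 5, 5)),
    cohort_rows(3, 8, c(8, 4.4, 5.2), c(5, 5, 5), c(5, 5, 5)),
    cohort_rows(4, 3, c(3, 1.6, 2.0), c(5, 5, 5), c(5, 5, 5))))
  trace <- replay_trial(dat)
  expect_false(trace$terminated)
  expect_match(trace$warnings, "intolerable", all = FALSE)
  expect_equal(trace$maximal_tolerated_dose, 4)
})

test_that("trace JSON export carries steps and summary", {
  tmp <- withr::local_tempfile(fileext = ".json")
  trace_to_json(replay_trial(fbi_trial()), tmp)
  obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(obj$steps$target_dose_min, c(2, 4, 8, 16, 32, 12, 12))
  expect_equal(obj$summary$mtd_min, 16)
  expect_equal(obj$summary$recommended_min, 12)
  expect_equal(obj$summary$termination_rule, "5")
})
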