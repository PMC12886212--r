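# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (normal equations, sum formulas, a recursive
# re-encoding of the escalation rules) rather than calling package internals.

# OLS via explicit normal equations on the raw polynomial basis.
ols_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  n <- length(y)
  p <- degree + 1
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = as.numeric(beta), se = as.numeric(se), rss = sum(res^2))
}

# Pearson r via the classic sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Recursive re-encoding of the preset escalation rules, written directly
# from their prose statement. Each call classifies how the latest dose was
# assigned by re-deriving the decision taken after the previous cohort.
oracle_decide <- function(steps, strict_3b = FALSE) {
  n <- length(steps)
  doses <- vapply(steps, `[[`, numeric(1), "target_dose")
  tol <- vapply(steps, `[[`, logical(1), "tolerable")
  ben <- vapply(steps, `[[`, logical(1), "beneficial")
  mr <- vapply(steps, `[[`, numeric(1), "mean_reduction")
  prev_action <- if (n == 1) "start" else
    oracle_decide(steps[-n], strict_3b)$action
  # rule 5: a second cohort found the dose tolerable and beneficial
  if (prev_action == "confirm_same_dose" && tol[n] && ben[n]) {
    return(list(action = "terminate", rule = "5"))
  }
  # rule 6: >= 1 beneficial dose, then two tolerable doses with no further
  # mean pain reduction
  if (n >= 3 && any(ben[seq_len(n - 2)]) && tol[n - 1] && tol[n] &&
      mr[n - 1] <= max(mr[seq_len(n - 2)]) + 1e-12 &&
      mr[n] <= max(mr[seq_len(n - 1)]) + 1e-12) {
    return(list(action = "terminate", rule = "6"))
  }
  if (tol[n]) {
    # rule 4: tolerated midpoint (or repeated confirmation) -> confirm;
    # tolerable + beneficial after a plain decrease -> increase
    if (prev_action %in% c("midpoint_probe", "confirm_same_dose")) {
      return(list(action = "confirm_same_dose", rule = "4",
                  next_dose = doses[n]))
    }
    if (prev_action == "deescalate_half_increment" && ben[n]) {
      return(list(action = "escalate_double", rule = "4",
                  next_dose = 2 * doses[n]))
    }
    # rules 1 and 2: double a tolerable dose
    return(list(action = "escalate_double", rule = if (ben[n]) "1" else "2",
                next_dose = 2 * doses[n]))
  }
  # rule 3a: decrease by half the previous increment
  inc <- doses[n]
  if (n > 1) {
    deltas <- abs(diff(doses))
    nz <- which(deltas > 1e-9)
    if (length(nz) > 0) inc <- deltas[max(nz)]
  }
  cand <- doses[n] - inc / 2
  aborts <- unlist(lapply(steps, `[[`, "aborted_durations"))
  hit <- length(aborts) > 0 &&
    (if (strict_3b) cand > min(aborts) + 1e-9 else cand >= min(aborts) - 1e-9)
  if (hit) {
    td <- sort(unique(doses[tol]), decreasing = TRUE)
    if (length(td) >= 2) {
      # rule 3b: midpoint of the two highest tolerated doses
      return(list(action = "midpoint_probe", rule = "3b",
                  next_dose = (td[1] + td[2]) / 2))
    }
  }
  list(action = "deescalate_half_increment", rule = "3a", next_dose = cand)
}

# Synthetic history step for the exhaustive rule-space walk: outcome type
# "TB" (tolerable + beneficial), "T" (tolerable only) or "I" (intolerable,
# with two of three members stopping early).
make_step <- function(dose, type) {
  switch(type,
    TB = list(target_dose = dose, tolerable = TRUE, beneficial = TRUE,
              mean_reduction = 2, aborted_durations = numeric(0)),
    T = list(target_dose = dose, tolerable = TRUE, beneficial = FALSE,
             mean_reduction = 0.4, aborted_durations = numeric(0)),
    I = list(target_dose = dose, tolerable = FALSE, beneficial = FALSE,
             mean_reduction = 0, aborted_durations = dose * c(0.55, 0.65)))
}

# Small synthetic trial dataset (all completers, two cohorts) for loader and
# validation tests.
make_toy_trial <- function() {
  trial_dataset(data.frame(
    participant_id = sprintf("%03d", 1:6),
    cohort_id = rep(c("A", "B"), each = 3),
    cohort_order = rep(1:2, each = 3),
    target_dose_min = rep(c(2, 4), each = 3),
    achieved_dose_min = rep(c(2, 4), each = 3),
    completed = TRUE,
    nrs_t1 = c(5, 6, 7, 4, 5, 6), nrs_t2 = c(5, 6, 6, 3, 4, 4),
    nrs_t3 = c(5, 5, 6, 3, 4, 5),
    ppt_left_t1 = 100, ppt_left_t2 = 110,
    ppt_right_t1 = 90, ppt_right_t2 = 95,
    ownership = c(0, 1, -1, 2, 0, 1), symptoms_24h = "",
    stringsAsFactors = FALSE))
}
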