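#' Per-participant change scores
#'
#' Later minus earlier, so a negative value means pain decreased (for the
#' pain-intensity scale) and a positive value means the pressure pain
#' threshold rose.
#'
#' @param dataset `fbi_trial` data frame.
#' @param from,to timepoints `"t1"`, `"t2"` or `"t3"` (`"t3"` exists for the
#'   pain-intensity scale only).
#' @param outcome `"nrs"`, `"ppt_left"` or `"ppt_right"`.
#' @return numeric vector in dataset row order.
#' @export
change_scores <- function(dataset, from = "t1", to = "t2",
                          outcome = c("nrs", "ppt_left", "ppt_right")) {
  outcome <- match.arg(outcome)
  pick <- function(tp) {
    col <- paste0(outcome, "_", tp)
    if (!col %in% names(dataset)) {
      stop("unknown timepoint for outcome: ", col, call. = FALSE)
    }
    dataset[[col]]
  }
  pick(to) - pick(from)
}

#' Durations used as the dose-response predictor
#'
#' The regression predictor is the duration each participant actually
#' experienced. Completers contribute their target duration; early
#' terminators contribute the session length they reached, taken to whole
#' minutes by default (the convention of the original analysis, where the
#' 32-min cohort's aborted sessions enter as 22 and 18 min). With
#' `whole_minutes = FALSE` the exact decimal achieved durations are used.
#'
#' @param dataset `fbi_trial` data frame.
#' @param whole_minutes logical; floor early-terminators' achieved durations
#'   to whole minutes (default `TRUE`).
#' @return numeric vector of minutes, one per participant.
#' @export
regression_durations <- function(dataset, whole_minutes = TRUE) {
  d <- dataset$achieved_dose_min
  if (whole_minutes) d <- ifelse(dataset$completed, d, floor(d))
  d
}

#' Polynomial dose-response fit
#'
#' Ordinary least squares on the raw polynomial basis (1, d, ..., d^degree)
#' with the usual Gaussian summaries: coefficient estimates, standard errors
#' from the inverse cross-product matrix, two-sided t tests, 95% confidence
#' intervals, R-squared, adjusted R-squared, the overall F test, and the
#' Gaussian maximum-likelihood log-likelihood used by [lrt()].
#'
#' @param x predictor (duration in minutes).
#' @param y response (e.g. change in pain intensity).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return `fbi_fit` object; its `coefficients` component is a table with
#'   columns estimate, se, t, p, ci_lo, ci_hi ordered intercept first.
#' @export
fit_polynomial <- function(x, y, degree = 2) {
  stopifnot(degree %in% c(1, 2), length(x) == length(y))
  n <- length(y)
  p <- degree + 1
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  if (length(unique(x)) < p) {
    stop("need at least degree + 1 distinct predictor values", call. = FALSE)
  }
  dat <- data.frame(y = y, x = x)
  fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  rss <- sum(resid(fit)^2)
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  tq <- qt(0.975, df = n - p)
  coefs <- data.frame(term = c("intercept", "dose", "dose2")[seq_len(p)],
                      estimate = unname(est), se = unname(se),
                      t = unname(tval), p = unname(pval),
                      ci_lo = unname(est - tq * se),
                      ci_hi = unname(est + tq * se),
                      stringsAsFactors = FALSE)
  structure(list(
    degree = degree, n = n, coefficients = coefs,
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    f_stat = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    f_p = pf(unname(sm$fstatistic[1]), unname(sm$fstatistic[2]),
             unname(sm$fstatistic[3]), lower.tail = FALSE),
    rss = rss,
    loglik = -n / 2 * (log(2 * pi * rss / n) + 1),
    lm = fit), class = "fbi_fit")
}

#' @export
print.fbi_fit <- function(x, ...) {
  cat(sprintf("<fbi_fit> degree %d, n = %d: R2 = %.3f (adj %.3f), F(%g,%g) = %.2f, p = %.4g\n",
              x$degree, x$n, x$r2, x$adj_r2, x$df1, x$df2, x$f_stat, x$f_p))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test for nested polynomial fits
#'
#' Gaussian maximum-likelihood comparison of two ordinary-least-squares fits
#' of the same response: the statistic is `n * log(RSS_reduced / RSS_full)`
#' (twice the log-likelihood difference) referred to a chi-square
#' distribution on the difference in parameter count.
#'
#' @param reduced,full `fbi_fit` objects on the same data, with
#'   `reduced$degree < full$degree`.
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt <- function(reduced, full) {
  stopifnot(inherits(reduced, "fbi_fit"), inherits(full, "fbi_fit"))
  if (reduced$n != full$n) stop("fits use different n", call. = FALSE)
  if (reduced$degree >= full$degree) {
    stop("models are not nested (reduced degree must be lower)",
         call. = FALSE)
  }
  chi2 <- 2 * (full$loglik - reduced$loglik)
  df <- full$degree - reduced$degree
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Paired t test with Cohen's d
#'
#' The mean difference is `mean(post - pre)`; the t statistic uses the
#' standard deviation of the paired differences with n - 1 denominator.
#' Cohen's d is the mean difference over that standard deviation, with a 95%
#' confidence interval obtained by noncentral-t inversion.
#'
#' @param pre,post numeric vectors of equal length (n >= 2).
#' @return `fbi_paired` list: `mean_diff`, `ci95`, `t_stat`, `df`, `p`,
#'   `cohen_d`, `d_ci95`, `n`. Confidence intervals are reported (low, high).
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) stop("paired differences have zero variance", call. = FALSE)
  m <- mean(d)
  t_stat <- m / (sd_d / sqrt(n))
  tq <- qt(0.975, df = n - 1)
  ci <- c(m - tq * sd_d / sqrt(n), m + tq * sd_d / sqrt(n))
  # noncentrality-parameter inversion for the d interval
  ncp_limit <- function(prob) {
    f <- function(nc) suppressWarnings(pt(t_stat, n - 1, ncp = nc)) - prob
    lim <- abs(t_stat) + 20
    uniroot(f, c(-lim, lim), tol = 1e-8)$root
  }
  d_ci <- sort(c(ncp_limit(0.975), ncp_limit(0.025)) / sqrt(n))
  structure(list(mean_diff = m, ci95 = ci, t_stat = t_stat, df = n - 1,
                 p = 2 * pt(-abs(t_stat), df = n - 1),
                 cohen_d = m / sd_d, d_ci95 = d_ci, n = n),
            class = "fbi_paired")
}

#' @export
print.fbi_paired <- function(x, ...) {
  cat(sprintf(
    "<fbi_paired> mean diff %.2f (95%% CI %.2f, %.2f), t(%d) = %.2f, p = %.4g, d = %.2f (95%% CI %.2f, %.2f)\n",
    x$mean_diff, x$ci95[1], x$ci95[2], x$df, x$t_stat, x$p, x$cohen_d,
    x$d_ci95[1], x$d_ci95[2]))
  invisible(x)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ANCOVA with estimated marginal means
#'
#' Linear model `post ~ pre + group`. Effect F tests use drop-term sums of
#' squares against the full-model residual mean square (for the group factor,
#' entered last, this equals the incremental F over the covariate-only
#' model). Eta-squared for each effect is its drop-term sum of squares over
#' the total of both effect sums plus the residual sum. Estimated marginal
#' means are group predictions at the grand mean of the covariate; all
#' pairwise contrasts are reported with standard errors from the coefficient
#' covariance and Bonferroni-adjusted p values (multiplier = number of
#' pairs).
#'
#' @param post numeric response (post-intervention scores).
#' @param pre numeric covariate (baseline scores).
#' @param group factor or vector coercible to factor, >= 2 levels.
#' @return `fbi_ancova` list with components `f_factor`, `df_factor`,
#'   `df_resid`, `p_factor`, `eta2_factor`, `f_covariate`, `p_covariate`,
#'   `eta2_covariate`, `emms` (named vector), `pairwise` (data frame with
#'   diff, se, t, p, p_bonferroni), `n`, `levels`.
#' @export
ancova <- function(post, pre, group) {
  group <- factor(group)
  n <- length(post)
  k <- nlevels(group)
  stopifnot(length(pre) == n, length(group) == n, k >= 1)
  if (n <= k + 1) stop("too few observations for the design", call. = FALSE)
  if (k == 1) {
    # degenerate design: no factor; the model collapses to post ~ pre
    fit <- lm(post ~ pre)
    rss <- sum(resid(fit)^2)
    df_resid <- n - 2
    ss_cov <- sum((post - mean(post))^2) - rss
    f_cov <- ss_cov / (rss / df_resid)
    return(structure(list(
      f_factor = NA_real_, df_factor = 0L, df_resid = df_resid,
      p_factor = NA_real_, eta2_factor = NA_real_,
      f_covariate = f_cov,
      p_covariate = pf(f_cov, 1, df_resid, lower.tail = FALSE),
      eta2_covariate = ss_cov / (ss_cov + rss),
      emms = setNames(mean(post), levels(group)),
      pairwise = data.frame(), n = n, levels = levels(group)),
      class = "fbi_ancova"))
  }
  dat <- data.frame(post = post, pre = pre, group = group)
  full <- lm(post ~ pre + group, data = dat)
  if (any(is.na(coef(full)))) {
    stop("singular design: group confounded with covariate", call. = FALSE)
  }
  rss_full <- sum(resid(full)^2)
  df_resid <- n - k - 1
  mse <- rss_full / df_resid
  ss_factor <- sum(resid(lm(post ~ pre, data = dat))^2) - rss_full
  ss_cov <- sum(resid(lm(post ~ group, data = dat))^2) - rss_full
  f_factor <- (ss_factor / (k - 1)) / mse
  f_cov <- ss_cov / mse
  ss_effects_total <- ss_factor + ss_cov + rss_full
  # estimated marginal means at the grand-mean covariate
  nd <- data.frame(pre = mean(pre), group = factor(levels(group),
                                                   levels = levels(group)))
  emms <- setNames(predict(full, nd), levels(group))
  # pairwise contrasts via the coefficient covariance
  X <- model.matrix(~ pre + group,
                    data = transform(nd, pre = mean(pre)))
  V <- vcov(full)
  pairs <- utils::combn(levels(group), 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   diff = NA_real_, se = NA_real_, t = NA_real_,
                   p = NA_real_, p_bonferroni = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- match(pairs[1, j], levels(group))
    i2 <- match(pairs[2, j], levels(group))
    cv <- X[i1, ] - X[i2, ]
    diff <- sum(cv * coef(full))
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tv <- diff / se
    pv <- 2 * pt(-abs(tv), df = df_resid)
    pw[j, c("diff", "se", "t", "p", "p_bonferroni")] <-
      c(diff, se, tv, pv, min(1, pv * m))
  }
  structure(list(
    f_factor = f_factor, df_factor = k - 1, df_resid = df_resid,
    p_factor = pf(f_factor, k - 1, df_resid, lower.tail = FALSE),
    eta2_factor = ss_factor / ss_effects_total,
    f_covariate = f_cov,
    p_covariate = pf(f_cov, 1, df_resid, lower.tail = FALSE),
    eta2_covariate = ss_cov / ss_effects_total,
    emms = emms, pairwise = pw, n = n, levels = levels(group)),
    class = "fbi_ancova")
}

#' @export
print.fbi_ancova <- function(x, ...) {
  cat(sprintf(
    "<fbi_ancova> factor F(%d,%d) = %.2f, p = %.4g, eta2 = %.2f; covariate F(1,%d) = %.2f, p = %.4g, eta2 = %.2f\n",
    x$df_factor, x$df_resid, x$f_factor, x$p_factor, x$eta2_factor,
    x$df_resid, x$f_covariate, x$p_covariate, x$eta2_covariate))
  cat("  adjusted means:\n")
  print(round(x$emms, 3))
  invisible(x)
}

#' Per-duration-group outcome summary
#'
#' Means of the pain-intensity ratings at the three timepoints and of the
#' two change scores, grouped by target duration (so the two 12-min cohorts
#' pool into one group).
#'
#' @param dataset `fbi_trial` data frame.
#' @return data frame, one row per target dose.
#' @export
cohort_summary <- function(dataset) {
  validate_trial(dataset)
  sp <- split(as.data.frame(dataset), dataset$target_dose_min)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(target_dose_min = g$target_dose_min[1], n = nrow(g),
               mean_nrs_t1 = mean(g$nrs_t1), mean_nrs_t2 = mean(g$nrs_t2),
               mean_nrs_t3 = mean(g$nrs_t3),
               mean_change_t1_t2 = mean(g$nrs_t2 - g$nrs_t1),
               mean_change_t2_t3 = mean(g$nrs_t3 - g$nrs_t2))
  }))
  out <- out[order(out$target_dose_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dose-response model summary table
#'
#' Fits linear and quadratic models of each outcome's change score on the
#' regression durations and lays the summaries out one row per term
#' (model, R2, adjusted R2, F with df, model p, term, B, 95% CI, SE, t, p),
#' ready to write as CSV.
#'
#' @param dataset `fbi_trial` data frame.
#' @param outcomes character vector among `"nrs"`, `"ppt_left"`,
#'   `"ppt_right"`, `"ownership"`.
#' @param whole_minutes passed to [regression_durations()].
#' @return data frame.
#' @export
model_summary_table <- function(dataset,
                                outcomes = c("nrs", "ppt_left", "ppt_right",
                                             "ownership"),
                                whole_minutes = TRUE) {
  x <- regression_durations(dataset, whole_minutes = whole_minutes)
  rows <- list()
  for (oc in outcomes) {
    y <- if (oc == "ownership") dataset$ownership else
      change_scores(dataset, "t1", "t2", oc)
    for (deg in 1:2) {
      fit <- fit_polynomial(x, y, degree = deg)
      cf <- fit$coefficients[-1, , drop = FALSE]  # slope terms only
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, model = if (deg == 1) "linear" else "quadratic",
        r2 = fit$r2, adj_r2 = fit$adj_r2, f = fit$f_stat,
        df1 = fit$df1, df2 = fit$df2, model_p = fit$f_p,
        term = cf$term, b = cf$estimate, ci_lo = cf$ci_lo, ci_hi = cf$ci_hi,
        se = cf$se, t = cf$t, p = cf$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
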