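study <- fbi_trial()

test_that("change scores are later minus earlier", {
  ch <- change_scores(study, "t1", "t2", "nrs")
  expect_equal(ch[study$participant_id == "018"], -3)
  expect_equal(sum(ch), -13)
  expect_equal(change_scores(study, "t1", "t1", "nrs"), rep(0, 20))
  expect_error(change_scores(study, "t1", "t3", "ppt_left"), "timepoint")
  expect_equal(change_scores(study, "t1", "t2", "ppt_left"),
               study$ppt_left_t2 - study$ppt_left_t1)
})

test_that("regression durations use achieved doses, whole-minute by default", {
  d <- regression_durations(study)
  expect_equal(sort(unique(d)), c(2, 4, 8, 12, 16, 18, 22))
  expect_equal(sum(d == 12), 6)
  exact <- regression_durations(study, whole_minutes = FALSE)
  expect_setequal(setdiff(exact, d), c(22.2, 18.05))
  # the convention reproduces the reported linear slope (normal equations)
  slope <- ols_oracle(d, change_scores(study), 1)$beta[2]
  expect_equal(round(slope, 2), -0.10)
})

test_that("polynomial fits agree with a normal-equations oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- runif(n, 0, 30)
    y <- rnorm(n, 2 - 0.3 * x + 0.01 * x^2, 1)
    deg <- sample(1:2, 1)
    fit <- fit_polynomial(x, y, deg)
    orc <- ols_oracle(x, y, deg)
    expect_equal(fit$coefficients$estimate, orc$beta, tolerance = 1e-10)
    expect_equal(fit$coefficients$se, orc$se, tolerance = 1e-10)
    expect_equal(fit$rss, orc$rss, tolerance = 1e-10)
  }
  # exactly linear data: quadratic term vanishes, fit is perfect
  x <- c(1, 3, 5, 8, 13)
  fit <- suppressWarnings(fit_polynomial(x, 2 * x + 1, 2))  # perfect fit
  expect_equal(fit$coefficients$estimate[3], 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(fit_polynomial(c(1, 2), c(1, 2), 2), "observations")
  expect_error(fit_polynomial(rep(1, 5), rnorm(5), 1), "distinct")
})

test_that("the study's quadratic dose-response summary is reproduced", {
  x <- regression_durations(study)
  ch <- change_scores(study)
  quad <- fit_polynomial(x, ch, 2)
  cf <- setNames(quad$coefficients$estimate, quad$coefficients$term)
  expect_equal(round(unname(cf[c("dose2", "dose", "intercept")]), 2),
               c(0.02, -0.58, 2.14))
  expect_equal(round(quad$adj_r2, 2), 0.52)
  expect_equal(round(quad$f_stat, 2), 11.46)
  expect_equal(c(quad$df1, quad$df2), c(2, 17))
  lin <- fit_polynomial(x, ch, 1)
  expect_equal(round(lin$adj_r2, 2), 0.17)
})

test_that("likelihood-ratio comparison matches n*log(RSS ratio) and is non-negative", {
  x <- regression_durations(study)
  ch <- change_scores(study)
  lin <- fit_polynomial(x, ch, 1)
  quad <- fit_polynomial(x, ch, 2)
  out <- lrt(lin, quad)
  expect_equal(out$chi2, 20 * log(lin$rss / quad$rss))
  expect_equal(round(out$chi2, 2), 12.37)
  expect_equal(out$df, 1)
  expect_lt(out$p, 0.001)
  expect_error(lrt(quad, lin), "nested")

  # chi-square is zero exactly when the added coefficient is zero: an odd
  # response over a symmetric design leaves the quadratic term at 0
  xs <- c(-2, -1, 0, 1, 2)
  ys <- xs^3
  z <- lrt(fit_polynomial(xs, ys, 1), fit_polynomial(xs, ys, 2))
  expect_equal(z$chi2, 0, tolerance = 1e-8)
  set.seed(7)
  for (i in 1:20) {
    xr <- runif(8); yr <- rnorm(8)
    expect_gte(lrt(fit_polynomial(xr, yr, 1),
                   fit_polynomial(xr, yr, 2))$chi2, 0)
    # adding a term can only help the coefficient of determination
    expect_gte(fit_polynomial(xr, yr, 2)$r2, fit_polynomial(xr, yr, 1)$r2)
  }
})

test_that("paired tests reproduce the threshold shifts with Cohen's d intervals", {
  left <- paired_t(study$ppt_left_t1, study$ppt_left_t2)
  expect_equal(round(left$mean_diff, 2), 17.33)
  # printed t/CI differ in the last digit (inputs are 2-dp table values)
  expect_equal(left$t_stat, 2.29, tolerance = 0.01)
  expect_equal(left$df, 19)
  expect_equal(round(left$p, 3), 0.034)
  expect_equal(round(left$cohen_d, 2), 0.51)
  expect_equal(round(left$d_ci95, 2), c(0.04, 0.97))

  right <- paired_t(study$ppt_right_t1, study$ppt_right_t2)
  expect_equal(round(right$mean_diff, 2), 25.60)
  expect_equal(right$t_stat, 4.22, tolerance = 0.01)
  expect_equal(round(right$cohen_d, 2), 0.94)
  expect_equal(round(right$d_ci95, 2), c(0.40, 1.46))

  # antisymmetry under swapping pre and post
  swapped <- paired_t(study$ppt_left_t2, study$ppt_left_t1)
  expect_equal(swapped$mean_diff, -left$mean_diff)
  expect_equal(swapped$t_stat, -left$t_stat)
  expect_equal(swapped$cohen_d, -left$cohen_d)
  expect_equal(swapped$p, left$p)
  expect_equal(swapped$d_ci95, -rev(left$d_ci95), tolerance = 1e-6)

  expect_error(paired_t(1:5, 1:5), "zero variance")
})

test_that("correlation matches the sum-formula oracle and behaves under sign flips", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  ch <- change_scores(study)
  got <- pearson_test(study$ownership, ch)
  expect_equal(got$r, pearson_oracle(study$ownership, ch), tolerance = 1e-12)
  flipped <- pearson_test(-study$ownership, ch)
  expect_equal(flipped$r, -got$r)
  expect_equal(flipped$p, got$p)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("ANCOVA reproduces the baseline-adjusted duration analysis", {
  an <- ancova(study$nrs_t2, study$nrs_t1, study$target_dose_min)
  expect_equal(round(an$f_factor, 2), 3.71)
  expect_equal(c(an$df_factor, an$df_resid), c(5, 13))
  expect_equal(round(an$p_factor, 3), 0.026)
  expect_equal(round(an$eta2_factor, 2), 0.26)
  expect_equal(round(an$f_covariate, 2), 40.08)
  expect_equal(round(an$eta2_covariate, 2), 0.56)
  pw <- an$pairwise
  row <- pw[pw$group1 == "2" & pw$group2 == "12", ]
  # reported as EMM(12) - EMM(2)
  expect_equal(round(unname(an$emms["12"] - an$emms["2"]), 2), -2.60)
  expect_equal(round(row$se, 2), 0.72)
  expect_equal(round(row$p_bonferroni, 3), 0.049)
  expect_equal(nrow(pw), 15)  # all pairs of 6 groups
})

test_that("ANCOVA agrees with emmeans/car as an independent route", {
  skip_if_not_installed("emmeans")
  skip_if_not_installed("car")
  an <- ancova(study$nrs_t2, study$nrs_t1, study$target_dose_min)
  dat <- data.frame(post = study$nrs_t2, pre = study$nrs_t1,
                    g = factor(study$target_dose_min))
  fit <- lm(post ~ pre + g, data = dat)
  aov3 <- car::Anova(fit, type = 3)
  expect_equal(an$f_factor, aov3["g", "F value"], tolerance = 1e-10)
  expect_equal(an$f_covariate, aov3["pre", "F value"], tolerance = 1e-10)
  em <- emmeans::emmeans(fit, "g")
  expect_equal(unname(an$emms), summary(em)$emmean, tolerance = 1e-10)
  prs <- summary(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
  ours <- an$pairwise
  expect_equal(ours$diff, prs$estimate, tolerance = 1e-10)
  expect_equal(ours$se, prs$SE, tolerance = 1e-10)
  expect_equal(ours$p_bonferroni, prs$p.value, tolerance = 1e-10)
})

test_that("single-group ANCOVA collapses to the simple baseline regression", {
  set.seed(33)
  pre <- rnorm(12, 5); post <- pre + rnorm(12)
  an <- ancova(post, pre, rep("all", 12))
  ref <- fit_polynomial(pre, post, 1)
  expect_equal(an$f_covariate, ref$f_stat, tolerance = 1e-10)
  expect_true(is.na(an$f_factor))
  expect_error(ancova(post, pre, seq_len(12)), "too few")
})

test_that("per-duration summaries pool the two 12-min cohorts", {
  cs <- cohort_summary(study)
  expect_equal(cs$target_dose_min, c(2, 4, 8, 12, 16, 32))
  expect_equal(cs$n, c(3, 3, 3, 6, 3, 2))
  r12 <- cs[cs$target_dose_min == 12, ]
  expect_equal(round(r12$mean_change_t1_t2, 2), -1.67)
  expect_equal(round(r12$mean_change_t2_t3, 2), -0.17)
  r32 <- cs[cs$target_dose_min == 32, ]
  expect_equal(r32$mean_nrs_t1, 5)
  tab <- model_summary_table(study)
  expect_equal(nrow(tab), 4 * 3)  # 4 outcomes x (1 linear + 2 quadratic terms)
  expect_equal(round(tab$b[tab$outcome == "nrs" & tab$term == "dose" &
                             tab$model == "quadratic"], 2), -0.58)
})
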