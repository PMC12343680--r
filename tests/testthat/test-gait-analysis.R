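# Gait-trial analysis: filtering, step metrics, outlier rejection,
# normalization, upper-extremity effort and statistics.

test_that("zero-lag filter has unit DC gain and half amplitude at cutoff", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  # constant signal unchanged
  expect_equal(lowpass_zero_lag(rep(3.7, length(t)), fs, 6),
               rep(3.7, length(t)), tolerance = 1e-6)
  # sine at exactly the 6 Hz cutoff: amplitude ratio 1/2 after settling
  x <- sin(2 * pi * 6 * t)
  y <- lowpass_zero_lag(x, fs, 6)
  mid <- t > 5 & t < 15
  ratio <- max(abs(y[mid])) / max(abs(x[mid]))
  expect_equal(ratio, 0.5, tolerance = 0.02)
  # zero-lag symmetry: filtering commutes with time reversal
  set.seed(4)
  z <- cumsum(rnorm(600))
  expect_equal(rev(lowpass_zero_lag(rev(z), fs, 6)),
               lowpass_zero_lag(z, fs, 6), tolerance = 1e-6)
  # low frequencies pass nearly unchanged
  xl <- sin(2 * pi * 0.5 * t)
  yl <- lowpass_zero_lag(xl, fs, 6)
  expect_equal(max(abs(yl[mid])), 1, tolerance = 0.01)
  expect_error(lowpass_zero_lag(x, fs, 60), "twice the cutoff")
  expect_error(lowpass_zero_lag(x[1:4], fs, 6), "too short")
})

test_that("step metrics recover generator ground truth exactly", {
  spec <- trial_spec(step_time_l = 16.85, step_time_r = 16.80,
                     step_length_l = 0.539, step_length_r = 0.538,
                     ratio_l = 0.13, ratio_r = 0.15, n_steps = 5)
  trial <- generate_trial(spec)
  rec <- step_metrics(trial)
  left <- rec[rec$side == "left", ]
  right <- rec[rec$side == "right", ]
  expect_equal(mean(left$step_time), 16.85, tolerance = 1e-9)
  expect_equal(mean(right$step_time), 16.80, tolerance = 1e-9)
  expect_equal(mean(left$step_length, na.rm = TRUE), 0.539,
               tolerance = 1e-6)
  expect_equal(mean(right$step_length, na.rm = TRUE), 0.538,
               tolerance = 1e-6)
  expect_equal(mean(left$ratio), 0.13, tolerance = 1e-9)
  expect_equal(mean(right$ratio), 0.15, tolerance = 1e-9)
  # swing/stance arithmetic: swing 2, stance 14 -> ratio 1/7
  expect_equal(unique(round(left$swing_time + left$stance_time, 9)),
               16.85)
  # empty trial yields an empty record set without error
  empty <- trial
  empty$events <- list(left = list(fs = numeric(), to = numeric()),
                       right = list(fs = numeric(), to = numeric()))
  expect_equal(nrow(step_metrics(empty)), 0L)
})

test_that("swing-stance ratio arithmetic is reported as specified", {
  spec <- trial_spec(step_time_l = 16, ratio_l = 2 / 14, n_steps = 3)
  trial <- generate_trial(spec)
  rec <- step_metrics(trial)
  left <- rec[rec$side == "left", ]
  expect_equal(unique(round(left$swing_time, 9)), 2)
  expect_equal(unique(round(left$stance_time, 9)), 14)
  expect_equal(unique(round(left$ratio, 6)), round(0.142857, 6))
})

test_that("IQR outlier rejection removes only fence violations, order-independently", {
  spec <- trial_spec(n_steps = 8)
  trial <- generate_trial(spec)
  rec <- step_metrics(trial)
  mlv <- c(trial$features$ml_vel$left, trial$features$ml_vel$right)
  ttr <- c(trial$features$toe_travel$left, trial$features$toe_travel$right)
  # identical-ish features: nothing removed
  out <- reject_outlier_steps(rec, mlv, ttr)
  expect_equal(nrow(out$rejected), 0L)
  # one ML-velocity sample at Q3 + 3 IQR is removed, with the feature
  # named in the log
  mlv2 <- mlv
  q <- quantile(mlv, c(0.25, 0.75))
  mlv2[4] <- q[2] + 3 * (q[2] - q[1])
  out2 <- reject_outlier_steps(rec, mlv2, ttr)
  expect_equal(nrow(out2$rejected), 1L)
  expect_equal(out2$rejected$reason, "ml_velocity")
  expect_equal(nrow(out2$retained), nrow(rec) - 1L)
  # fences are computed once over the full set: permuting rows rejects
  # the same steps
  o <- sample(nrow(rec))
  out3 <- reject_outlier_steps(rec[o, ], mlv2[o], ttr[o])
  expect_equal(sort(out3$rejected$fs_time), sort(out2$rejected$fs_time))
  # manual exclusions are logged separately
  out4 <- reject_outlier_steps(rec, mlv, ttr, exclusions = 2L)
  expect_equal(out4$rejected$reason, "manual")
})

test_that("stride normalization and ensembles behave like the closed forms", {
  tmpl <- function(s) sin(2 * pi * s) + 0.3 * cos(4 * pi * s)
  # identical steps: SD 0, mean equals the step
  tr1 <- lapply(1:5, function(i) {
    t <- seq(0, 1, length.out = 201)
    list(time = t, value = tmpl(t))
  })
  e1 <- stride_normalize_and_ensemble(tr1)
  expect_equal(max(e1$sd), 0)
  expect_equal(e1$mean, tmpl(e1$percent / 100), tolerance = 1e-3)
  # two steps offset by a constant c: SD = c / sqrt(2)
  tr2 <- list(list(time = seq(0, 1, length.out = 40),
                   value = tmpl(seq(0, 1, length.out = 40))),
              list(time = seq(0, 1, length.out = 40),
                   value = tmpl(seq(0, 1, length.out = 40)) + 0.4))
  e2 <- stride_normalize_and_ensemble(tr2)
  expect_equal(unique(round(e2$sd, 10)), round(0.4 / sqrt(2), 10))
  # steps of different durations but identical percent-cycle shape: SD 0
  tr3 <- lapply(c(0.8, 1.3, 2.4), function(d) {
    t <- seq(0, d, length.out = 61)
    list(time = t, value = tmpl(t / d))
  })
  e3 <- stride_normalize_and_ensemble(tr3)
  expect_lt(max(e3$sd), 1e-10)
  # fewer than two steps: SD undefined with a warning
  expect_warning(e4 <- stride_normalize_and_ensemble(tr1[1]), "SD")
  expect_true(all(is.na(e4$sd)))
})

test_that("gait speed estimate is the ratio of side-averaged means", {
  # agreement at the printed precision (half a unit in the last digit)
  expect_equal(gait_speed_estimate(c(0.539, 0.538), c(16.85, 16.80)),
               0.032, tolerance = 0.016)
  expect_equal(gait_speed_estimate(c(0.556, 0.564), c(18.09, 17.82)),
               0.031, tolerance = 0.016)
  expect_equal(gait_speed_estimate(0, 10), 0)
  expect_error(gait_speed_estimate(0.5, 0), "step time")
})

test_that("upper-extremity effort metrics summarize the resultant force", {
  # constant (0, 100, 0) N on both handles: resultant 200, peak = mean
  spec <- trial_spec(n_steps = 3, uee_baseline = 200, uee_peak = 200.001)
  trial <- generate_trial(spec)
  trial$handle_forces$left[] <- rep(c(0, 100, 0),
                                    each = length(trial$force_time))
  trial$handle_forces$right[] <- rep(c(0, 100, 0),
                                     each = length(trial$force_time))
  u <- uee_metrics(trial)
  expect_equal(unique(u$peak), 200)
  expect_equal(unique(u$mean), 200)
  # zero forces: zero metrics
  trial$handle_forces$left[] <- 0
  trial$handle_forces$right[] <- 0
  u0 <- uee_metrics(trial)
  expect_equal(unique(u0$peak), 0)
  # programmed swing peak is recovered
  spec2 <- trial_spec(n_steps = 4, uee_baseline = 190, uee_peak = 440)
  trial2 <- generate_trial(spec2)
  u2 <- uee_metrics(trial2)
  sw <- u2[u2$window == "swing", ]
  expect_equal(max(sw$peak), 440, tolerance = 1e-6)
  # missing channel is a named error
  trial2$handle_forces$right <- NULL
  expect_error(uee_metrics(trial2), "handle force")
  # sum-of-norms combination is available and never smaller
  trial3 <- generate_trial(spec2)
  u3 <- uee_metrics(trial3, combine = "sum_norms")
  expect_true(all(u3$peak >= u2$peak - 1e-9))
})

test_that("Welch and rank-sum comparisons match hand computations", {
  a <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  b <- c(27.6, 23.1, 27.4, 26.1, 24.5, 22.9, 24.8, 29.0)
  # hand-computed Welch statistic and Satterthwaite df
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tstat), df)
  w <- compare_conditions(a, b, "welch_t")
  expect_equal(w$statistic, tstat, tolerance = 1e-6)
  expect_equal(w$df, df, tolerance = 1e-6)
  expect_equal(w$p_value, p, tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  w0 <- compare_conditions(a, a, "welch_t")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # degenerate equal-constant groups reported as undefined, not an error
  wd <- compare_conditions(c(1, 1, 1), c(1, 1, 1), "welch_t")
  expect_true(is.na(wd$statistic))
  # rank-sum statistic is invariant under strictly monotone transforms
  r1 <- compare_conditions(a, b, "wilcoxon_rank_sum")
  r2 <- compare_conditions(exp(a / 10), exp(b / 10),
                           "wilcoxon_rank_sum")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Likert summaries report medians, IQRs and rank-sum tests", {
  set.seed(2)
  resp <- data.frame(
    question = rep(1:2, each = 10),
    score = c(sample(0:3, 10, TRUE), sample(-2:1, 10, TRUE)),
    condition = rep(rep(c("optimized", "manual"), each = 5), 2))
  s <- likert_summary(resp)
  expect_equal(nrow(s$summary), 4L)
  q1o <- resp$score[resp$question == 1 & resp$condition == "optimized"]
  expect_equal(s$summary$median[1], median(q1o))
  expect_equal(length(s$tests), 2L)
  expect_error(likert_summary(data.frame(question = 1, score = 5,
                                         condition = "a")),
               "-3..3")
})

test_that("normality report measures ECDF distance from a fitted normal", {
  set.seed(10)
  x <- rnorm(400)
  r <- normality_report(x)
  expect_lt(r$distance, 0.08)
  y <- rexp(400)
  expect_gt(normality_report(y)$distance, r$distance)
})
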