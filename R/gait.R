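# Gait-trial analysis pipeline: zero-lag filtering, step metrics,
# interquartile-range outlier rejection, stride normalization and
# ensemble averaging, upper-extremity effort metrics, and statistics.

#' Zero-lag lowpass Butterworth filter
#'
#' Forward-backward (two-pass) second-order Butterworth lowpass: zero
#' phase shift, unit DC gain, squared magnitude response (amplitude ratio
#' 1/2 at the cutoff).
#'
#' @param x signal vector (or matrix filtered by column)
#' @param fs sampling rate, Hz
#' @param cutoff cutoff frequency, Hz (must satisfy fs > 2 * cutoff)
#' @param order filter order per pass (default 2)
#' @return filtered signal
#' @export
lowpass_zero_lag <- function(x, fs, cutoff = 6, order = 2) {
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass_zero_lag, fs = fs, cutoff = cutoff,
                 order = order))
  }
  if (length(x) < 3 * (order + 1)) {
    stop("signal too short for the filter warm-up")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  np <- min(length(x) - 1L, as.integer(round(3 * fs / cutoff)))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(np + 1):(np + length(x))])
}

#' Step metrics from a gait trial
#'
#' Step time is footstrike-to-footstrike per side; swing is toe-off to
#' the next footstrike and stance footstrike to toe-off; step length is
#' the anterior distance between the landing heel at footstrike and the
#' contralateral heel at its most recent footstrike.
#'
#' @param trial a `gait_trial` (markers + events; see [generate_trial()])
#' @return data.frame of class `step_records`: `side`, `step`, `fs_time`,
#'   `step_time`, `step_length`, `swing_time`, `stance_time`, `ratio`
#' @export
step_metrics <- function(trial) {
  ev <- trial$events
  if (is.null(ev)) stop("trial has no step events")
  out <- NULL
  heel <- list(left = trial$markers$HEEL_l, right = trial$markers$HEEL_r)
  heel_at <- function(side, t) {
    approx(trial$marker_time, heel[[side]][, 1], xout = t, rule = 2)$y
  }
  for (side in c("left", "right")) {
    other <- if (side == "left") "right" else "left"
    fs <- ev[[side]]$fs
    to <- ev[[side]]$to
    fso <- ev[[other]]$fs
    if (length(fs) < 2L) next
    for (k in seq_len(length(fs) - 1L)) {
      t0 <- fs[k]
      t1 <- fs[k + 1]
      tk <- to[to > t0 & to < t1]
      if (length(tk) != 1L) {
        message("step skipped (missing toe-off): ", side, " #", k)
        next
      }
      prev_o <- fso[fso < t1]
      slen <- if (length(prev_o)) {
        heel_at(side, t1) - heel_at(other, max(prev_o))
      } else NA_real_
      out <- rbind(out, data.frame(
        side = side, step = k, fs_time = t0,
        step_time = t1 - t0,
        step_length = slen,
        swing_time = t1 - tk,
        stance_time = tk - t0,
        ratio = (t1 - tk) / (tk - t0),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(side = character(), step = integer(),
                      fs_time = numeric(), step_time = numeric(),
                      step_length = numeric(), swing_time = numeric(),
                      stance_time = numeric(), ratio = numeric())
  }
  class(out) <- c("step_records", class(out))
  out
}

#' Interquartile-range outlier rejection of steps
#'
#' A step is removed when its medial-lateral walker velocity or its toe
#' anterior-posterior travel lies outside the Tukey fences
#' \[Q1 - k IQR, Q3 + k IQR\] computed once over all supplied steps (so
#' removal is order-independent). Every removal is logged with the
#' violated feature.
#'
#' @param steps a `step_records` data.frame
#' @param ml_velocity per-step medial-lateral walker velocity (m/s),
#'   aligned with `steps` rows
#' @param toe_travel per-step toe anterior travel (m), aligned with
#'   `steps` rows
#' @param k fence multiplier (default 1.5)
#' @param exclusions optional integer rows to drop for documented manual
#'   reasons (spasm interference etc.); logged as `manual`
#' @return list with `retained` (data.frame), `rejected` (data.frame with
#'   `reason`), `fences`
#' @export
reject_outlier_steps <- function(steps, ml_velocity, toe_travel,
                                 k = 1.5, exclusions = integer()) {
  stopifnot(length(ml_velocity) == nrow(steps),
            length(toe_travel) == nrow(steps))
  fence <- function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    c(q[1] - k * iqr, q[2] + k * iqr)
  }
  fml <- fence(ml_velocity)
  ftt <- fence(toe_travel)
  reasons <- rep(NA_character_, nrow(steps))
  bad_ml <- ml_velocity < fml[1] | ml_velocity > fml[2]
  bad_tt <- toe_travel < ftt[1] | toe_travel > ftt[2]
  reasons[bad_tt] <- "toe_travel"
  reasons[bad_ml] <- ifelse(bad_tt[bad_ml], "ml_velocity+toe_travel",
                            "ml_velocity")
  reasons[exclusions] <- "manual"
  drop <- !is.na(reasons)
  rejected <- steps[drop, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[drop]
  list(retained = steps[!drop, , drop = FALSE],
       rejected = rejected,
       fences = list(ml_velocity = fml, toe_travel = ftt))
}

#' Stride normalization and ensemble averaging
#'
#' Each step's trace (footstrike to footstrike) is resampled by linear
#' interpolation onto a fixed percent-gait-cycle grid; the pointwise mean
#' and sample standard deviation across steps are returned.
#'
#' @param traces list of per-step data.frames/lists with `time` and
#'   `value`
#' @param n_points grid resolution (default 101, i.e. 0-100%)
#' @return list with `percent`, `mean`, `sd`, `n`; `sd` is `NA` (with a
#'   warning) when fewer than two steps are supplied
#' @export
stride_normalize_and_ensemble <- function(traces, n_points = 101L) {
  if (length(traces) == 0L) stop("no steps supplied")
  pct <- seq(0, 100, length.out = n_points)
  M <- vapply(traces, function(tr) {
    s <- (tr$time - tr$time[1]) /
      (tr$time[length(tr$time)] - tr$time[1]) * 100
    approx(s, tr$value, xout = pct)$y
  }, numeric(n_points))
  n <- length(traces)
  if (n < 2L) {
    warning("fewer than two steps: ensemble SD undefined")
    return(list(percent = pct, mean = as.numeric(M), sd = rep(NA_real_,
                                                              n_points),
                n = n))
  }
  list(percent = pct, mean = rowMeans(M), sd = apply(M, 1, sd), n = n)
}

#' Gait speed estimate from mean step length and time
#'
#' For approximately symmetric stepping, gait speed is estimated as the
#' side-averaged mean step length divided by the side-averaged mean step
#' time.
#'
#' @param step_length mean step length per side (vector averaged), m
#' @param step_time mean step time per side (vector averaged), s
#' @return speed, m/s
#' @export
gait_speed_estimate <- function(step_length, step_time) {
  Tm <- mean(step_time)
  if (Tm <= 0) stop("step time must be > 0")
  mean(step_length) / Tm
}

#' Upper-extremity effort metrics
#'
#' The resultant force is the Euclidean norm of the summed left and right
#' handle force vectors (configurable to the sum of per-handle norms).
#' Peak and time-averaged resultants are reported per gait cycle and per
#' swing phase, per side.
#'
#' @param trial a `gait_trial` with `handle_forces` and `events`
#' @param combine `"sum_vectors"` (default) or `"sum_norms"`
#' @return data.frame with `side`, `step`, `window` (`cycle`/`swing`),
#'   `peak`, `mean` (N)
#' @export
uee_metrics <- function(trial, combine = c("sum_vectors", "sum_norms")) {
  combine <- match.arg(combine)
  hf <- trial$handle_forces
  if (is.null(hf$left) || is.null(hf$right)) {
    stop("missing handle force channel (need left and right)")
  }
  res <- if (combine == "sum_vectors") {
    s <- hf$left + hf$right
    sqrt(rowSums(s^2))
  } else {
    sqrt(rowSums(hf$left^2)) + sqrt(rowSums(hf$right^2))
  }
  tt <- trial$force_time
  out <- NULL
  for (side in c("left", "right")) {
    fs <- trial$events[[side]]$fs
    to <- trial$events[[side]]$to
    for (k in seq_len(length(fs) - 1L)) {
      cyc <- tt >= fs[k] & tt <= fs[k + 1]
      tk <- to[to > fs[k] & to < fs[k + 1]]
      wins <- list(cycle = cyc)
      if (length(tk) == 1L) {
        wins$swing <- tt >= tk & tt <= fs[k + 1]
      }
      for (w in names(wins)) {
        v <- res[wins[[w]]]
        out <- rbind(out, data.frame(
          side = side, step = k, window = w,
          peak = max(v), mean = mean(v), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Two-group comparison statistics
#'
#' Welch's unequal-variance t-test (Satterthwaite degrees of freedom) or
#' the Wilcoxon rank-sum test, two-sided.
#'
#' @param a,b numeric samples
#' @param kind `"welch_t"` or `"wilcoxon_rank_sum"`
#' @return list with `statistic`, `p_value`, `df` (Welch) and the
#'   underlying `htest`
#' @export
compare_conditions <- function(a, b,
                               kind = c("welch_t",
                                        "wilcoxon_rank_sum")) {
  kind <- match.arg(kind)
  if (kind == "welch_t") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("Welch test needs at least two samples per group")
    }
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(list(statistic = NA_real_, p_value = NA_real_,
                    df = NA_real_, note = "zero variance, equal means"))
      }
    }
    ht <- t.test(a, b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), htest = ht)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         htest = ht)
  }
}

#' Likert response summaries
#'
#' Median and interquartile range per question and condition, with
#' Wilcoxon rank-sum comparisons between conditions.
#'
#' @param responses data.frame with `question`, `score` (integers in
#'   -3..3), `condition`
#' @return list with `summary` (data.frame) and `tests` (per question)
#' @export
likert_summary <- function(responses) {
  if (!all(responses$score %in% -3:3)) {
    stop("scores must be integers in -3..3")
  }
  agg <- NULL
  tests <- list()
  for (q in unique(responses$question)) {
    rq <- responses[responses$question == q, ]
    for (cond in unique(rq$condition)) {
      s <- rq$score[rq$condition == cond]
      agg <- rbind(agg, data.frame(
        question = q, condition = cond, median = median(s),
        iqr = stats::IQR(s), n = length(s), stringsAsFactors = FALSE))
    }
    conds <- unique(rq$condition)
    if (length(conds) == 2L) {
      tests[[as.character(q)]] <- compare_conditions(
        rq$score[rq$condition == conds[1]],
        rq$score[rq$condition == conds[2]], "wilcoxon_rank_sum")
    }
  }
  list(summary = agg, tests = tests)
}

#' Normality check report
#'
#' Supremum distance between the sample's empirical CDF and the normal
#' CDF with matched mean and SD (a report to inspect, not a gate).
#'
#' @param x numeric sample
#' @return list with `distance`, `mean`, `sd`, `n`
#' @export
normality_report <- function(x) {
  m <- mean(x)
  s <- sd(x)
  e <- ecdf(x)
  grid <- sort(unique(x))
  dplus <- max(abs(e(grid) - pnorm(grid, m, s)))
  dminus <- max(abs(e(grid) - 1 / length(x) - pnorm(grid, m, s)))
  list(distance = max(dplus, dminus), mean = m, sd = s, n = length(x))
}
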