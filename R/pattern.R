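# Compilation of optimized muscle excitations into device-ready
# stimulation pulse-width schedules, and charge-delivery accounting.

#' Stimulation channel calibration
#'
#' Pulse-width mapping Stim = Excitation * Sat + Thresh (microseconds),
#' with device limits: pulse widths clamp to [0, 255] microseconds and
#' amplitudes are bounded by the stimulation method (implanted 0-20 mA,
#' surface 0-100 mA).
#'
#' @param channel channel id
#' @param muscle_group muscle group driven by the channel
#' @param side `"left"` or `"right"`
#' @param method `"implanted"` or `"surface"`
#' @param sat saturation pulse width scale, microseconds (> 0)
#' @param thresh threshold pulse width, microseconds (>= 0)
#' @param amplitude pulse amplitude, mA
#' @return one-row data.frame of class `channel_calibration`
#' @export
channel_calibration <- function(channel, muscle_group, side,
                                method = c("implanted", "surface"),
                                sat, thresh, amplitude) {
  method <- match.arg(method)
  if (sat <= 0) stop("Sat must be > 0")
  if (thresh < 0) stop("Thresh must be >= 0")
  amp_max <- if (method == "implanted") 20 else 100
  if (amplitude < 0 || amplitude > amp_max) {
    stop(method, " channel amplitude must lie in [0, ", amp_max, "] mA")
  }
  out <- data.frame(channel = channel, muscle_group = muscle_group,
                    side = side, method = method, sat = sat,
                    thresh = thresh, amplitude = amplitude,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_calibration", class(out))
  out
}

pw_limit <- 255

#' Extract per-side swing-phase excitations from a two-step solution
#'
#' Left-side muscle excitations come from the first half of the
#' optimization period and right-side excitations from the second half;
#' the stance-phase portion of the solution is discarded, keeping only
#' the swing window of each side (detected from that side's foot contact
#' force falling below a threshold, or supplied explicitly). Muscle-group
#' elements are averaged into a single channel trace.
#'
#' @param solution an `fns_ocs` (or an `fns_trajectory`)
#' @param swing_windows optional list with `left` and `right` c(t0, t1)
#'   windows, s; detected from contact forces when `NULL`
#' @param threshold_frac swing detection threshold as a fraction of body
#'   weight
#' @return list of class `swing_excitations`: per side, a list with
#'   `time` (s, re-zeroed to swing onset) and `excitations` (matrix, one
#'   column per muscle group)
#' @export
extract_swing_excitations <- function(solution, swing_windows = NULL,
                                      threshold_frac = 0.05) {
  traj <- if (inherits(solution, "fns_ocs")) solution$trajectory else
    solution
  model <- traj$model
  if (n_muscle(model) == 0L) stop("solution has no muscle channels")
  tmid <- (traj$time[1] + traj$time[length(traj$time)]) / 2
  if (is.null(swing_windows)) {
    Fm <- foot_contact_forces(model, traj_Q(traj), traj_U(traj))
    thr <- threshold_frac * model$total_mass * model$gravity
    swing_windows <- list()
    for (side in c("left", "right")) {
      fy <- Fm[paste0(side, "_fy"), ]
      half <- if (side == "left") {
        traj$time <= tmid
      } else traj$time >= tmid
      off <- which(half & fy < thr)
      if (length(off) == 0L) {
        stop("no swing phase found for ", side,
             " side (foot never unloads)")
      }
      swing_windows[[side]] <- range(traj$time[off])
    }
  }
  out <- list()
  for (side in c("left", "right")) {
    win <- swing_windows[[side]]
    if (is.null(win)) stop("missing swing window for side ", side)
    keep <- traj$time >= win[1] & traj$time <= win[2]
    if (sum(keep) < 2L) stop("swing window too short for ", side)
    mus <- model$muscles[model$muscles$side == side, , drop = FALSE]
    E <- traj$controls[keep, paste0("exc_", mus$name), drop = FALSE]
    groups <- unique(mus$group)
    G <- vapply(groups, function(g) {
      rowMeans(E[, paste0("exc_", mus$name[mus$group == g]),
                 drop = FALSE])
    }, numeric(sum(keep)))
    colnames(G) <- groups
    out[[side]] <- list(time = traj$time[keep] - win[1],
                        excitations = G,
                        duration = diff(range(traj$time[keep])))
  }
  class(out) <- "swing_excitations"
  out
}

resample_linear <- function(time, values, n = 22L) {
  tt <- seq(time[1], time[length(time)], length.out = n)
  approx(time, values, xout = tt)$y
}

#' Compile excitations into a stimulation pattern
#'
#' Each channel trace is resampled to 22 points by linear interpolation,
#' mapped to pulse widths by Stim = Excitation * Sat + Thresh, and
#' clamped to the 0-255 microsecond device range. Empirical strength
#' scalings are then applied: left-side pulse widths are multiplied by
#' `left_pw_gain` (re-clamped), and right-side sample times are stretched
#' by `right_time_gain`.
#'
#' @param excitations a `swing_excitations` object (or a compatible list)
#' @param calib data.frame of [channel_calibration()] rows covering every
#'   muscle group/side present
#' @param left_pw_gain pulse-width gain applied to left channels
#'   (default 1.2)
#' @param right_time_gain time-scale factor for the right side (default
#'   1.5)
#' @return list of class `stim_pattern`: per side, `sample_times` (s),
#'   `pw` (22 x channels matrix, microseconds), `amplitude` (per
#'   channel), `frequency` (per-channel schedule), `swing_duration`
#' @export
compile_pattern <- function(excitations, calib, left_pw_gain = 1.2,
                            right_time_gain = 1.5) {
  out <- list()
  for (side in c("left", "right")) {
    ex <- excitations[[side]]
    if (is.null(ex)) next
    grps <- colnames(ex$excitations)
    dur <- ex$duration %||% max(ex$time)
    if (side == "right") dur <- dur * right_time_gain
    tt <- seq(0, dur, length.out = 22L)
    pw <- matrix(NA_real_, 22L, length(grps))
    amp <- numeric(length(grps))
    freq <- list()
    for (j in seq_along(grps)) {
      cl <- calib[calib$muscle_group == grps[j] & calib$side == side, ,
                  drop = FALSE]
      if (nrow(cl) == 0L) {
        stop("no calibration for channel ", grps[j], " (", side, ")")
      }
      e <- resample_linear(ex$time, ex$excitations[, j])
      if (any(e < -1e-9 | e > 1 + 1e-9)) {
        stop("excitation outside [0, 1] for channel ", grps[j])
      }
      p <- pmin(pmax(e * cl$sat + cl$thresh, 0), pw_limit)
      if (side == "left") p <- pmin(p * left_pw_gain, pw_limit)
      pw[, j] <- p
      amp[j] <- cl$amplitude
      freq[[grps[j]]] <- build_frequency_schedule(side, grps[j], dur)
    }
    colnames(pw) <- grps
    out[[side]] <- list(sample_times = tt, pw = pw,
                        amplitude = setNames(amp, grps),
                        frequency = freq, swing_duration = dur)
  }
  class(out) <- "stim_pattern"
  out
}

#' Per-channel stimulation frequency schedule
#'
#' Frequency starts at 16 Hz and doubles to 32 Hz after 0.15 s for all
#' muscles except the vasti (which stay at 16 Hz throughout). On the
#' right side the frequency returns to 16 Hz for the final 30% of the
#' pattern; on the left the higher frequency is held to the end.
#'
#' @param side `"left"` or `"right"`
#' @param channel muscle-group id (vasti detected by name)
#' @param swing_duration pattern duration, s
#' @param tail_frac right-side low-frequency tail fraction (default 0.3)
#' @return data.frame with `t0`, `t1`, `hz` rows (piecewise constant)
#' @export
build_frequency_schedule <- function(side, channel, swing_duration,
                                     tail_frac = 0.3) {
  if (swing_duration <= 0) stop("swing_duration must be > 0")
  vasti <- grepl("vasti", channel, ignore.case = TRUE)
  if (vasti) {
    return(data.frame(t0 = 0, t1 = swing_duration, hz = 16))
  }
  if (swing_duration <= 0.15) {
    warning("swing shorter than the 0.15 s low-frequency lead-in; ",
            "single-segment schedule")
    return(data.frame(t0 = 0, t1 = swing_duration, hz = 16))
  }
  if (side == "left") {
    data.frame(t0 = c(0, 0.15), t1 = c(0.15, swing_duration),
               hz = c(16, 32))
  } else {
    ttail <- (1 - tail_frac) * swing_duration
    if (ttail <= 0.15) {
      data.frame(t0 = c(0, 0.15), t1 = c(0.15, swing_duration),
                 hz = c(16, 16))
    } else {
      data.frame(t0 = c(0, 0.15, ttail),
                 t1 = c(0.15, ttail, swing_duration),
                 hz = c(16, 32, 16))
    }
  }
}

schedule_freq_at <- function(schedule, t) {
  hz <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(schedule))) {
    sel <- t >= schedule$t0[i] & (t < schedule$t1[i] |
                                    (i == nrow(schedule) &
                                       t <= schedule$t1[i]))
    hz[sel] <- schedule$hz[i]
  }
  hz
}

#' Charge delivered per swing phase for one channel
#'
#' Pulses are placed sequentially from t = 0 at the instantaneous
#' frequency of the channel's schedule; each pulse delivers amplitude
#' times the pulse width linearly interpolated between the 22 pattern
#' samples. A partial trailing inter-pulse interval delivers no pulse.
#' Charge is amplitude (mA) x pulse width (us) = nanocoulombs; reported
#' in microcoulombs.
#'
#' @param pattern a `stim_pattern`
#' @param side `"left"` or `"right"`
#' @param channel muscle-group id
#' @return charge in microcoulombs
#' @export
charge_per_swing <- function(pattern, side, channel) {
  p <- pattern[[side]]
  if (is.null(p)) stop("pattern has no ", side, " side")
  j <- match(channel, colnames(p$pw))
  if (is.na(j)) stop("unknown channel ", channel)
  sched <- p$frequency[[channel]]
  dur <- p$swing_duration
  t <- 0
  charge <- 0
  while (t < dur - 1e-12) {
    pwt <- approx(p$sample_times, p$pw[, j], xout = t)$y
    charge <- charge + p$amplitude[[channel]] * pwt  # mA * us = nC
    hz <- schedule_freq_at(sched, t)
    t <- t + 1 / hz
  }
  charge / 1000  # nC -> uC
}

#' Charge table for all channels of a pattern
#' @param pattern a `stim_pattern`
#' @return data.frame with `side`, `channel`, `charge_uC`
#' @export
pattern_charges <- function(pattern) {
  out <- NULL
  for (side in c("left", "right")) {
    p <- pattern[[side]]
    if (is.null(p)) next
    for (ch in colnames(p$pw)) {
      out <- rbind(out, data.frame(
        side = side, channel = ch,
        charge_uC = charge_per_swing(pattern, side, ch),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Compare charge delivery between two patterns
#'
#' Percent reduction is 100 (1 - optimized/reference) per muscle;
#' increases are reported with negative reduction (and a positive
#' `percent_increase`). The summary mean covers only muscles showing a
#' reduction, with the min/max reduction endpoints.
#'
#' @param optimized,reference named numeric vectors of per-muscle charge
#'   (microcoulombs) with identical names, or data.frames as returned by
#'   [pattern_charges()] (matched on side:channel)
#' @return list of class `charge_report` with `table` (per-muscle) and
#'   `summary`
#' @export
compare_patterns <- function(optimized, reference) {
  tovec <- function(x) {
    if (is.data.frame(x)) {
      setNames(x$charge_uC, paste(x$side, x$channel, sep = ":"))
    } else x
  }
  a <- tovec(optimized)
  b <- tovec(reference)
  if (!setequal(names(a), names(b))) {
    stop("patterns must cover the same muscle keys")
  }
  b <- b[names(a)]
  if (any(b == 0)) {
    stop("undefined percent change: zero reference charge for ",
         paste(names(b)[b == 0], collapse = ", "))
  }
  pct_red <- 100 * (1 - a / b)
  tab <- data.frame(muscle = names(a), optimized = unname(a),
                    reference = unname(b),
                    percent_reduction = unname(pct_red),
                    stringsAsFactors = FALSE)
  red <- pct_red[pct_red > 0]
  summary <- list(
    mean_reduction = if (length(red)) mean(red) else NA_real_,
    min_reduction = if (length(red)) min(red) else NA_real_,
    max_reduction = if (length(red)) max(red) else NA_real_,
    n_reduced = length(red),
    increases = -pct_red[pct_red < 0]
  )
  structure(list(table = tab, summary = summary),
            class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("mean reduction %.1f%% (range %.1f-%.1f%%, n=%d)\n",
              x$summary$mean_reduction, x$summary$min_reduction,
              x$summary$max_reduction, x$summary$n_reduced))
  if (length(x$summary$increases)) {
    cat("increases:", paste(sprintf("%s +%.1f%%",
                                    names(x$summary$increases),
                                    x$summary$increases),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# pattern export / import (CSV + JSON sidecar)
# ---------------------------------------------------------------------------

#' Write or read a stimulation pattern
#'
#' The pattern is stored as a CSV of samples (`side`, `channel`,
#' `sample_index`, `time_s`, `pw_us`) plus a JSON sidecar carrying the
#' amplitudes, frequency schedules and swing durations. The round trip is
#' bit-stable (full double precision is written).
#'
#' @param pattern a `stim_pattern`
#' @param path base path; `<path>.csv` and `<path>.json` are written
#' @export
write_pattern <- function(pattern, path) {
  rows <- NULL
  meta <- list()
  for (side in c("left", "right")) {
    p <- pattern[[side]]
    if (is.null(p)) next
    for (ch in colnames(p$pw)) {
      rows <- rbind(rows, data.frame(
        side = side, channel = ch, sample_index = seq_len(nrow(p$pw)),
        time_s = sprintf("%.17g", p$sample_times),
        pw_us = sprintf("%.17g", p$pw[, ch]),
        stringsAsFactors = FALSE))
    }
    meta[[side]] <- list(
      amplitude = as.list(p$amplitude),
      swing_duration = p$swing_duration,
      frequency = lapply(p$frequency, function(s) {
        list(t0 = s$t0, t1 = s$t1, hz = s$hz)
      })
    )
  }
  utils::write.table(rows, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  rows <- utils::read.table(paste0(path, ".csv"), sep = ",",
                            header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  out <- list()
  for (side in unique(rows$side)) {
    rs <- rows[rows$side == side, ]
    chans <- unique(rs$channel)
    n <- max(rs$sample_index)
    pw <- matrix(NA_real_, n, length(chans),
                 dimnames = list(NULL, chans))
    for (ch in chans) {
      sel <- rs[rs$channel == ch, ]
      pw[sel$sample_index, ch] <- as.numeric(sel$pw_us)
    }
    tt <- as.numeric(rs$time_s[rs$channel == chans[1]])
    m <- meta[[side]]
    freq <- lapply(m$frequency, function(s) {
      data.frame(t0 = unlist(s$t0), t1 = unlist(s$t1),
                 hz = unlist(s$hz))
    })
    out[[side]] <- list(
      sample_times = tt, pw = pw,
      amplitude = unlist(m$amplitude),
      frequency = freq,
      swing_duration = m$swing_duration)
  }
  class(out) <- "stim_pattern"
  out
}

#' Manually tuned pattern import
#'
#' Manually tuned patterns are specified directly as pulse-width
#' sequences (no saturation/threshold mapping); this reads the same CSV +
#' JSON layout as [write_pattern()].
#' @inheritParams read_pattern
#' @export
read_manual_pattern <- function(path) read_pattern(path)
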