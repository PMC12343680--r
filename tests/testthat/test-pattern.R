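# Stimulation pattern compilation and charge accounting.

default_calib <- function() {
  rbind(
    channel_calibration("ch1", "iliopsoas_l", "left", "implanted",
                        sat = 200, thresh = 50, amplitude = 20),
    channel_calibration("ch2", "vasti_l", "left", "implanted",
                        sat = 150, thresh = 40, amplitude = 18),
    channel_calibration("ch3", "ta_l", "left", "implanted",
                        sat = 180, thresh = 30, amplitude = 20),
    channel_calibration("ch4", "tfl_l", "left", "implanted",
                        sat = 160, thresh = 20, amplitude = 16),
    channel_calibration("ch5", "iliopsoas_r", "right", "surface",
                        sat = 220, thresh = 35, amplitude = 60),
    channel_calibration("ch6", "vasti_r", "right", "implanted",
                        sat = 150, thresh = 40, amplitude = 18),
    channel_calibration("ch7", "ta_r", "right", "implanted",
                        sat = 180, thresh = 30, amplitude = 20),
    channel_calibration("ch8", "sart_r", "right", "surface",
                        sat = 240, thresh = 45, amplitude = 70),
    channel_calibration("ch9", "bfsh_r", "right", "surface",
                        sat = 200, thresh = 40, amplitude = 65)
  )
}

simple_excitations <- function(shape_l = NULL, shape_r = NULL,
                               duration = 1) {
  t <- seq(0, duration, length.out = 41)
  val <- function(shape) {
    if (is.null(shape)) 0.5 + 0.4 * sin(pi * t / duration) else
      shape(t)
  }
  out <- list(
    left = list(time = t,
                excitations = cbind(iliopsoas_l = val(shape_l),
                                    vasti_l = val(shape_l),
                                    ta_l = val(shape_l),
                                    tfl_l = val(shape_l)),
                duration = duration),
    right = list(time = t,
                 excitations = cbind(iliopsoas_r = val(shape_r),
                                     vasti_r = val(shape_r),
                                     ta_r = val(shape_r),
                                     sart_r = val(shape_r),
                                     bfsh_r = val(shape_r)),
                 duration = duration))
  class(out) <- "swing_excitations"
  out
}

test_that("channel calibration enforces device limits", {
  expect_error(channel_calibration("c", "g", "left", "implanted",
                                   sat = 0, thresh = 10, amplitude = 10),
               "Sat")
  expect_error(channel_calibration("c", "g", "left", "implanted",
                                   sat = 100, thresh = -1,
                                   amplitude = 10), "Thresh")
  expect_error(channel_calibration("c", "g", "left", "implanted",
                                   sat = 100, thresh = 10,
                                   amplitude = 50), "20")
  expect_silent(channel_calibration("c", "g", "left", "surface",
                                    sat = 100, thresh = 10,
                                    amplitude = 50))
})

test_that("pulse-width mapping applies saturation, threshold and clamping", {
  calib <- default_calib()
  ex <- simple_excitations(shape_l = function(t) rep(1, length(t)))
  p <- compile_pattern(ex, calib, left_pw_gain = 1)
  # e = 1, Sat = 200, Thresh = 50 -> 250 us
  expect_equal(unname(p$left$pw[, "iliopsoas_l"]), rep(250, 22))
  # clamped at the 255 us device limit
  calib2 <- calib
  calib2$sat[calib2$muscle_group == "iliopsoas_l"] <- 250
  p2 <- compile_pattern(ex, calib2, left_pw_gain = 1)
  expect_equal(unname(p2$left$pw[, "iliopsoas_l"]), rep(255, 22))
  # left pulse-width gain is applied post-mapping and re-clamped
  p3 <- compile_pattern(ex, calib, left_pw_gain = 1.2)
  expect_equal(unname(p3$left$pw[, "ta_l"]),
               rep(min(1.2 * (180 + 30), 255), 22))
  # constant excitation of any length gives 22 identical samples
  exc <- simple_excitations(shape_l = function(t) rep(0.5, length(t)))
  p4 <- compile_pattern(exc, calib)
  expect_equal(nrow(p4$left$pw), 22L)
  expect_equal(unname(p4$left$pw[, "vasti_l"]),
               rep(min(1.2 * (0.5 * 150 + 40), 255), 22))
  # right-side time scale is stretched by 50%
  expect_equal(p4$right$swing_duration, 1.5)
  expect_equal(max(p4$right$sample_times), 1.5)
  # missing calibration is a named error
  expect_error(compile_pattern(ex, calib[-4, ]), "tfl_l")
})

test_that("resampling to 22 points preserves endpoints and affine traces", {
  t <- seq(0, 0.8, length.out = 37)
  v <- 0.2 + 0.6 * t / 0.8
  r <- fnstep:::resample_linear(t, v, 22L)
  expect_equal(r[1], v[1])
  expect_equal(r[22], v[37])
  tt <- seq(0, 0.8, length.out = 22)
  expect_equal(r, 0.2 + 0.6 * tt / 0.8, tolerance = 1e-12)
})

test_that("frequency schedules follow the side and muscle rules", {
  # left non-vasti: 16 Hz for 0.15 s then 32 Hz to the end
  s <- build_frequency_schedule("left", "ta_l", 1.0)
  expect_equal(s$hz, c(16, 32))
  expect_equal(s$t1[1], 0.15)
  expect_equal(s$t1[2], 1.0)
  # vasti: constant 16 Hz on either side
  for (side in c("left", "right")) {
    sv <- build_frequency_schedule(side, "vasti_l", 1.0)
    expect_equal(sv$hz, 16)
  }
  # right non-vasti: 16 Hz resumes for the final 30%
  sr <- build_frequency_schedule("right", "ta_r", 1.0)
  expect_equal(sr$hz, c(16, 32, 16))
  expect_equal(sr$t0[3], 0.7)
  # short swings degrade to a single segment with a warning
  expect_warning(s1 <- build_frequency_schedule("left", "ta_l", 0.1),
                 "lead-in")
  expect_equal(nrow(s1), 1L)
})

# pulse-by-pulse enumeration oracle, independent of charge_per_swing
charge_oracle <- function(times, pw, amp, sched, dur) {
  q <- 0
  t <- 0
  while (t < dur - 1e-12) {
    q <- q + amp * approx(times, pw, xout = t)$y
    hz <- sched$hz[max(which(sched$t0 <= t + 1e-12))]
    t <- t + 1 / hz
  }
  q / 1000
}

test_that("charge per swing matches arithmetic and the enumeration oracle", {
  calib <- default_calib()
  # constant 100 us at 20 mA, 16 Hz, 1 s: 16 pulses x 2 uC = 32 uC
  p <- list(left = list(
    sample_times = seq(0, 1, length.out = 22),
    pw = matrix(100, 22, 1, dimnames = list(NULL, "vasti_l")),
    amplitude = c(vasti_l = 20),
    frequency = list(vasti_l = data.frame(t0 = 0, t1 = 1, hz = 16)),
    swing_duration = 1))
  class(p) <- "stim_pattern"
  expect_equal(charge_per_swing(p, "left", "vasti_l"), 32)
  # zero pulse width delivers zero charge
  p$left$pw[] <- 0
  expect_equal(charge_per_swing(p, "left", "vasti_l"), 0)
  # random patterns with frequency-doubling schedules match the oracle
  set.seed(21)
  for (i in 1:12) {
    dur <- runif(1, 0.4, 1.6)
    ex <- simple_excitations(
      shape_l = function(t) pmin(pmax(splinefun(
        seq(0, max(t), length.out = 4), runif(4))(t), 0), 1),
      shape_r = function(t) pmin(pmax(splinefun(
        seq(0, max(t), length.out = 5), runif(5))(t), 0), 1),
      duration = dur)
    pat <- compile_pattern(ex, calib)
    for (side in c("left", "right")) {
      for (ch in colnames(pat[[side]]$pw)) {
        expect_equal(
          charge_per_swing(pat, side, ch),
          charge_oracle(pat[[side]]$sample_times, pat[[side]]$pw[, ch],
                        pat[[side]]$amplitude[[ch]],
                        pat[[side]]$frequency[[ch]],
                        pat[[side]]$swing_duration),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("raising any excitation sample never decreases channel charge", {
  calib <- default_calib()
  set.seed(31)
  ex <- simple_excitations(duration = 0.9)
  pat <- compile_pattern(ex, calib)
  q0 <- charge_per_swing(pat, "right", "ta_r")
  for (k in c(1, 10, 20, 41)) {
    ex2 <- ex
    ex2$right$excitations[k, "ta_r"] <-
      min(1, ex2$right$excitations[k, "ta_r"] + 0.2)
    q1 <- charge_per_swing(compile_pattern(ex2, calib), "right", "ta_r")
    expect_gte(q1, q0 - 1e-12)
  }
})

test_that("swing excitations come from the correct half and are averaged", {
  m <- planar_biped("model_p")
  # synthetic two-step solution: airborne feet during the middle of each
  # half, grounded otherwise
  n <- 81
  t <- seq(0, 2.2, length.out = n)
  q0 <- standing_pose(m)
  q0["pelvis_ty"] <- q0["pelvis_ty"] - 0.012
  cn <- coord_names(m)
  S <- matrix(rep(c(q0, numeric(10), rep(0.01, 15)), each = n), n, 35)
  colnames(S) <- c(paste0("q_", cn), paste0("u_", cn),
                   paste0("act_", m$muscles$name))
  # left swing in the first half, right swing in the second
  lift_l <- 0.5 * sin(pi * pmin(pmax((t - 0.3) / 0.5, 0), 1))^2
  lift_r <- 0.5 * sin(pi * pmin(pmax((t - 1.4) / 0.5, 0), 1))^2
  S[, "q_thigh_l_q"] <- lift_l
  S[, "q_thigh_r_q"] <- lift_r
  Ctl <- matrix(0.01, n, 25,
                dimnames = list(NULL, c(paste0("exc_", m$muscles$name),
                                        paste0("res_",
                                               m$reserves$name))))
  Ctl[, "exc_vas_med_r"] <- 0.2 + 0.5 * lift_r
  Ctl[, "exc_vas_int_r"] <- 0.4 + 0.3 * lift_r
  Ctl[, "exc_vas_lat_r"] <- 0.3 + 0.4 * lift_r
  Ctl[, paste0("res_", m$reserves$name)] <- 0
  tr <- trajectory(t, S, Ctl, m)
  sw <- extract_swing_excitations(tr)
  # windows fall in the expected halves (t_f = 2.2 -> boundary at 1.1)
  expect_lt(max(sw$left$time) + 0.3, 1.1)
  expect_equal(min(sw$right$time), 0)  # re-zeroed to swing onset
  # vasti trace is the average of its three elements over the detected
  # unloaded (swing) window
  Fm <- foot_contact_forces(m, t(S[, paste0("q_", cn)]),
                            t(S[, paste0("u_", cn)]))
  thr <- 0.05 * m$total_mass * m$gravity
  half_r <- t >= 1.1
  keep <- half_r & Fm["right_fy", ] < thr
  win <- range(t[keep])
  inwin <- t >= win[1] & t <= win[2]
  expected <- rowMeans(cbind(0.2 + 0.5 * lift_r, 0.4 + 0.3 * lift_r,
                             0.3 + 0.4 * lift_r))[inwin]
  got <- sw$right$excitations[, "vasti_r"]
  expect_equal(length(got), sum(inwin))
  expect_equal(unname(got), unname(expected), tolerance = 1e-6)
})

test_that("charge comparison reproduces the published reduction statistics", {
  # charges in microcoulombs per swing (optimized vs manually tuned)
  opt <- c(il_l = 28.1, il_r = 294.7, vas_l = 9.5, vas_r = 21.1,
           ta_l = 17.5, ta_r = 38.9, tfl_l = 77.8, sart_r = 948.7,
           bfsh_r = 94.5)
  man <- c(il_l = 56.0, il_r = 585.0, vas_l = 19.2, vas_r = 55.0,
           ta_l = 58.4, ta_r = 195.0, tfl_l = 120.0, sart_r = 682.5,
           bfsh_r = 300.0)
  rep <- compare_patterns(opt, man)
  tab <- rep$table
  expect_equal(tab$percent_reduction[tab$muscle == "ta_r"], 80,
               tolerance = 0.01)
  expect_equal(tab$percent_reduction[tab$muscle == "tfl_l"], 35,
               tolerance = 0.01)
  expect_equal(unname(rep$summary$increases["sart_r"]), 39,
               tolerance = 0.01)
  expect_equal(rep$summary$mean_reduction, 58, tolerance = 0.01)
  expect_equal(rep$summary$n_reduced, 8L)
  # zero reference charge is flagged
  man2 <- man
  man2["ta_l"] <- 0
  expect_error(compare_patterns(opt, man2), "zero reference")
  # mismatched keys are rejected
  expect_error(compare_patterns(opt[-1], man), "same muscle keys")
})

test_that("pattern CSV/JSON round trip reproduces identical charge", {
  calib <- default_calib()
  set.seed(8)
  ex <- simple_excitations(duration = 1.1)
  pat <- compile_pattern(ex, calib)
  path <- file.path(tempdir(), "pattern_rt")
  write_pattern(pat, path)
  pat2 <- read_pattern(path)
  for (side in c("left", "right")) {
    for (ch in colnames(pat[[side]]$pw)) {
      expect_identical(charge_per_swing(pat2, side, ch),
                       charge_per_swing(pat, side, ch))
    }
  }
})
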