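# Cost subterms and their compositions.

make_ref_from_traj <- function(traj, marker_offsets = NULL) {
  model <- traj$model
  Q <- t(traj$states[, paste0("q_", model$coordinates$name)])
  pos <- fnstep:::model_marker_positions(model, Q)
  markers <- list()
  for (i in seq_len(nrow(model$markers))) {
    mm <- cbind(pos[2 * i - 1, ], pos[2 * i, ])
    nm <- model$markers$name[i]
    if (!is.null(marker_offsets[[nm]])) {
      mm <- sweep(mm, 2, marker_offsets[[nm]], `+`)
    }
    markers[[nm]] <- mm
  }
  Fm <- foot_contact_forces(model, Q,
                            t(traj$states[, paste0("u_",
                                                   model$coordinates$name)]))
  reference_data(marker_time = traj$time, markers = markers,
                 force_time = traj$time,
                 forces = list(left = t(Fm[1:2, ]), right = t(Fm[3:4, ])))
}

test_that("marker tracking is zero on coincident data and scales with weight", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, q = standing_pose(m), duration = 1, n = 21)
  ref <- make_ref_from_traj(tr)
  expect_equal(eval_marker_tracking(tr, ref), 0, tolerance = 1e-14)
  # constant 0.1 m offset on one weight-1 marker over 1 s: w d^2 T = 0.01
  ref2 <- make_ref_from_traj(tr, marker_offsets = list(HEEL_l = c(0.1, 0)))
  expect_equal(eval_marker_tracking(tr, ref2), 0.01, tolerance = 1e-12)
  # same offset on a bony-prominence marker (weight 10): 0.1
  ref3 <- make_ref_from_traj(tr, marker_offsets = list(ANK_l = c(0.1, 0)))
  expect_equal(eval_marker_tracking(tr, ref3), 0.1, tolerance = 1e-12)
  # marker missing from the reference is a named error
  ref4 <- ref
  ref4$markers$SACR <- NULL
  expect_error(eval_marker_tracking(tr, ref4), "SACR")
})

test_that("contact tracking normalizes by body weight", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, q = standing_pose(m), duration = 1, n = 21)
  ref <- make_ref_from_traj(tr)
  expect_equal(eval_contact_tracking(tr, ref), 0, tolerance = 1e-14)
  # constant 1 N error on one foot over 1 s: 1 / (m g)
  ref2 <- ref
  ref2$forces$left[, 2] <- ref2$forces$left[, 2] + 1
  expect_equal(eval_contact_tracking(tr, ref2),
               1 / (m$total_mass * m$gravity), tolerance = 1e-10)
  # mismatched grouping is a named error
  ref3 <- ref
  names(ref3$forces) <- c("left", "other")
  expect_error(eval_contact_tracking(tr, ref3), "feet")
})

test_that("synergy cost penalizes within-group excitation differences", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, q = standing_pose(m), duration = 1, n = 21)
  # identical members: zero (singleton groups are reported, not errors)
  expect_equal(suppressMessages(eval_synergy(tr)), 0)
  # pair e1 = 1, e2 = 0: contributes 1.0 over 1 s
  tr2 <- tr
  tr2$controls[, "exc_psoas_l"] <- 1
  tr2$controls[, "exc_iliacus_l"] <- 0
  expect_equal(suppressMessages(eval_synergy(tr2)), 1, tolerance = 1e-12)
  # triple e1 = 1, e2 = e3 = 0: two squared terms, 2.0
  tr3 <- tr
  tr3$controls[, "exc_vas_med_r"] <- 1
  tr3$controls[, "exc_vas_int_r"] <- 0
  tr3$controls[, "exc_vas_lat_r"] <- 0
  expect_equal(suppressMessages(eval_synergy(tr3)), 2, tolerance = 1e-12)
})

test_that("effort cost weights channels and divides by distance", {
  m <- double_integrator_model()
  tr <- constant_trajectory(m, duration = 1, n = 21, exc = 0)
  tr$controls[, "res_res_u"] <- 0
  expect_equal(eval_effort(tr, cost_weights(reserve_weight = 1), d = 1), 0)
  tr$controls[, "res_res_u"] <- 0.5
  w <- cost_weights(reserve_weight = 1)
  expect_equal(eval_effort(tr, w, d = 1), 0.25, tolerance = 1e-12)
  expect_equal(eval_effort(tr, w, d = 2), 0.125, tolerance = 1e-12)
  # without the distance flag the 1/d factor is omitted
  expect_equal(eval_effort(tr, w, d = 2, divide_by_distance = FALSE),
               0.25, tolerance = 1e-12)
  expect_error(eval_effort(tr, w, d = 0), "d must be > 0")
  # reserve channels are penalized relative to muscles
  expect_equal(eval_effort(tr, cost_weights(reserve_weight = 10), d = 1),
               2.5, tolerance = 1e-12)
})

test_that("energy injection penalty targets the trunk muscles only", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, duration = 1, n = 21, exc = 0)
  # the planar fixture omits rectus abdominus / external oblique
  expect_equal(eval_energy_penalty(tr), 0)
  # synthetic trajectory carrying those channels
  t <- seq(0, 1, length.out = 21)
  S <- tr$states
  Ctl <- cbind(tr$controls, exc_rect_abd = 1, exc_ext_obl = 1)
  tr2 <- trajectory(t, S, Ctl, m)
  expect_equal(eval_energy_penalty(tr2), 20, tolerance = 1e-12)
  Ctl3 <- cbind(tr$controls[, ], exc_rect_abd = 0.5, exc_ext_obl = 0)
  tr3 <- trajectory(seq(0, 2, length.out = 21), S, Ctl3, m)
  expect_equal(eval_energy_penalty(tr3), 5, tolerance = 1e-12)
})

test_that("auxiliary-derivative cost integrates squared tendon force rates", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, duration = 1, n = 21)
  expect_message(v <- eval_aux_deriv(tr), "rigid-tendon")
  expect_equal(v, 0)
  # one tendon, linear ramp of slope 2 N/s over 1 s: integral 4
  t <- seq(0, 1, length.out = 21)
  S <- cbind(tr$states, ft_x = 2 * t)
  tr2 <- trajectory(t, S, tr$controls, m)
  expect_equal(eval_aux_deriv(tr2), 4, tolerance = 1e-10)
  # constant tendon force: zero
  S3 <- cbind(tr$states, ft_x = rep(5, 21))
  expect_equal(eval_aux_deriv(trajectory(t, S3, tr$controls, m)), 0)
})

test_that("all subterm integrals match an independent trapezoidal oracle", {
  m <- planar_biped("model_p")
  set.seed(99)
  for (rep in 1:5) {
    t <- seq(0, 1.3, length.out = 41)
    n <- length(t)
    tr <- constant_trajectory(m, q = standing_pose(m), duration = 1.3,
                              n = n)
    # random smooth excitations
    for (cc in grep("^exc_", colnames(tr$controls))) {
      kn <- runif(5)
      tr$controls[, cc] <- splinefun(seq(0, 1.3, length.out = 5),
                                     kn)(t)
      tr$controls[, cc] <- pmin(pmax(tr$controls[, cc], 0), 1)
    }
    for (cc in grep("^res_", colnames(tr$controls))) {
      tr$controls[, cc] <- sin(runif(1, 1, 4) * t)
    }
    # synergy oracle
    E <- t(tr$controls[, paste0("exc_", m$muscles$name)])
    D <- fnstep:::synergy_differences(E, m$muscles)
    expect_equal(suppressMessages(eval_synergy(tr)),
                 trapz_oracle(t, colSums(D^2)), tolerance = 1e-10)
    # effort oracle
    w <- cost_weights(reserve_weight = 10)
    C <- rbind(E, t(tr$controls[, grep("^res_", colnames(tr$controls))]))
    wch <- c(rep(1, nrow(E)), rep(10, nrow(C) - nrow(E)))
    expect_equal(eval_effort(tr, w, d = 2),
                 trapz_oracle(t, colSums(wch * C^2)) / 2,
                 tolerance = 1e-10)
  }
})

test_that("cost composition follows the tracking and predictive forms", {
  w <- cost_weights()
  expect_equal(compose_cost(list(J_mt = 0, J_ct = 0, J_s = 0, J_e = 0,
                                 J_p = 0, J_ad = 0), w, "tracking"), 0)
  # tracking: unit weights, unit subterms, d = 2 -> 1+1+1+2+1+1 = 7
  s1 <- list(J_mt = 1, J_ct = 1, J_s = 1, J_e = 1, J_p = 1, J_ad = 1)
  expect_equal(compose_cost(s1, w, "tracking", d = 2), 7)
  # predictive: J_s + J_e + J_p + J_ad = 4
  expect_equal(compose_cost(s1, w, "predictive"), 4)
  # linear in each subterm and weight
  s2 <- s1
  s2$J_s <- 3
  expect_equal(compose_cost(s2, w, "predictive") -
                 compose_cost(s1, w, "predictive"), 2)
  w2 <- cost_weights(w_e = 5)
  expect_equal(compose_cost(s1, w2, "predictive"), 3 + 5)
  # tracking without reference subterms is a named error
  expect_error(compose_cost(list(J_s = 1), w, "tracking"), "J_mt")
})

test_that("cost report composes evaluated subterms consistently", {
  m <- planar_biped("model_p")
  tr <- constant_trajectory(m, q = standing_pose(m), duration = 1, n = 21)
  tr$controls[, "exc_tib_ant_l"] <- 0.4
  rep <- suppressMessages(cost_report(tr, mode = "predictive"))
  expect_gte(rep$total, 0)
  expect_equal(rep$total,
               compose_cost(rep[c("J_s", "J_e", "J_p", "J_ad")],
                            cost_weights(), "predictive"),
               tolerance = 1e-12)
  # JSON export round trip
  path <- tempfile(fileext = ".json")
  write_cost_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$total, rep$total, tolerance = 1e-9)
})
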