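# Transcription and solution of optimal-control problems.

test_that("transcription sizes the decision vector as points x variables + t_f", {
  m <- planar_biped("model_p")
  cons <- list(constraint_spec("sym_full"),
               constraint_spec("tf_bound", bounds = c(2.0, 2.2)))
  nlp <- transcribe(oc_problem(m, mode = "predictive",
                               constraints = cons, mesh_intervals = 10))
  P <- 2 * 10 + 1
  expect_equal(nlp$n_points, P)
  expect_equal(nlp$n_decision,
               P * (nlp$n_states + nlp$n_controls) + 1L)
  # inconsistent bounds are a named error
  expect_error(
    transcribe(oc_problem(m, mode = "predictive",
                          constraints = list(
                            constraint_spec("tf_bound",
                                            bounds = c(2.2, 2.0))))),
    "bounds")
})

test_that("compiled residual stack matches the reference implementation", {
  m <- planar_biped("model_g")
  ref <- generate_nt_reference(nt_reference_spec(), m)
  cons <- list(constraint_spec("sym_half"),
               constraint_spec("speed_bound", percent = 0.1))
  nlp <- transcribe(oc_problem(m, mode = "tracking", constraints = cons,
                               mesh_intervals = 4, ref = ref, t_f = 0.5))
  set.seed(13)
  for (i in 1:3) {
    z <- rnorm(nlp$n_decision) * 0.5
    fast <- nlp$eval_vec(z)
    slow <- nlp$eval_raw_reference(z)
    expect_equal(fast, c(slow$cost, slow$eq, slow$ineq),
                 tolerance = 1e-12)
  }
})

test_that("sparse colored Jacobian agrees with a dense finite difference", {
  m <- planar_biped("symmetric")
  cons <- list(constraint_spec("sym_half"),
               constraint_spec("speed_bound", percent = 1),
               constraint_spec("avg_speed", target = 0.1),
               constraint_spec("tf_bound", bounds = c(0.9, 1.1)),
               constraint_spec("intersect", min_gap = 0.05),
               constraint_spec("knees"),
               constraint_spec("rest"))
  nlp <- transcribe(oc_problem(m, mode = "predictive",
                               constraints = cons, mesh_intervals = 3))
  kc <- match(c("q_shank_l_q", "q_shank_r_q"), nlp$state_names)
  nlp$set_knee_events(cbind(kc, c(2L, 6L)))
  set.seed(17)
  z <- rnorm(nlp$n_decision) * 0.4
  r0 <- nlp$eval_vec(z)
  sp <- fnstep:::build_sparsity(nlp)
  J <- fnstep:::fd_jacobian(nlp$eval_vec, z, r0, sp)
  d <- 1e-6
  Jd <- matrix(0, length(r0), length(z))
  for (j in seq_along(z)) {
    zp <- z
    zp[j] <- zp[j] + d
    Jd[, j] <- (nlp$eval_vec(zp) - r0) / d
  }
  expect_equal(max(abs(as.matrix(J) - Jd)), 0)
})

test_that("the analytic double-integrator optimum has zero defects when inserted", {
  prob <- double_integrator_problem(Tf = 1, d = 1)
  nlp <- transcribe(prob)
  # closed-form minimum-effort trajectory: cubic position, quadratic
  # speed, linear control
  tt <- nlp$tau * 1
  q <- 3 * tt^2 - 2 * tt^3
  u <- 6 * tt - 6 * tt^2
  acc <- 6 - 12 * tt
  ctl <- acc / 10  # reserve control normalized by its 10 N capacity
  S <- cbind(q_block_tx = q, u_block_tx = u)
  Ctl <- cbind(res_res_u = ctl, acc_block_tx = acc)
  tr <- trajectory(tt, S, Ctl, prob$model)
  z <- nlp$guess_z(tr)
  r <- nlp$eval_raw(z)
  nx <- nlp$nx
  defects <- r$eq[seq_len(2 * nx * prob$mesh_intervals)]
  expect_lt(max(abs(defects)), 1e-8)
})

test_that("minimum-effort double integrator matches 12 d^2/T^3 to 4 significant figures", {
  for (Tf in c(1, 2)) {
    sol <- solve_ocp(double_integrator_problem(Tf = Tf, d = 1))
    expect_lt(sol$max_violation, 1e-6)
    analytic <- 12 / Tf^3
    expect_equal(sol$objective / analytic, 1, tolerance = 5e-5)
    # control is linear in time with the analytic endpoints
    u <- sol$trajectory$controls[, "res_res_u"] * 10
    tt <- sol$trajectory$time
    fit <- stats::lm(u ~ tt)
    expect_equal(unname(coef(fit)[2]), -12 / Tf^3, tolerance = 1e-3)
    expect_lt(max(abs(residuals(fit))), 1e-3)
  }
})

test_that("balanced-rod reorientation matches the rotational closed form", {
  # a rod pivoted at its center of mass is a rotational double
  # integrator: minimum-effort objective 12 I^2 dtheta^2 / T^3 (divided
  # by the minimum-distance floor, since the CoM does not translate)
  segs <- data.frame(
    name = c("anchor", "rod"), parent = c(NA, "anchor"),
    mass = c(0, 2), inertia = c(0, 2 * 0.5^2 / 12),
    dx = 0, dy = 0, comx = 0, comy = 0,
    qsign = 1, length = c(0, 0.5), stringsAsFactors = FALSE)
  cr <- data.frame(name = "rod_q", lo = -2 * pi, hi = 2 * pi,
                   speed_lo = -20, speed_hi = 20)
  res <- data.frame(name = "res_rod", coordinate = "rod_q",
                    max = 20, tag = "penalized",
                    stringsAsFactors = FALSE)
  m <- msk_model(segs, base_dofs = character(0), coord_ranges = cr,
                 reserves = res)
  Ip <- 2 * 0.5^2 / 12
  dth <- 1
  Tf <- 1
  prob <- oc_problem(
    m, mode = "predictive",
    weights = cost_weights(w_e = 1, reserve_weight = 20^2),
    mesh_intervals = 10, t_f = Tf,
    endpoint_conditions = list(
      initial = c(q_rod_q = 0, u_rod_q = 0),
      final = c(q_rod_q = dth, u_rod_q = 0)),
    options = list(opt_tol = 1e-6, feas_tol = 1e-8))
  sol <- solve_ocp(prob)
  expect_lt(sol$max_violation, 1e-6)
  analytic <- 12 * Ip^2 * dth^2 / Tf^3 / 0.05
  expect_equal(sol$objective / analytic, 1, tolerance = 5e-4)
})

test_that("warm starts are deterministic and refinement does not degrade the objective", {
  # identical problem and guess give identical objectives
  s1 <- solve_ocp(double_integrator_problem(Tf = 1, d = 1))
  s2 <- solve_ocp(double_integrator_problem(Tf = 1, d = 1))
  expect_identical(s1$objective, s2$objective)
  # pendulum swing against gravity: re-solving on a refined mesh from the
  # coarse solution must not raise the objective beyond discretization
  # error (5% documented tolerance)
  m <- pendulum_torque_model(mass = 1, length = 0.5, gravity = 9.81,
                             tau_max = 20)
  mkprob <- function(mesh) {
    oc_problem(
      m, mode = "predictive",
      weights = cost_weights(w_e = 1, reserve_weight = 20^2),
      mesh_intervals = mesh, t_f = 1,
      endpoint_conditions = list(
        initial = c(q_rod_q = 0, u_rod_q = 0),
        final = c(q_rod_q = pi / 2, u_rod_q = 0)))
  }
  c1 <- solve_ocp(mkprob(8))
  expect_lt(c1$max_violation, 1e-5)
  c2 <- solve_ocp(mkprob(16), guess = c1$trajectory)
  expect_lt(c2$max_violation, 1e-5)
  expect_lt(c2$objective, c1$objective * 1.05)
})

test_that("infeasible problems report failure without raising", {
  # demand 10 m/s average speed within 0.5 s from rest with bounded
  # travel: unattainable
  m <- double_integrator_model()
  cons <- list(constraint_spec("avg_speed", target = 10),
               constraint_spec("tf_bound", bounds = c(0.4, 0.5)),
               constraint_spec("rest"))
  prob <- oc_problem(m, mode = "predictive",
                     weights = cost_weights(reserve_weight = 100),
                     constraints = cons, mesh_intervals = 5,
                     options = list(max_outer = 6, max_inner = 30))
  expect_no_error(sol <- solve_ocp(prob))
  expect_false(sol$status == "converged")
  expect_gt(sol$max_violation, 1e-3)
})

test_that("predictive objective equals the composed synergy cost on zero controls", {
  m <- planar_biped("model_p")
  cons <- list(constraint_spec("sym_full"),
               constraint_spec("tf_bound", bounds = c(2.0, 2.2)))
  prob <- oc_problem(m, mode = "predictive", constraints = cons,
                     mesh_intervals = 3)
  nlp <- transcribe(prob)
  # a zero-excitation trajectory has zero synergy subterm; its
  # transcription objective reduces to the (distance-normalized) effort
  # of the excitation floor
  z <- nlp$guess_z(balanced_standing_trajectory(m, duration = 2.1,
                                                n_points = nlp$P))
  r <- nlp$eval_raw(z)
  tr <- nlp$build_trajectory(z)
  sub <- list(J_s = suppressMessages(eval_synergy(tr, "simpson")),
              J_e = eval_effort(tr, prob$weights,
                                d = nlp$options$min_distance,
                                quadrature = "simpson"),
              J_p = 0, J_ad = 0)
  expect_equal(sum(r$cost^2),
               compose_cost(sub, prob$weights, "predictive"),
               tolerance = 1e-6)
})
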