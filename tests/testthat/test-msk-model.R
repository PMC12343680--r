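# Muscle mechanics, contact, and multibody dynamics of the model module.

test_that("Hill muscle force matches the curve oracle and its identity point", {
  mtu <- list(fmax = 1234, pennation = 0)
  # identity point: maximum isometric force exactly
  expect_equal(muscle_force(1, 1, 0, mtu), 1234)
  # passive force at optimal length is zero
  expect_equal(muscle_force(0, 1, 0, mtu), 0, tolerance = 1e-12)
  # random grid against an independently coded curve oracle
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1)
    l <- runif(1, 0.6, 1.6)
    v <- runif(1, -0.9, 0.9)
    expect_equal(muscle_force(a, l, v, mtu),
                 hill_oracle(a, l, v, fmax = 1234),
                 tolerance = 1e-12)
  }
  # pennation scales by its cosine
  mtu2 <- list(fmax = 1000, pennation = 0.3)
  expect_equal(muscle_force(0.5, 1.1, 0.2, mtu2),
               hill_oracle(0.5, 1.1, 0.2, 1000, 0.3), tolerance = 1e-12)
  # invalid inputs are rejected with a diagnostic
  expect_error(muscle_force(NaN, 1, 0, mtu), "non-finite")
  expect_error(muscle_force(1.2, 1, 0, mtu), "activation")
  expect_error(muscle_force(1, -0.1, 0, mtu), "length")
})

test_that("activation dynamics follow first-order rates with the right sign", {
  mtu <- list(tact = 0.01, tdeact = 0.04)
  expect_equal(activation_dynamics(0.5, 0.5, mtu), 0)
  expect_equal(activation_dynamics(1, 0, mtu), 100, tolerance = 1e-6)
  expect_equal(activation_dynamics(0, 1, mtu), -25, tolerance = 1e-6)
  # sign always matches e - a
  set.seed(7)
  e <- runif(20)
  a <- runif(20)
  r <- activation_dynamics(e, a, list(tact = 0.015, tdeact = 0.06))
  expect_true(all(sign(r) == sign(e - a)))
  expect_error(activation_dynamics(1.5, 0, mtu), "\\[0, 1\\]")
})

test_that("smoothed contact vanishes above ground and matches Hunt-Crossley in contact", {
  sph <- list(stiffness = 5e4, dissipation = 1.0, mu_d = 0.8, mu_v = 1.0,
              smoothing = 1e-3, v_smooth = 0.05)
  # 10 cm above ground: negligible force
  f <- contact_force(-0.1, 0, 0, sph)
  expect_lt(sqrt(sum(f^2)), 1e-3)
  # static penetration: unsmoothed Hunt-Crossley normal force within the
  # smoothing tolerance
  for (pen in c(0.01, 0.02, 0.04)) {
    f <- contact_force(pen, 0, 0, sph)
    hc <- sph$stiffness * pen^1.5
    expect_equal(unname(f["normal"]), hc, tolerance = 5e-3)
  }
  # dissipation factor: loading increases, unloading decreases the force
  fl <- contact_force(0.01, 0.1, 0, sph)
  fu <- contact_force(0.01, -0.1, 0, sph)
  f0 <- contact_force(0.01, 0, 0, sph)
  expect_gt(fl[["normal"]], f0[["normal"]])
  expect_lt(fu[["normal"]], f0[["normal"]])
  # reversing slip flips the tangential force, normal unchanged
  fp <- contact_force(0.01, 0, 0.2, sph)
  fm <- contact_force(0.01, 0, -0.2, sph)
  expect_equal(fp[["tangential"]], -fm[["tangential"]])
  expect_equal(fp[["normal"]], fm[["normal"]])
  expect_lt(fp[["tangential"]], 0)  # opposes slip
  # C1 at zero penetration: central-difference derivative converges
  d1 <- (contact_force(1e-4, 0, 0, sph)[["normal"]] -
           contact_force(-1e-4, 0, 0, sph)[["normal"]]) / 2e-4
  d2 <- (contact_force(5e-5, 0, 0, sph)[["normal"]] -
           contact_force(-5e-5, 0, 0, sph)[["normal"]]) / 1e-4
  expect_equal(d1, d2, tolerance = 0.05)
})

test_that("static standing residual matches an independent virtual-work oracle", {
  m <- planar_biped("model_g")
  q <- standing_pose(m)
  q["pelvis_ty"] <- q["pelvis_ty"] - 0.005  # loaded stance
  nq <- length(q)
  u <- numeric(nq)
  nm <- nrow(m$muscles)
  # oracle: generalized applied force from gravity and contact via
  # finite-difference point Jacobians
  com_y <- function(qv) {
    segs <- m$segments$name
    pos <- fnstep:::model_point_positions(m, matrix(qv, nq, 1), segs,
                                          rbind(m$segments$comx,
                                                m$segments$comy))
    pos[seq(2, 2 * length(segs), by = 2), 1]
  }
  sph_xy <- function(qv) {
    fnstep:::model_point_positions(m, matrix(qv, nq, 1),
                                   m$spheres$segment,
                                   rbind(m$spheres$x, m$spheres$y))[, 1]
  }
  Fs <- fnstep:::cpp_sphere_state(m$compiled, q, u)  # rows: px py fx fy
  Qgen <- numeric(nq)
  h <- 1e-7
  for (j in seq_len(nq)) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    dcom <- (com_y(qp) - com_y(qm)) / (2 * h)
    dsph <- (sph_xy(qp) - sph_xy(qm)) / (2 * h)
    grav <- -sum(m$segments$mass * m$gravity * dcom)
    cont <- sum(Fs[3, ] * dsph[seq(1, 11, 2)] +
                  Fs[4, ] * dsph[seq(2, 12, 2)])
    Qgen[j] <- grav + cont
  }
  r <- dynamics_residual(list(q = q, u = u, a = numeric(nm)),
                         list(udot = numeric(nq)),
                         list(e = numeric(nm)), m)
  dyn <- r[paste0("dyn_", m$coordinates$name)]
  # residual of the unactuated static state equals minus the applied
  # generalized force; balance requires tau = -Qgen
  expect_lt(max(abs(dyn + Qgen)), 1e-5 * m$total_mass * m$gravity)
})

test_that("force-balance residual is linear in inertia (airborne state)", {
  base <- planar_biped("symmetric")
  ranges <- base$coordinates[, c("name", "lo", "hi", "speed_lo",
                                 "speed_hi")]
  skel <- function(scale) {
    segs <- base$segments
    segs$mass <- scale * segs$mass
    segs$inertia <- scale * segs$inertia
    msk_model(segs, base_dofs = c("tx", "ty", "rot"),
              coord_ranges = ranges)
  }
  m1 <- skel(1)
  m2 <- skel(2)
  set.seed(3)
  nq <- nrow(m1$coordinates)
  q <- setNames(runif(nq, -0.2, 0.2), m1$coordinates$name)
  q["pelvis_ty"] <- 2  # airborne: no contact
  u <- runif(nq, -1, 1)
  ud <- runif(nq, -2, 2)
  st <- list(q = q, u = u)
  dv <- list(udot = ud)
  ct <- list()
  r1 <- dynamics_residual(st, dv, ct, m1)
  r2 <- dynamics_residual(st, dv, ct, m2)
  i <- paste0("dyn_", m1$coordinates$name)
  expect_equal(unname(r2[i]), 2 * unname(r1[i]), tolerance = 1e-10)
})

test_that("passive pendulum integration reproduces the analytic period", {
  m <- pendulum_model(mass = 2, length = 0.5)
  Ip <- 2 * 0.5^2 / 12 + 2 * 0.25^2
  Tan <- 2 * pi * sqrt(Ip / (2 * 9.81 * 0.25))
  amp <- 0.05
  tt <- seq(0, 3 * Tan, by = 1e-4)
  sim <- integrate_dynamics(m, q0 = amp, u0 = 0, t = tt)
  cross <- which(diff(sign(sim$q[, 1])) > 0)
  per <- mean(diff(tt[cross]))
  expect_equal(per, Tan, tolerance = 0.01)
  # mass matrix equals the pivot inertia
  expect_equal(unname(mass_matrix(m, 0.3)[1, 1]), Ip, tolerance = 1e-12)
})

test_that("passive drop with dissipative contact never gains energy", {
  m <- planar_biped("symmetric")
  q0 <- standing_pose(m)
  q0["pelvis_ty"] <- q0["pelvis_ty"] + 0.02  # drop from 2 cm
  tt <- seq(0, 0.35, by = 2e-4)
  sim <- integrate_dynamics(m, q0, numeric(10), tt)
  etot <- vapply(seq_along(tt), function(i) {
    mechanical_energy(m, sim$q[i, ], sim$u[i, ])$total
  }, 0)
  increases <- diff(etot)
  # tolerance covers integration error and the smoothing-zone mismatch
  # between the contact force and its stored elastic potential
  expect_lt(max(increases), 5e-3)
  expect_lt(etot[length(etot)], etot[1])
})

test_that("mirrored states produce mirrored dynamics residuals", {
  m <- planar_biped("model_g")
  mm <- mirror_map(m)
  set.seed(11)
  nq <- 10
  nm <- nrow(m$muscles)
  q <- setNames(runif(nq, -0.3, 0.3), m$coordinates$name)
  q["pelvis_ty"] <- 0.95
  u <- runif(nq, -1, 1)
  ud <- runif(nq, -3, 3)
  a <- runif(nm, 0, 1)
  e <- runif(nm, 0.01, 1)
  res <- runif(nrow(m$reserves), -1, 1)
  r <- dynamics_residual(list(q = q, u = u, a = a), list(udot = ud),
                         list(e = e, res = res), m)
  rm_ <- dynamics_residual(
    list(q = q[mm$coord], u = u[mm$coord], a = a[mm$muscle]),
    list(udot = ud[mm$coord]),
    list(e = e[mm$muscle], res = res[mm$reserve]), m)
  i <- paste0("dyn_", m$coordinates$name)
  expect_equal(unname(rm_[i]), unname(r[i][mm$coord]), tolerance = 1e-9)
  # the mirror map composed with itself is the identity
  expect_identical(mm$coord[mm$coord], seq_along(mm$coord))
  expect_identical(mm$muscle[mm$muscle], seq_along(mm$muscle))
})

test_that("model YAML round trip preserves the dynamics", {
  m <- planar_biped("model_p")
  path <- tempfile(fileext = ".yaml")
  write_msk_model(m, path)
  m2 <- read_msk_model(path)
  expect_equal(m2$total_mass, m$total_mass)
  expect_equal(nrow(m2$muscles), nrow(m$muscles))
  set.seed(5)
  q <- setNames(runif(10, -0.2, 0.2), m$coordinates$name)
  q["pelvis_ty"] <- 0.94
  u <- runif(10, -1, 1)
  ud <- runif(10, -2, 2)
  a <- runif(15)
  st <- list(q = q, u = u, a = a)
  ct <- list(e = runif(15, 0.01, 1), res = runif(10, -1, 1))
  expect_equal(dynamics_residual(st, list(udot = ud), ct, m2),
               dynamics_residual(st, list(udot = ud), ct, m),
               tolerance = 1e-12)
})

test_that("model invariants are enforced at construction", {
  m <- planar_biped()
  expect_equal(m$total_mass, sum(m$segments$mass))
  # a muscle group with four members is rejected
  mus <- m$muscles
  mus$group[mus$group == "ta_r"] <- "vasti_r"
  expect_error(
    msk_model(m$segments, c("tx", "ty", "rot"),
              m$coordinates[, c("name", "lo", "hi", "speed_lo",
                                "speed_hi")],
              muscles = mus, moment_arms = m$moment_arms,
              groups = m$groups, spheres = m$spheres,
              reserves = m$reserves),
    "1 to 3 members")
  # unknown group membership is rejected
  mus2 <- m$muscles
  mus2$group[1] <- "nonexistent"
  expect_error(
    msk_model(m$segments, c("tx", "ty", "rot"),
              m$coordinates[, c("name", "lo", "hi", "speed_lo",
                                "speed_hi")],
              muscles = mus2, moment_arms = m$moment_arms,
              groups = m$groups),
    "declared group")
})
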