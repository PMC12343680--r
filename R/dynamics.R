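# User-facing dynamics operations: Hill muscle mechanics, activation
# dynamics, smoothed contact, and the implicit multibody dynamics residual.

#' Hill-type muscle-tendon force
#'
#' Active force-length and force-velocity dependencies plus passive fiber
#' elasticity, using a smooth curve family normalized so the identity point
#' (a = 1, normalized length 1, normalized velocity 0) produces exactly the
#' maximum isometric force.
#'
#' @param activation activation in \[0, 1\]
#' @param norm_fiber_length fiber length / optimal fiber length
#' @param norm_fiber_velocity fiber velocity / (vmax * optimal length);
#'   positive lengthening
#' @param mtu a muscle row (list or one-row data.frame) with at least
#'   `fmax` (N) and `pennation` (rad)
#' @return force along the tendon, N
#' @export
muscle_force <- function(activation, norm_fiber_length,
                         norm_fiber_velocity, mtu) {
  check_finite(c(activation, norm_fiber_length, norm_fiber_velocity),
               "muscle_force inputs")
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]")
  }
  if (any(norm_fiber_length <= 0)) stop("fiber length must be > 0")
  as.numeric(cpp_muscle_force(activation, norm_fiber_length,
                              norm_fiber_velocity,
                              as.numeric(mtu$fmax),
                              as.numeric(mtu$pennation %||% 0)))
}

#' First-order activation dynamics
#'
#' Activation approaches excitation with the activation time constant when
#' excitation exceeds activation and with the deactivation time constant
#' otherwise (smoothly blended near equality).
#'
#' @param excitation neural excitation in \[0, 1\]
#' @param activation current activation in \[0, 1\]
#' @param mtu muscle row with `tact` and `tdeact` (s)
#' @return da/dt (1/s)
#' @export
activation_dynamics <- function(excitation, activation, mtu) {
  if (any(excitation < 0 | excitation > 1) ||
      any(activation < 0 | activation > 1)) {
    stop("excitation and activation must lie in [0, 1]")
  }
  n <- max(length(excitation), length(activation))
  as.numeric(cpp_activation_rate(
    rep_len(excitation, n), rep_len(activation, n),
    rep_len(as.numeric(mtu$tact), n), rep_len(as.numeric(mtu$tdeact), n)))
}

#' Smoothed Hunt-Crossley contact force
#'
#' Continuous, differentiable sphere-on-plane contact: the penetration and
#' the Hunt-Crossley dissipation factor are smoothed so the force is
#' defined (and tiny) for negative penetration; friction is a smooth tanh
#' slip law plus a viscous term.
#'
#' @param penetration sphere penetration into the ground, m (negative above
#'   ground)
#' @param penetration_rate m/s, positive when penetrating faster
#' @param slip_velocity tangential velocity of the sphere center, m/s
#' @param sphere contact sphere row with `stiffness`, `dissipation`,
#'   `mu_d`, `mu_v`, `smoothing`, `v_smooth`
#' @return named vector `c(tangential = , normal = )`, N
#' @export
contact_force <- function(penetration, penetration_rate = 0,
                          slip_velocity = 0, sphere) {
  n <- max(length(penetration), length(penetration_rate),
           length(slip_velocity))
  f <- cpp_contact_force(rep_len(penetration, n),
                         rep_len(penetration_rate, n),
                         rep_len(slip_velocity, n),
                         sphere$stiffness, sphere$dissipation,
                         sphere$mu_d, sphere$mu_v,
                         sphere$smoothing, sphere$v_smooth)
  if (n == 1L) {
    c(tangential = f$tangential, normal = f$normal)
  } else {
    cbind(tangential = f$tangential, normal = f$normal)
  }
}

#' Implicit multibody dynamics residual
#'
#' Evaluates the implicit equations of motion: the residual is zero exactly
#' when the supplied state, state derivative and controls satisfy the
#' multibody, muscle and contact equations. Components are named; the
#' kinematic rows compare the supplied coordinate derivatives to the speed
#' states, the force rows are in N or Nm, the activation rows in 1/s.
#'
#' @param state list with `q` (coordinates), `u` (speeds), `a`
#'   (activations) and, in compliant-tendon mode, `ft` (normalized tendon
#'   forces)
#' @param state_derivative list with `qdot`, `udot`, `adot` (and `ftdot`)
#' @param controls list with `e` (muscle excitations) and `res` (reserve
#'   controls in \[-1, 1\])
#' @param model an `msk_model`
#' @return named residual vector
#' @export
dynamics_residual <- function(state, state_derivative, controls, model) {
  nq <- n_coord(model)
  nm <- n_muscle(model)
  q <- as.numeric(state$q); u <- as.numeric(state$u)
  a <- as.numeric(state$a %||% numeric(nm))
  stopifnot(length(q) == nq, length(u) == nq, length(a) == nm)
  e <- as.numeric(controls$e %||% numeric(nm))
  res <- as.numeric(controls$res %||% numeric(n_reserve(model)))
  qdot <- as.numeric(state_derivative$qdot %||% u)
  udot <- as.numeric(state_derivative$udot)
  adot <- as.numeric(state_derivative$adot %||% numeric(nm))
  ft <- as.numeric(state$ft %||% numeric(nm))
  check_finite(c(q, u, a, e, res, qdot, udot, adot), "dynamics inputs")
  FT <- if (model$rigid_tendon) matrix(0, nm, 1) else matrix(ft, nm, 1)
  dyn <- cpp_dyn_residual_batch(model$compiled,
                                matrix(q, nq, 1), matrix(u, nq, 1),
                                matrix(udot, nq, 1),
                                matrix(a, max(nm, 0), 1),
                                matrix(res, length(res), 1), FT)[, 1]
  kin <- qdot - u
  act <- if (nm > 0L) {
    adot - cpp_activation_rate(e, a, model$muscles$tact,
                               model$muscles$tdeact)
  } else numeric()
  out <- c(setNames(kin, paste0("kin_", coord_names(model))),
           setNames(dyn, paste0("dyn_", coord_names(model))),
           if (nm > 0L) setNames(act, paste0("act_", model$muscles$name)))
  if (!model$rigid_tendon && nm > 0L) {
    ftdot <- as.numeric(state_derivative$ftdot %||% numeric(nm))
    eq <- cpp_tendon_equilibrium_batch(model$compiled,
                                       matrix(q, nq, 1), matrix(u, nq, 1),
                                       matrix(a, nm, 1), matrix(ft, nm, 1),
                                       matrix(ftdot, nm, 1))[, 1]
    out <- c(out, setNames(eq, paste0("ten_", model$muscles$name)))
  }
  out
}

#' Forward dynamics: generalized accelerations
#'
#' @inheritParams dynamics_residual
#' @return named acceleration vector (rigid-tendon models)
#' @export
forward_dynamics <- function(state, controls, model) {
  nq <- n_coord(model)
  nm <- n_muscle(model)
  M <- cpp_mass_matrix(model$compiled, as.numeric(state$q))
  if (rcond(M) < 1e-12) {
    stop("singular mass matrix at configuration (",
         paste(signif(state$q, 3), collapse = ", "), ")")
  }
  acc <- cpp_fd_accel(model$compiled, as.numeric(state$q),
                      as.numeric(state$u),
                      as.numeric(state$a %||% numeric(nm)),
                      as.numeric(controls$res %||%
                                   numeric(n_reserve(model))),
                      as.numeric(state$ft %||% numeric(nm)))
  setNames(as.numeric(acc), coord_names(model))
}

#' Mass matrix at a configuration
#' @param model an `msk_model`
#' @param q coordinate vector
#' @export
mass_matrix <- function(model, q) {
  M <- cpp_mass_matrix(model$compiled, as.numeric(q))
  dimnames(M) <- list(coord_names(model), coord_names(model))
  M
}

#' Mechanical energy of a state
#'
#' Kinetic plus gravitational plus contact elastic energy. With zero
#' excitation and dissipative contact this total is non-increasing along
#' trajectories.
#' @param model an `msk_model`
#' @param q,u coordinate and speed vectors
#' @return list with `kinetic`, `gravitational`, `contact`, `total` (J)
#' @export
mechanical_energy <- function(model, q, u) {
  cpp_energy(model$compiled, as.numeric(q), as.numeric(u))
}

#' Fixed-step RK4 integration of the model dynamics
#'
#' Convenience integrator for simulation tests (passive or with prescribed
#' controls); rigid-tendon models only. Activations follow the activation
#' dynamics.
#'
#' @param model an `msk_model`
#' @param q0,u0 initial coordinates and speeds
#' @param t time grid (uniform)
#' @param controls function of time returning `list(e = , res = )`;
#'   defaults to passive (all zero)
#' @return list with `time`, `q`, `u`, `a` matrices (time in rows)
#' @export
integrate_dynamics <- function(model, q0, u0, t,
                               controls = function(tt) list()) {
  nq <- n_coord(model)
  nm <- n_muscle(model)
  nr <- n_reserve(model)
  q <- matrix(NA_real_, length(t), nq,
              dimnames = list(NULL, coord_names(model)))
  u <- q
  a <- matrix(NA_real_, length(t), max(nm, 1L))
  x <- c(as.numeric(q0), as.numeric(u0), numeric(nm))
  deriv <- function(tt, x) {
    qq <- x[1:nq]; uu <- x[nq + 1:nq]
    aa <- if (nm > 0L) x[2 * nq + 1:nm] else numeric()
    ctl <- controls(tt)
    e <- rep_len(ctl$e %||% 0, max(nm, 0L))
    res <- rep_len(ctl$res %||% 0, nr)
    acc <- cpp_fd_accel(model$compiled, qq, uu, aa, res, numeric(nm))
    adot <- if (nm > 0L) {
      cpp_activation_rate(e, aa, model$muscles$tact, model$muscles$tdeact)
    } else numeric()
    c(uu, as.numeric(acc), adot)
  }
  for (i in seq_along(t)) {
    q[i, ] <- x[1:nq]; u[i, ] <- x[nq + 1:nq]
    if (nm > 0L) a[i, seq_len(nm)] <- x[2 * nq + 1:nm]
    if (i < length(t)) {
      h <- t[i + 1] - t[i]
      k1 <- deriv(t[i], x)
      k2 <- deriv(t[i] + h / 2, x + h / 2 * k1)
      k3 <- deriv(t[i] + h / 2, x + h / 2 * k2)
      k4 <- deriv(t[i] + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  list(time = t, q = q, u = u, a = if (nm > 0L) a[, seq_len(nm)] else NULL)
}

# batch helpers used by costs/constraints (Q, U: ncoord x P)

model_marker_positions <- function(model, Q) {
  mk <- model$markers
  seg_idx <- setNames(seq_len(nrow(model$segments)) - 1L,
                      model$segments$name)
  P <- cpp_point_positions(model$compiled, Q,
                           as.integer(seg_idx[mk$segment]),
                           rbind(mk$x, mk$y))
  rownames(P) <- paste0(rep(mk$name, each = 2), c("_x", "_y"))
  P
}

model_point_positions <- function(model, Q, segments, offsets) {
  seg_idx <- setNames(seq_len(nrow(model$segments)) - 1L,
                      model$segments$name)
  cpp_point_positions(model$compiled, Q, as.integer(seg_idx[segments]),
                      offsets)
}

#' Whole-body center of mass over a batch of states
#' @param model an `msk_model`
#' @param Q,U coordinate / speed matrices (coordinates x points)
#' @return 4 x P matrix with rows x, y, vx, vy
#' @export
com_state <- function(model, Q, U = NULL) {
  Q <- as.matrix(Q)
  if (is.null(U)) U <- matrix(0, nrow(Q), ncol(Q))
  out <- cpp_com_batch(model$compiled, Q, as.matrix(U))
  rownames(out) <- c("x", "y", "vx", "vy")
  out
}

#' Per-foot resultant ground contact force over a batch of states
#' @inheritParams com_state
#' @return 4 x P matrix with rows left_fx, left_fy, right_fx, right_fy (N)
#' @export
foot_contact_forces <- function(model, Q, U = NULL) {
  Q <- as.matrix(Q)
  if (is.null(U)) U <- matrix(0, nrow(Q), ncol(Q))
  out <- cpp_foot_forces_batch(model$compiled, Q, as.matrix(U))
  rownames(out) <- c("left_fx", "left_fy", "right_fx", "right_fy")
  out
}
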