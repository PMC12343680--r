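# shared fixtures: simple mechanical models and trajectory builders

pendulum_model <- function(mass = 2, length = 0.5, gravity = 9.81) {
  segs <- data.frame(
    name = c("anchor", "rod"), parent = c(NA, "anchor"),
    mass = c(0, mass), inertia = c(0, mass * length^2 / 12),
    dx = 0, dy = 0, comx = 0, comy = c(0, -length / 2),
    qsign = 1, length = c(0, length), stringsAsFactors = FALSE)
  cr <- data.frame(name = "rod_q", lo = -2 * pi, hi = 2 * pi,
                   speed_lo = -50, speed_hi = 50)
  msk_model(segs, base_dofs = character(0), coord_ranges = cr,
            gravity = gravity)
}

# torque-actuated pendulum (reserve on the rod coordinate)
pendulum_torque_model <- function(mass = 2, length = 0.5, gravity = 9.81,
                                  tau_max = 20) {
  segs <- data.frame(
    name = c("anchor", "rod"), parent = c(NA, "anchor"),
    mass = c(0, mass), inertia = c(0, mass * length^2 / 12),
    dx = 0, dy = 0, comx = 0, comy = c(0, -length / 2),
    qsign = 1, length = c(0, length), stringsAsFactors = FALSE)
  cr <- data.frame(name = "rod_q", lo = -2 * pi, hi = 2 * pi,
                   speed_lo = -20, speed_hi = 20)
  res <- data.frame(name = "res_rod", coordinate = "rod_q",
                    max = tau_max, tag = "penalized",
                    stringsAsFactors = FALSE)
  msk_model(segs, base_dofs = character(0), coord_ranges = cr,
            reserves = res, gravity = gravity)
}

# unit point mass sliding on x with one force reserve
double_integrator_model <- function(umax = 10) {
  segs <- data.frame(name = "block", parent = NA, mass = 1,
                     inertia = 0.01, dx = 0, dy = 0, comx = 0, comy = 0,
                     qsign = 1, length = 0.1, stringsAsFactors = FALSE)
  cr <- data.frame(name = "block_tx", lo = -2, hi = 3,
                   speed_lo = -10, speed_hi = 10)
  res <- data.frame(name = "res_u", coordinate = "block_tx", max = umax,
                    tag = "penalized", stringsAsFactors = FALSE)
  msk_model(segs, base_dofs = "tx", coord_ranges = cr, reserves = res)
}

# minimum-effort rest-to-rest double-integrator problem; the analytic
# optimum is u(t) = 6 d / T^2 (1 - 2 t / T) with objective 12 d^2 / T^3
double_integrator_problem <- function(Tf = 1, d = 1, umax = 10,
                                      mesh = 10, options = list()) {
  m <- double_integrator_model(umax)
  opts <- modifyList(list(opt_tol = 1e-6, feas_tol = 1e-8), options)
  oc_problem(
    m, mode = "predictive",
    weights = cost_weights(w_e = 1, reserve_weight = umax^2),
    mesh_intervals = mesh, t_f = Tf,
    endpoint_conditions = list(
      initial = c(q_block_tx = 0, u_block_tx = 0),
      final = setNames(c(d, 0), c("q_block_tx", "u_block_tx"))),
    options = opts)
}

# constant-state trajectory for a model (handy cost/constraint fixture)
constant_trajectory <- function(model, q = NULL, duration = 1,
                                n = 11, exc = 0.01) {
  nq <- nrow(model$coordinates)
  nm <- if (is.null(model$muscles)) 0L else nrow(model$muscles)
  nr <- if (is.null(model$reserves)) 0L else nrow(model$reserves)
  cn <- model$coordinates$name
  q <- q %||% setNames(numeric(nq), cn)
  S <- matrix(rep(c(q, numeric(nq), rep(exc, nm)), each = n), n,
              2 * nq + nm)
  colnames(S) <- c(paste0("q_", cn), paste0("u_", cn),
                   if (nm > 0L) paste0("act_", model$muscles$name))
  Ctl <- matrix(rep(c(rep(exc, nm), numeric(nr)), each = n), n, nm + nr)
  colnames(Ctl) <- c(if (nm > 0L) paste0("exc_", model$muscles$name),
                     if (nr > 0L) paste0("res_", model$reserves$name))
  trajectory(seq(0, duration, length.out = n), S, Ctl, model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# test-side trapezoidal quadrature oracle (kept independent of the
# package's quadrature helper)
trapz_oracle <- function(t, v) {
  n <- length(t)
  sum((v[-1] + v[-n]) / 2 * diff(t))
}

# test-side Hill curve oracle with the published smooth-curve constants,
# normalized at the identity point
hill_oracle <- function(a, l, v, fmax = 1, pennation = 0) {
  fl <- function(x) {
    b1 <- c(0.814483478343008, 0.433004984392647, 0.1)
    b2 <- c(1.055033428970575, 0.71677541339776, 1.0)
    b3 <- c(0.162384573599574, -0.029947116970696, 0.353553390593274)
    b4 <- c(0.063303448465465, 0.200356847296188, 0)
    sum(b1 * exp(-0.5 * (x - b2)^2 / (b3 + b4 * x)^2))
  }
  fv <- function(x) {
    d1 <- -0.318323436899127; d2 <- -8.14915604347525
    d3 <- -0.374121508647863; d4 <- 0.885644059915004
    z <- d2 * x + d3
    d1 * log(z + sqrt(z^2 + 1)) + d4
  }
  fp <- function(x) (exp(4 * (x - 1) / 0.6) - 1) / (exp(4) - 1)
  fmax * (a * fl(l) / fl(1) * fv(v) / fv(0) + fp(l)) * cos(pennation)
}
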