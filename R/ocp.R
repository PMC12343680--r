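# Direct-collocation transcription of optimal-control gait problems.
# Separated Hermite-Simpson defects on a uniform mesh; implicit dynamics
# (generalized accelerations are extra controls constrained by the
# multibody residual at every collocation point); all decision variables
# are reparameterized through their bounds onto an unconstrained scale.

#' Define an optimal-control problem
#'
#' @param model an `msk_model`
#' @param mode `"tracking"` (marker + contact tracking subterms active,
#'   fixed final time) or `"predictive"`
#' @param weights an [cost_weights()] object
#' @param constraints list of [constraint_spec()] objects
#' @param mesh_intervals number of mesh intervals (>= 2); collocation uses
#'   2 * mesh_intervals + 1 points (mesh nodes plus interval midpoints)
#' @param ref an `fns_reference` (required in tracking mode)
#' @param markers optional marker set override
#' @param t_f final time: a single number fixes it; otherwise supply a
#'   `tf_bound` constraint to make it a bounded decision variable
#' @param endpoint_conditions optional list with named numeric vectors
#'   `initial` and/or `final` pinning state values (used by simple
#'   fixtures; gait problems instead use rest/symmetry constraints)
#' @param guess optional `fns_trajectory` initial guess; the default is
#'   the midpoint of the variable bounds
#' @param options list; recognized entries include `acc_bound_rot`,
#'   `acc_bound_trans` (implicit acceleration bounds, default 400 rad/s^2
#'   and 60 m/s^2), `exc_min` (0.01), `feas_tol` (1e-6), `opt_tol`
#'   (1e-4), `max_outer`, `max_inner`, `knee_threshold` (0.05 body
#'   weight)
#' @return object of class `fns_ocp`
#' @export
oc_problem <- function(model, mode = c("tracking", "predictive"),
                       weights = cost_weights(), constraints = list(),
                       mesh_intervals = 10, ref = NULL, markers = NULL,
                       t_f = NULL, endpoint_conditions = NULL,
                       guess = NULL, options = list()) {
  mode <- match.arg(mode)
  if (mesh_intervals < 2) stop("mesh_intervals must be >= 2")
  if (mode == "tracking" && is.null(ref)) {
    stop("tracking mode requires reference data")
  }
  kinds <- vapply(constraints, `[[`, "", "kind")
  tfb <- constraints[kinds == "tf_bound"]
  if (length(tfb) > 0L) {
    t_f <- list(bounds = tfb[[1]]$bounds)
  } else if (is.numeric(t_f)) {
    t_f <- list(fixed = t_f)
  } else if (is.null(t_f)) {
    stop("supply t_f or a tf_bound constraint")
  }
  structure(list(model = model, mode = mode, weights = weights,
                 constraints = constraints, mesh_intervals = mesh_intervals,
                 ref = ref, markers = markers, t_f = t_f,
                 endpoint_conditions = endpoint_conditions,
                 guess = guess, options = options),
            class = "fns_ocp")
}

#' Coordinate speed ranges from reference inverse kinematics
#'
#' Differentiates the joint-angle table of a reference data set and
#' returns the per-coordinate speed range, used to build the speed-bound
#' constraint.
#'
#' @param ref an `fns_reference` with an `ik` table (`time` + coordinate
#'   columns)
#' @param coords coordinate names to report (defaults to all columns)
#' @return data.frame with `name`, `lo`, `hi`
#' @export
nt_speed_ranges <- function(ref, coords = NULL) {
  ik <- ref$ik
  if (is.null(ik)) stop("reference data has no ik table")
  cn <- setdiff(colnames(ik), "time")
  out <- data.frame(name = cn, lo = NA_real_, hi = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cn)) {
    v <- grad_time(ik$time, ik[[cn[i]]])
    out$lo[i] <- min(v)
    out$hi[i] <- max(v)
  }
  if (!is.null(coords)) {
    miss <- setdiff(coords, out$name)
    if (length(miss)) {
      # coordinates absent from the reference keep generous defaults
      out <- rbind(out, data.frame(name = miss, lo = -10, hi = 10))
    }
    out <- out[match(coords, out$name), ]
  }
  out
}

ocp_default_options <- function() {
  list(acc_bound_rot = 400, acc_bound_trans = 60, exc_min = 0.01,
       feas_tol = 1e-6, opt_tol = 1e-4, max_outer = 20, max_inner = 60,
       knee_threshold = 0.05, knee_refresh_outers = 6, rho0 = 10,
       verbose = FALSE,
       min_distance = 0.05, ft_max = 2.5, dft_max = 30,
       max_step = 2)
}

#' Transcribe an optimal-control problem into a nonlinear program
#'
#' Builds the decision vector layout, bounds, residual evaluators
#' (cost rows as a least-squares stack, equality and inequality
#' constraints), the sparsity pattern and a finite-difference coloring.
#'
#' @param problem an `fns_ocp`
#' @return object of class `fns_nlp`; fields include `n_decision`,
#'   `var_names`, `lb`, `ub`, `eval_raw` (residual stack), and
#'   `build_trajectory`
#' @export
transcribe <- function(problem) {
  model <- problem$model
  opts <- modifyList(ocp_default_options(), problem$options)
  cm <- model$compiled
  nq <- n_coord(model)
  nmus <- n_muscle(model)
  nres <- n_reserve(model)
  compliant <- !model$rigid_tendon && nmus > 0L
  nx <- 2L * nq + nmus + if (compliant) nmus else 0L
  nu <- nmus + nres + nq + if (compliant) nmus else 0L
  b <- nx + nu
  N <- problem$mesh_intervals
  P <- 2L * N + 1L

  # state/control row indices within a point block
  iq <- 1:nq
  iu <- nq + 1:nq
  ia <- if (nmus > 0L) 2L * nq + 1:nmus else integer()
  ift <- if (compliant) 2L * nq + nmus + 1:nmus else integer()
  je <- if (nmus > 0L) 1:nmus else integer()
  jr <- if (nres > 0L) nmus + 1:nres else integer()
  jacc <- nmus + nres + 1:nq
  jdft <- if (compliant) nmus + nres + nq + 1:nmus else integer()

  kinds <- vapply(problem$constraints, `[[`, "", "kind")
  getcon <- function(k) {
    i <- which(kinds == k)
    if (length(i)) problem$constraints[[i[1]]] else NULL
  }

  # ----- bounds ------------------------------------------------------------
  crd <- model$coordinates
  sb <- getcon("speed_bound")
  if (!is.null(sb)) {
    ranges <- sb$ranges
    if (is.null(ranges) && !is.null(problem$ref$ik)) {
      ranges <- nt_speed_ranges(problem$ref, crd$name)
    }
    if (is.null(ranges)) {
      ranges <- data.frame(name = crd$name, lo = crd$speed_lo,
                           hi = crd$speed_hi)
    }
    bnd <- speed_bounds(ranges, sb$percent)
    bnd <- bnd[match(crd$name, bnd$name), ]
    # the speed bound concerns joint coordinates; the floating-base
    # coordinates (pelvis-to-ground) keep their model speed ranges
    joint <- crd$type == "revolute"
    u_lo <- ifelse(joint, bnd$lo, crd$speed_lo)
    u_hi <- ifelse(joint, bnd$hi, crd$speed_hi)
  } else {
    u_lo <- crd$speed_lo
    u_hi <- crd$speed_hi
  }
  acc_bnd <- ifelse(grepl("_t[xy]$", crd$name), opts$acc_bound_trans,
                    opts$acc_bound_rot)
  # activations floored slightly below the excitation floor: equilibrium
  # activations never fall below the excitation bound, and a strictly
  # positive floor keeps the variables out of the reparameterization tails
  x_lo <- c(crd$lo, u_lo, rep(opts$exc_min / 2, nmus),
            rep(0, length(ift)))
  x_hi <- c(crd$hi, u_hi, rep(1, nmus), rep(opts$ft_max, length(ift)))
  u_lo_c <- c(rep(opts$exc_min, nmus), rep(-1, nres), -acc_bnd,
              rep(-opts$dft_max, length(jdft)))
  u_hi_c <- c(rep(1, nmus), rep(1, nres), acc_bnd,
              rep(opts$dft_max, length(jdft)))
  lb_pt <- c(x_lo, u_lo_c)
  ub_pt <- c(x_hi, u_hi_c)
  tf_free <- is.null(problem$t_f$fixed)
  # leg-clearance inequalities become equalities with bounded slack
  # variables (smooth rows suit the least-squares machinery better than
  # hinge penalties)
  inter <- getcon("intersect")
  n_pairs <- if (!is.null(inter)) nrow(clearance_points(model)$pairs)
             else 0L
  n_slack <- n_pairs * P
  nvar <- P * b + as.integer(tf_free) + n_slack
  lb <- c(rep(lb_pt, P), if (tf_free) problem$t_f$bounds[1],
          rep(0, n_slack))
  ub <- c(rep(ub_pt, P), if (tf_free) problem$t_f$bounds[2],
          rep(0.6, n_slack))
  if (any(lb > ub)) stop("inconsistent bounds (lower > upper)")
  span <- ub - lb
  if (any(span <= 0)) stop("degenerate variable bounds")

  state_names <- c(paste0("q_", crd$name), paste0("u_", crd$name),
                   if (nmus > 0L) paste0("act_", model$muscles$name),
                   if (compliant) paste0("ft_", model$muscles$name))
  ctrl_names <- c(if (nmus > 0L) paste0("exc_", model$muscles$name),
                  if (nres > 0L) paste0("res_", model$reserves$name),
                  paste0("acc_", crd$name),
                  if (compliant) paste0("dft_", model$muscles$name))
  var_names <- c(paste0(rep(c(state_names, ctrl_names), P), "@",
                        rep(seq_len(P), each = b)),
                 if (tf_free) "t_f",
                 if (n_slack) paste0("s_clear", seq_len(n_slack)))

  # ----- quadrature and mesh ----------------------------------------------
  tau <- seq(0, 1, length.out = P)
  simp_pat <- rep(c(2, 4), length.out = P)
  simp_pat[c(1, P)] <- 1
  # integral over [0, tf]: weights = simp_pat * (tf / N) / 6 since the
  # sub-step is tf / (2 N)
  qw_unit <- simp_pat / (6 * N)
  I0 <- seq(1L, P - 2L, by = 2L)
  IM <- I0 + 1L
  I1 <- I0 + 2L

  # characteristic force scale for the dynamics rows (body weight, with a
  # floor so zero-gravity toy fixtures stay well scaled)
  mg <- model$total_mass * max(model$gravity, 1)
  sx <- pmax(x_hi - x_lo, 1e-2)

  # ----- tracking references on the mesh ----------------------------------
  track <- problem$mode == "tracking"
  if (track && tf_free) {
    stop("tracking mode requires a fixed final time")
  }
  mkset <- NULL
  ref_mark <- NULL
  ref_foot <- NULL
  mark_segs <- NULL
  mark_off <- NULL
  if (track) {
    tf0 <- problem$t_f$fixed
    tgrid <- tau * tf0
    ref <- problem$ref
    mkset <- marker_set(problem$markers %||% model$markers)
    miss <- setdiff(mkset$name, names(ref$markers))
    if (length(miss)) {
      stop("markers absent from reference data: ",
           paste(miss, collapse = ", "))
    }
    ref_mark <- matrix(NA_real_, 2L * nrow(mkset), P)
    for (i in seq_len(nrow(mkset))) {
      rm <- ref$markers[[mkset$name[i]]]
      ref_mark[2 * i - 1, ] <- approx(ref$marker_time, rm[, 1],
                                      xout = tgrid, rule = 2)$y
      ref_mark[2 * i, ] <- approx(ref$marker_time, rm[, 2],
                                  xout = tgrid, rule = 2)$y
    }
    ref_foot <- matrix(NA_real_, 4L, P)
    k <- 1L
    for (side in c("left", "right")) {
      rf <- ref$forces[[side]]
      ref_foot[k, ] <- approx(ref$force_time, rf[, 1], xout = tgrid,
                              rule = 2)$y
      ref_foot[k + 1, ] <- approx(ref$force_time, rf[, 2], xout = tgrid,
                                  rule = 2)$y
      k <- k + 2L
    }
    seg_idx <- setNames(seq_len(nrow(model$segments)) - 1L,
                        model$segments$name)
    mark_segs <- as.integer(seg_idx[mkset$segment])
    mark_off <- rbind(mkset$x, mkset$y)
  }

  # ----- constraint bookkeeping -------------------------------------------
  sym <- getcon("sym_half") %||% getcon("sym_full")
  sym_mode <- if (!is.null(sym)) {
    if (sym$kind == "sym_half") "half" else "full"
  } else NULL
  sym_idx <- NULL
  if (!is.null(sym)) {
    base_tx <- paste0("q_", model$segments$name[1], "_tx")
    sex <- sym$state_exemptions %||% base_tx
    if (sym_mode == "half") {
      mm <- mirror_map(model)
      sperm <- c(mm$coord, nq + mm$coord,
                 if (nmus > 0L) 2L * nq + mm$muscle,
                 if (compliant) 2L * nq + nmus + mm$muscle)
      cperm <- c(if (nmus > 0L) mm$muscle,
                 if (nres > 0L) nmus + mm$reserve,
                 nmus + nres + mm$coord,
                 if (compliant) nmus + nres + nq + mm$muscle)
      cex <- sym$control_exemptions %||%
        (if (nres > 0L) paste0("res_", model$reserves$name) else
           character())
    } else {
      sperm <- seq_len(nx)
      cperm <- seq_len(nu)
      cex <- sym$control_exemptions %||% character()
    }
    skeep <- which(!(state_names %in% sex))
    ckeep <- which(!(ctrl_names %in% cex) &
                     !grepl("^acc_", ctrl_names) &
                     !grepl("^dft_", ctrl_names))
    sym_idx <- list(sperm = sperm, cperm = cperm, skeep = skeep,
                    ckeep = ckeep)
  }
  avg <- getcon("avg_speed")
  rest <- !is.null(getcon("rest"))
  knees_con <- getcon("knees")
  cp <- if (!is.null(inter)) clearance_points(model) else NULL
  cp_segidx <- if (!is.null(cp)) {
    seg_idx <- setNames(seq_len(nrow(model$segments)) - 1L,
                        model$segments$name)
    as.integer(seg_idx[cp$segments])
  } else NULL
  ep <- problem$endpoint_conditions
  knee_cols <- match(c("q_shank_l_q", "q_shank_r_q"), state_names)
  knee_cols <- knee_cols[!is.na(knee_cols)]

  wts <- problem$weights
  eff_w <- c(rep(1, nmus), rep(wts$reserve_weight, nres))
  syn_pairs <- NULL
  if (nmus > 0L) {
    prs <- list()
    for (g in unique(model$muscles$group)) {
      idx <- which(model$muscles$group == g)
      if (length(idx) >= 2L) prs[[length(prs) + 1L]] <- idx[c(1, 2)]
      if (length(idx) == 3L) prs[[length(prs) + 1L]] <- idx[c(1, 3)]
    }
    if (length(prs)) syn_pairs <- do.call(rbind, prs)
  }
  jp_rows <- if (nmus > 0L) {
    which(grepl("^(rect_abd|ext_obl)", model$muscles$name))
  } else integer()

  env <- environment()

  # knee events (knee state row, node), updated between outer iterations
  # (frozen during the inner least-squares solve)
  knee_events <- matrix(integer(), 0, 2)

  unscale <- function(z) {
    lb + span * sigmoid(z)
  }
  scale_to_z <- function(x) {
    p <- pmin(pmax((x - lb) / span, 0.005), 0.995)
    logit(p)
  }

  # setup block consumed by the compiled residual evaluator; row ordering
  # must stay in step with row_points() below
  su <- list(
    nq = nq, nmus = nmus, nres = nres, nx = nx, nu = nu, b = b, P = P,
    N = N, tf_free = tf_free,
    tf_fixed = if (tf_free) 0 else problem$t_f$fixed,
    track = track, predictive = problem$mode == "predictive",
    compliant = compliant,
    has_sym = !is.null(sym_idx), has_rest = rest,
    has_avg = !is.null(avg), has_inter = !is.null(inter),
    has_knees = !is.null(knees_con),
    wad_on = wts$w_ad > 0,
    mg = mg, sx = sx, qw_pat = qw_unit,
    min_distance = opts$min_distance,
    avg_target = if (!is.null(avg)) avg$target else 0,
    mark_segs = mark_segs, mark_off = mark_off,
    ref_mark = ref_mark, ref_foot = ref_foot,
    mark_w = if (track) sqrt(wts$w_mt * rep(mkset$weight, each = 2)),
    foot_scale = if (track) sqrt(wts$w_ct / mg) else 0,
    syn_a = if (!is.null(syn_pairs)) as.integer(syn_pairs[, 1] - 1L)
            else integer(),
    syn_b = if (!is.null(syn_pairs)) as.integer(syn_pairs[, 2] - 1L)
            else integer(),
    sqrt_ws = sqrt(wts$w_s),
    eff_w_sqrt = sqrt(wts$w_e * eff_w),
    jp_rows = as.integer(jp_rows - 1L),
    jp_scale = sqrt(10 * wts$w_p),
    sqrt_wad = sqrt(wts$w_ad),
    sperm = if (!is.null(sym_idx)) as.integer(sym_idx$sperm - 1L)
            else integer(),
    cperm = if (!is.null(sym_idx)) as.integer(sym_idx$cperm - 1L)
            else integer(),
    skeep = if (!is.null(sym_idx)) as.integer(sym_idx$skeep - 1L)
            else integer(),
    ckeep = if (!is.null(sym_idx)) as.integer(sym_idx$ckeep - 1L)
            else integer(),
    ep_init_idx = if (!is.null(ep$initial)) {
      as.integer(match(names(ep$initial), state_names) - 1L)
    } else integer(),
    ep_init_val = as.numeric(ep$initial %||% numeric()),
    ep_final_idx = if (!is.null(ep$final)) {
      as.integer(match(names(ep$final), state_names) - 1L)
    } else integer(),
    ep_final_val = as.numeric(ep$final %||% numeric()),
    cp_segs = cp_segidx, cp_off = if (!is.null(cp)) cp$offsets,
    cp_pairs = if (!is.null(cp)) t(cp$pairs - 1L),
    inter_min_gap = if (!is.null(inter)) inter$min_gap %||% 0.05 else 0,
    slack_off = P * b + as.integer(tf_free),
    knee_cols = as.integer(knee_cols - 1L),
    knee_tol = if (!is.null(knees_con)) {
      knees_con$tolerance %||% (pi / 180)
    } else 0
  )

  n_cost_fixed <- (if (track) (2L * nrow(mkset) + 4L) * P else 0L) +
    (if (!is.null(syn_pairs)) nrow(syn_pairs) * P else 0L) +
    (if (nmus + nres > 0L) (nmus + nres) * P else 0L) +
    length(jp_rows) * P +
    (if (compliant && wts$w_ad > 0) nmus * P else 0L)
  n_eq_fixed <- 2L * nx * N + nq * P +
    (if (compliant) nmus * P else 0L) +
    (if (!is.null(sym_idx)) {
      length(sym_idx$skeep) + length(sym_idx$ckeep)
    } else 0L) +
    (if (rest) nq else 0L) +
    (if (!is.null(avg)) 1L else 0L) +
    length(ep$initial) + length(ep$final)

  eval_vec <- function(z) {
    as.numeric(cpp_nlp_eval(cm, su, unscale(z), knee_events - 1L))
  }
  eval_raw <- function(z) {
    r <- eval_vec(z)
    n_in <- length(r) - n_cost_fixed - n_eq_fixed - n_slack
    list(cost = r[seq_len(n_cost_fixed)],
         eq = r[n_cost_fixed + seq_len(n_eq_fixed)],
         clearance = if (n_slack > 0L) {
           r[n_cost_fixed + n_eq_fixed + seq_len(n_slack)]
         } else numeric(),
         ineq = if (n_in > 0L) {
           r[n_cost_fixed + n_eq_fixed + n_slack + seq_len(n_in)]
         } else numeric())
  }

  eval_raw_slow <- function(z) {
    x <- unscale(z)
    V <- matrix(x[seq_len(P * b)], b, P)
    X <- V[seq_len(nx), , drop = FALSE]
    U <- V[nx + seq_len(nu), , drop = FALSE]
    tf <- if (tf_free) x[P * b + 1L] else problem$t_f$fixed
    slacks <- if (n_slack) {
      x[P * b + as.integer(tf_free) + seq_len(n_slack)]
    } else numeric()
    h <- tf / N
    Q <- X[iq, , drop = FALSE]
    Uq <- X[iu, , drop = FALSE]
    ACT <- if (nmus > 0L) X[ia, , drop = FALSE] else matrix(0, 0, P)
    FT <- if (compliant) X[ift, , drop = FALSE] else matrix(0, nmus, P)
    EXC <- if (nmus > 0L) U[je, , drop = FALSE] else matrix(0, 0, P)
    RES <- if (nres > 0L) U[jr, , drop = FALSE] else matrix(0, 0, P)
    ACC <- U[jacc, , drop = FALSE]
    DFT <- if (compliant) U[jdft, , drop = FALSE] else NULL

    # state derivative stack f
    ARATE <- if (nmus > 0L) {
      matrix(cpp_activation_rate(as.numeric(EXC), as.numeric(ACT),
                                 rep(cm$mus_tact, P),
                                 rep(cm$mus_tdeact, P)), nmus, P)
    } else matrix(0, 0, P)
    F <- rbind(Uq, ACC, ARATE, if (compliant) DFT)

    # Hermite-Simpson defects (scaled by the state spans)
    DH <- (X[, IM, drop = FALSE] -
             0.5 * (X[, I0, drop = FALSE] + X[, I1, drop = FALSE]) -
             (h / 8) * (F[, I0, drop = FALSE] - F[, I1, drop = FALSE])) / sx
    DS <- (X[, I1, drop = FALSE] - X[, I0, drop = FALSE] -
             (h / 6) * (F[, I0, drop = FALSE] +
                          4 * F[, IM, drop = FALSE] +
                          F[, I1, drop = FALSE])) / sx

    # dynamics path residual at every collocation point
    dyn <- cpp_dyn_residual_batch(cm, Q, Uq, ACC, ACT, RES, FT) / mg
    eqs <- c(as.numeric(DH), as.numeric(DS), as.numeric(dyn))
    if (compliant) {
      ten <- cpp_tendon_equilibrium_batch(cm, Q, Uq, ACT, FT, DFT)
      eqs <- c(eqs, as.numeric(ten))
    }

    need_com <- !is.null(avg) || problem$mode == "predictive"
    com <- if (need_com) {
      cpp_com_batch(cm, Q[, c(1L, P), drop = FALSE],
                    Uq[, c(1L, P), drop = FALSE])
    } else NULL

    if (!is.null(sym_idx)) {
      xs <- X[, 1L]
      x0m <- xs
      x0m[seq_len(nx)] <- xs[sym_idx$sperm]
      cs <- U[, 1L]
      c0m <- cs
      c0m[seq_len(nu)] <- cs[sym_idx$cperm]
      eqs <- c(eqs,
               ((X[, P] - x0m) / sx)[sym_idx$skeep],
               (U[, P] - c0m)[sym_idx$ckeep])
    }
    if (rest) eqs <- c(eqs, Uq[, 1L])
    if (!is.null(avg)) {
      eqs <- c(eqs, (com[1, 2] - com[1, 1]) / tf - avg$target)
    }
    if (!is.null(ep)) {
      if (!is.null(ep$initial)) {
        idx <- match(names(ep$initial), state_names)
        eqs <- c(eqs, (X[idx, 1L] - ep$initial) / sx[idx])
      }
      if (!is.null(ep$final)) {
        idx <- match(names(ep$final), state_names)
        eqs <- c(eqs, (X[idx, P] - ep$final) / sx[idx])
      }
    }

    ineqs <- numeric()
    if (!is.null(inter)) {
      pos <- cpp_point_positions(cm, Q, cp_segidx, cp$offsets)
      min_gap <- inter$min_gap %||% 0.05
      srow <- 0L
      for (k in seq_len(nrow(cp$pairs))) {
        i <- cp$pairs[k, 1]; j <- cp$pairs[k, 2]
        gap <- sqrt((pos[2 * i - 1, ] - pos[2 * j - 1, ])^2 +
                      (pos[2 * i, ] - pos[2 * j, ])^2 + 1e-12)
        ineqs <- c(ineqs, gap - min_gap - slacks[srow + seq_len(P)])
        srow <- srow + P
      }
    }
    if (!is.null(knees_con) && nrow(knee_events)) {
      tol <- knees_con$tolerance %||% (pi / 180)
      for (k in seq_len(nrow(knee_events))) {
        ang <- X[knee_events[k, 1], knee_events[k, 2]]
        ineqs <- c(ineqs, tol - ang, ang + tol)
      }
    }

    # ----- cost rows (least-squares stack) --------------------------------
    qw <- qw_unit * tf
    sqw <- sqrt(qw)
    cost <- numeric()
    if (track) {
      pos <- cpp_point_positions(cm, Q, mark_segs, mark_off)
      wm <- sqrt(wts$w_mt * rep(mkset$weight, each = 2))
      cost <- c(cost,
                as.numeric((pos - ref_mark) * wm *
                             rep(sqw, each = nrow(pos))))
      Fm <- cpp_foot_forces_batch(cm, Q, Uq)
      cost <- c(cost, as.numeric((Fm - ref_foot) *
                                   sqrt(wts$w_ct / mg) *
                                   rep(sqw, each = 4L)))
    }
    if (!is.null(syn_pairs)) {
      D <- EXC[syn_pairs[, 1], , drop = FALSE] -
        EXC[syn_pairs[, 2], , drop = FALSE]
      cost <- c(cost, as.numeric(D * sqrt(wts$w_s) *
                                   rep(sqw, each = nrow(D))))
    }
    CTL <- rbind(EXC, RES)
    if (nrow(CTL) > 0L) {
      eff <- sqrt(wts$w_e * eff_w)
      if (problem$mode == "predictive") {
        d <- max(abs(com[1, 2] - com[1, 1]), opts$min_distance)
        eff <- eff / sqrt(d)
      }
      cost <- c(cost, as.numeric(CTL * eff * rep(sqw, each = nrow(CTL))))
    }
    if (length(jp_rows)) {
      cost <- c(cost, as.numeric(EXC[jp_rows, , drop = FALSE] *
                                   sqrt(10 * wts$w_p) *
                                   rep(sqw, each = length(jp_rows))))
    }
    if (compliant && wts$w_ad > 0) {
      cost <- c(cost, as.numeric(DFT * cm$mus_fmax * sqrt(wts$w_ad) *
                                   rep(sqw, each = nmus)))
    }
    list(cost = cost, eq = eqs, ineq = ineqs)
  }

  # ----- sparsity pattern and coloring ------------------------------------
  # rows -> supporting collocation points; columns grouped by
  # (variable-within-point, point class); t_f is its own color
  r0 <- eval_raw(rep(0, nvar))
  n_cost <- length(r0$cost)
  n_eq <- length(r0$eq)
  n_ineq <- length(r0$ineq)

  row_columns <- function() {
    # exact column support (global decision-variable indices) per residual
    # row, in the order emitted by the evaluator; drives the
    # finite-difference coloring and the Jacobian sparsity
    tfc <- if (tf_free) P * b + 1L else integer()
    vid <- function(slots, p) {
      as.integer(outer((p - 1L) * b, slots, `+`))
    }
    rc <- vector("list", 0L)
    add <- function(x) {
      rc[[length(rc) + 1L]] <<- as.integer(x)
    }
    sl_exc <- nx + je
    sl_res <- nx + jr
    sl_acc <- nx + jacc
    sl_dft <- nx + jdft
    if (track) {
      for (p in seq_len(P)) {
        for (r in seq_len(2L * nrow(mkset))) add(vid(iq, p))
      }
      for (p in seq_len(P)) {
        for (r in 1:4) add(vid(c(iq, iu), p))
      }
    }
    if (!is.null(syn_pairs)) {
      for (p in seq_len(P)) {
        for (k in seq_len(nrow(syn_pairs))) {
          add(c(vid(sl_exc[syn_pairs[k, ]], p), tfc))
        }
      }
    }
    nctl <- nmus + nres
    if (nctl > 0L) {
      dcols <- if (problem$mode == "predictive") {
        c(vid(iq, 1L), vid(iq, P))
      } else integer()
      for (p in seq_len(P)) {
        for (cch in seq_len(nctl)) {
          add(c(vid(nx + cch, p), dcols, tfc))
        }
      }
    }
    if (length(jp_rows)) {
      for (p in seq_len(P)) {
        for (mrow in jp_rows) add(c(vid(sl_exc[mrow], p), tfc))
      }
    }
    if (compliant && wts$w_ad > 0) {
      for (p in seq_len(P)) {
        for (mrow in seq_len(nmus)) add(c(vid(sl_dft[mrow], p), tfc))
      }
    }
    # defect rows: the row for state s couples x_s and the inputs of its
    # derivative f_s at the three points of the interval
    fdep <- function(s) {
      if (s <= nq) return(iu[s])
      if (s <= 2L * nq) return(sl_acc[s - nq])
      if (s <= 2L * nq + nmus) {
        mrow <- s - 2L * nq
        return(c(ia[mrow], sl_exc[mrow]))
      }
      mrow <- s - 2L * nq - nmus
      sl_dft[mrow]
    }
    for (blk in 1:2) {
      for (i in seq_len(N)) {
        trip <- c(2L * i - 1L, 2L * i, 2L * i + 1L)
        for (s in seq_len(nx)) {
          slots <- c(s, fdep(s))
          add(c(vid(slots, trip[1]), vid(slots, trip[2]),
                vid(slots, trip[3]), tfc))
        }
      }
    }
    # dynamics rows: all states, reserves and accelerations at the point
    # (excitations enter only through activation dynamics)
    dyn_slots <- c(iq, iu, ia, ift, sl_res, sl_acc)
    for (p in seq_len(P)) {
      for (s in seq_len(nq)) add(vid(dyn_slots, p))
    }
    if (compliant) {
      for (p in seq_len(P)) {
        for (mrow in seq_len(nmus)) {
          add(vid(c(iq, iu, ia[mrow], ift[mrow], sl_dft[mrow]), p))
        }
      }
    }
    if (!is.null(sym_idx)) {
      for (s in sym_idx$skeep) {
        add(c(vid(s, P), vid(sym_idx$sperm[s], 1L)))
      }
      for (cch in sym_idx$ckeep) {
        add(c(vid(nx + cch, P), vid(nx + sym_idx$cperm[cch], 1L)))
      }
    }
    if (rest) for (s in seq_len(nq)) add(vid(iu[s], 1L))
    if (!is.null(avg)) add(c(vid(iq, 1L), vid(iq, P), tfc))
    if (!is.null(ep)) {
      for (nm in names(ep$initial)) {
        add(vid(match(nm, state_names), 1L))
      }
      for (nm in names(ep$final)) {
        add(vid(match(nm, state_names), P))
      }
    }
    if (!is.null(inter)) {
      soff <- P * b + as.integer(tf_free)
      srow <- 0L
      for (k in seq_len(nrow(cp$pairs))) {
        for (p in seq_len(P)) {
          srow <- srow + 1L
          add(c(vid(iq, p), soff + srow))
        }
      }
    }
    if (!is.null(knees_con) && nrow(knee_events)) {
      for (k in seq_len(nrow(knee_events))) {
        add(vid(knee_events[k, 1], knee_events[k, 2]))
        add(vid(knee_events[k, 1], knee_events[k, 2]))
      }
    }
    rc
  }

  nlp <- list(
    problem = problem, options = opts,
    n_decision = nvar, n_states = nx, n_controls = nu, n_points = P,
    var_names = var_names, lb = lb, ub = ub, tf_free = tf_free,
    state_names = state_names, ctrl_names = ctrl_names,
    n_cost = n_cost, n_eq = n_eq, n_ineq = n_ineq,
    n_slack = n_slack,
    eval_raw = eval_raw, eval_vec = eval_vec,
    eval_raw_reference = eval_raw_slow,
    unscale = unscale, scale_to_z = scale_to_z,
    row_columns = row_columns,
    b = b, P = P, nx = nx, nu = nu, nq = nq, nmus = nmus, nres = nres,
    compliant = compliant,
    set_knee_events = function(events) {
      ev <- matrix(as.integer(events), ncol = 2)
      assign("knee_events", ev, envir = env)
    },
    get_knee_events = function() knee_events,
    knee_state_cols = knee_cols,
    tau = tau
  )
  nlp$build_trajectory <- function(z) {
    x <- unscale(z)
    V <- matrix(x[seq_len(P * b)], b, P)
    tf <- if (tf_free) x[P * b + 1L] else problem$t_f$fixed
    states <- t(V[seq_len(nx), , drop = FALSE])
    controls <- t(V[nx + seq_len(nu), , drop = FALSE])
    colnames(states) <- state_names
    colnames(controls) <- ctrl_names
    trajectory(tau * tf, states, controls, model)
  }
  nlp$guess_z <- function(traj = NULL) {
    if (is.null(traj)) return(rep(0, nvar))
    told <- traj$time
    tau_old <- (told - told[1]) / (told[length(told)] - told[1])
    S <- interp_cols(tau_old, traj$states, tau)
    Ctl <- interp_cols(tau_old, traj$controls, tau)
    V <- matrix(NA_real_, b, P)
    for (s in seq_len(nx)) {
      V[s, ] <- if (state_names[s] %in% colnames(S)) {
        S[, state_names[s]]
      } else (lb_pt[s] + ub_pt[s]) / 2
    }
    for (s in seq_len(nu)) {
      nm <- ctrl_names[s]
      V[nx + s, ] <- if (nm %in% colnames(Ctl)) {
        Ctl[, nm]
      } else if (grepl("^acc_", nm)) {
        cn <- sub("^acc_", "u_", nm)
        tf_old <- told[length(told)] - told[1]
        grad_time(tau * max(tf_old, 1e-6), S[, cn])
      } else (lb_pt[nx + s] + ub_pt[nx + s]) / 2
    }
    xg <- as.numeric(V)
    if (tf_free) {
      tfg <- min(max(told[length(told)] - told[1],
                     problem$t_f$bounds[1]), problem$t_f$bounds[2])
      xg <- c(xg, tfg)
    }
    if (n_slack) {
      pos <- model_point_positions(model, V[iq, , drop = FALSE],
                                   cp$segments, cp$offsets)
      mgap <- inter$min_gap %||% 0.05
      sg <- numeric()
      for (k in seq_len(nrow(cp$pairs))) {
        i2 <- cp$pairs[k, 1]
        j2 <- cp$pairs[k, 2]
        gap <- sqrt((pos[2 * i2 - 1, ] - pos[2 * j2 - 1, ])^2 +
                      (pos[2 * i2, ] - pos[2 * j2, ])^2 + 1e-12)
        sg <- c(sg, gap - mgap)
      }
      xg <- c(xg, pmin(pmax(sg, 0.005), 0.55))
    }
    scale_to_z(xg)
  }
  class(nlp) <- "fns_nlp"
  nlp
}

#' @export
print.fns_nlp <- function(x, ...) {
  cat("<fns_nlp>", x$n_decision, "decision variables;",
      x$P, "collocation points;", x$n_cost, "cost rows,", x$n_eq,
      "equality and", x$n_ineq, "inequality residuals\n")
  invisible(x)
}
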