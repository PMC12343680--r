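# Staged solution cascade: a tracking problem seeds a series of
# progressively edited predictive problems, each warm-started from its
# predecessor's solution.

#' Cascade stage definition
#'
#' @param name stage label
#' @param mode `"tracking"` or `"predictive"`
#' @param mesh mesh intervals
#' @param muscle_set `"model_g"`, `"symmetric"` or `"model_p"`
#' @param sym `"half"` or `"full"` stride symmetry
#' @param speed_percent fraction of the neurotypical speed range allowed
#' @param avg_speed target CoM speed (m/s) or `NULL`
#' @param tf fixed final time (single number) or bounds (length 2)
#' @param intersect,knees,rest logicals enabling those constraints
#' @param reserve_weight effort-weight multiplier for reserve channels
#' @return stage spec list
#' @export
cascade_stage <- function(name, mode, mesh, muscle_set = "model_g",
                          sym = "half", speed_percent = 1,
                          avg_speed = NULL, tf = NULL, intersect = FALSE,
                          knees = FALSE, rest = FALSE,
                          reserve_weight = 10) {
  list(name = name, mode = mode, mesh = mesh, muscle_set = muscle_set,
       sym = sym, speed_percent = speed_percent, avg_speed = avg_speed,
       tf = tf, intersect = intersect, knees = knees, rest = rest,
       reserve_weight = reserve_weight)
}

#' Default staged-optimization configuration
#'
#' The full cascade: a tracking problem at 10 then 50 mesh intervals
#' (half-stride symmetry, joint speeds limited to 10% of the neurotypical
#' reference range), followed by six predictive refinements: Predict1
#' drops the tracking subterms, adds leg-clearance, initial-rest and
#' average-speed (0.4 m/s) constraints with the final time bounded in
#' [0.4, 0.6] s and speed bounds relaxed to 100%; Predict2 adds the
#' straight-knee double-stance constraint; Predict3 reduces the muscles to
#' the symmetric iliopsoas/vasti/tibialis-anterior set, lowers the target
#' speed to 0.1 m/s with final time in [0.9, 1.1] s; Predict4 raises the
#' reserve-actuator effort penalty; Predict5 raises the target speed to
#' 0.2 m/s; Predict6 restores the full asymmetric muscle set, switches to
#' full-stride symmetry and bounds the final time in [2.0, 2.2] s (a
#' complete two-step cycle).
#'
#' @param tracking_tf fixed final time of the tracking stages (s),
#'   normally the reference half-stride duration
#' @param mesh_track,mesh_predict mesh intervals for the refined stages
#' @param predict4_reserve_mult factor applied to the reserve weight at
#'   Predict4 (the magnitude is configuration, not prescribed)
#' @return list of stage specs
#' @export
cascade_config <- function(tracking_tf = 0.5, mesh_track = 50,
                           mesh_predict = 50,
                           predict4_reserve_mult = 10) {
  w0 <- 10
  list(
    cascade_stage("NTtrack10", "tracking", 10, tf = tracking_tf,
                  speed_percent = 0.1),
    cascade_stage("NTtrack50", "tracking", mesh_track, tf = tracking_tf,
                  speed_percent = 0.1),
    cascade_stage("Predict1", "predictive", mesh_predict,
                  speed_percent = 1, avg_speed = 0.4, tf = c(0.4, 0.6),
                  intersect = TRUE, rest = TRUE),
    cascade_stage("Predict2", "predictive", mesh_predict,
                  speed_percent = 1, avg_speed = 0.4, tf = c(0.4, 0.6),
                  intersect = TRUE, rest = TRUE, knees = TRUE),
    cascade_stage("Predict3", "predictive", mesh_predict,
                  muscle_set = "symmetric", speed_percent = 1,
                  avg_speed = 0.1, tf = c(0.9, 1.1), intersect = TRUE,
                  rest = TRUE, knees = TRUE),
    cascade_stage("Predict4", "predictive", mesh_predict,
                  muscle_set = "symmetric", speed_percent = 1,
                  avg_speed = 0.1, tf = c(0.9, 1.1), intersect = TRUE,
                  rest = TRUE, knees = TRUE,
                  reserve_weight = w0 * predict4_reserve_mult),
    cascade_stage("Predict5", "predictive", mesh_predict,
                  muscle_set = "symmetric", speed_percent = 1,
                  avg_speed = 0.2, tf = c(0.9, 1.1), intersect = TRUE,
                  rest = TRUE, knees = TRUE,
                  reserve_weight = w0 * predict4_reserve_mult),
    cascade_stage("Predict6", "predictive", mesh_predict,
                  muscle_set = "model_p", sym = "full",
                  speed_percent = 1, avg_speed = 0.2, tf = c(2.0, 2.2),
                  intersect = TRUE, rest = TRUE, knees = TRUE,
                  reserve_weight = w0 * predict4_reserve_mult)
  )
}

#' Reduced cascade for desk-scale verification
#'
#' Tracking at 10 mesh intervals followed by Predict1 and Predict2, all at
#' 10 mesh intervals.
#' @inheritParams cascade_config
#' @export
reduced_cascade_config <- function(tracking_tf = 0.5) {
  cfg <- cascade_config(tracking_tf = tracking_tf, mesh_track = 10,
                        mesh_predict = 10)
  cfg[c(1, 3, 4)]
}

stage_constraints <- function(stage) {
  cons <- list()
  cons[[length(cons) + 1L]] <-
    constraint_spec(if (stage$sym == "half") "sym_half" else "sym_full")
  cons[[length(cons) + 1L]] <-
    constraint_spec("speed_bound", percent = stage$speed_percent)
  if (!is.null(stage$avg_speed)) {
    cons[[length(cons) + 1L]] <-
      constraint_spec("avg_speed", target = stage$avg_speed)
  }
  if (length(stage$tf) == 2L) {
    cons[[length(cons) + 1L]] <-
      constraint_spec("tf_bound", bounds = stage$tf)
  }
  if (isTRUE(stage$intersect)) {
    # planar projection: contralateral joint centers legitimately close
    # in on each other as the legs cross, so the sagittal gap floor is
    # smaller than the general-purpose 3D default
    cons[[length(cons) + 1L]] <- constraint_spec(
      "intersect", min_gap = stage$min_gap %||% 0.02)
  }
  if (isTRUE(stage$knees)) {
    # the striking (leading) knee straightens at footstrike; the
    # supporting knee flexes through stance in these gaits
    cons[[length(cons) + 1L]] <- constraint_spec("knees",
                                                 both_knees = FALSE)
  }
  if (isTRUE(stage$rest)) {
    cons[[length(cons) + 1L]] <- constraint_spec("rest")
  }
  cons
}

# duplicate a half-stride trajectory into a full-stride guess: the second
# half is the left-right mirror of the first with the forward translation
# advanced
double_stride_guess <- function(traj) {
  model <- traj$model
  mm <- mirror_map(model)
  cn <- coord_names(model)
  n <- length(traj$time)
  S <- traj$states
  Ctl <- traj$controls
  S2 <- S
  qcols <- paste0("q_", cn)
  ucols <- paste0("u_", cn)
  S2[, qcols] <- S[, qcols[mm$coord]]
  S2[, ucols] <- S[, ucols[mm$coord]]
  if (n_muscle(model) > 0L) {
    acols <- paste0("act_", model$muscles$name)
    have <- acols[acols %in% colnames(S)]
    S2[, have] <- S[, paste0("act_", model$muscles$name[mm$muscle])[
      acols %in% colnames(S)]]
  }
  tx <- paste0("q_", model$segments$name[1], "_tx")
  adv <- S[n, tx] - S[1, tx]
  S2[, tx] <- S2[, tx] + adv
  C2 <- Ctl
  if (n_muscle(model) > 0L) {
    ecols <- paste0("exc_", model$muscles$name)
    have <- ecols[ecols %in% colnames(Ctl)]
    C2[, have] <- Ctl[, paste0("exc_", model$muscles$name[mm$muscle])[
      ecols %in% colnames(Ctl)]]
  }
  if (n_reserve(model) > 0L) {
    rcols <- paste0("res_", model$reserves$name)
    have <- rcols[rcols %in% colnames(Ctl)]
    C2[, have] <- Ctl[, paste0("res_", model$reserves$name[mm$reserve])[
      rcols %in% colnames(Ctl)]]
  }
  acc_cols <- grep("^acc_", colnames(Ctl), value = TRUE)
  if (length(acc_cols)) {
    C2[, acc_cols] <- Ctl[, paste0("acc_", cn[mm$coord])]
  }
  tf <- traj$time[n] - traj$time[1]
  time2 <- c(traj$time, traj$time[n] + traj$time[-1] - traj$time[1])
  trajectory(time2, rbind(S, S2[-1, , drop = FALSE]),
             rbind(Ctl, C2[-1, , drop = FALSE]), model)
}

#' Balanced standing trajectory
#'
#' A constant quiet-standing trajectory: all coordinates at the neutral
#' pose with the base height chosen so the total vertical contact force
#' equals body weight, zero speeds and accelerations, excitations at the
#' floor. Used to initialize the first cascade stage.
#'
#' @param model an `msk_model`
#' @param duration trajectory duration, s
#' @param n_points number of nodes
#' @param exc_floor excitation floor
#' @param stagger optional split-stance hip offset (rad): the left hip
#'   flexes and the right extends by this angle, ankles compensating so
#'   both feet stay flat
#' @return an `fns_trajectory`
#' @export
balanced_standing_trajectory <- function(model, duration = 0.5,
                                         n_points = 21, exc_floor = 0.01,
                                         stagger = 0) {
  q0 <- standing_pose(model)
  if (stagger != 0) {
    hips <- intersect(c("thigh_l_q", "thigh_r_q"), names(q0))
    anks <- intersect(c("foot_l_q", "foot_r_q"), names(q0))
    if (length(hips) == 2L && length(anks) == 2L) {
      q0[hips] <- c(stagger, -stagger)
      q0[anks] <- c(-stagger, stagger)  # keep both feet flat
    }
  }
  ty <- paste0(model$segments$name[1], "_ty")
  if (ty %in% names(q0) && !is.null(model$spheres)) {
    bw <- model$total_mass * model$gravity
    f <- function(v) {
      q <- q0
      q[ty] <- v
      Fm <- foot_contact_forces(model, matrix(q, length(q), 1),
                                matrix(0, length(q), 1))
      sum(Fm[c(2, 4), 1]) - bw
    }
    q0[ty] <- stats::uniroot(f, c(q0[ty] - 0.1, q0[ty]))$root
  }
  nq <- n_coord(model)
  nm <- n_muscle(model)
  nr <- n_reserve(model)
  cn <- coord_names(model)
  S <- matrix(rep(c(q0, numeric(nq), rep(exc_floor, nm)),
                  each = n_points), n_points, 2 * nq + nm)
  colnames(S) <- c(paste0("q_", cn), paste0("u_", cn),
                   if (nm > 0L) paste0("act_", model$muscles$name))
  Ctl <- matrix(rep(c(rep(exc_floor, nm), numeric(nr), numeric(nq)),
                    each = n_points), n_points, nm + nr + nq)
  colnames(Ctl) <- c(if (nm > 0L) paste0("exc_", model$muscles$name),
                     if (nr > 0L) paste0("res_", model$reserves$name),
                     paste0("acc_", cn))
  trajectory(seq(0, duration, length.out = n_points), S, Ctl, model)
}

#' Gait-template step guess for the predictive stages
#'
#' Builds a single-step initial trajectory from the reference joint-angle
#' template: a half stride starting at peak leg separation, so the legs
#' exchange roles over the stage (the basin the predictive problems must
#' land in). Speeds and accelerations come from differentiating the
#' template; excitations and activations start at the floor.
#'
#' @param model an `msk_model`
#' @param ref an `fns_reference` carrying an `ik` table (and, if built by
#'   [generate_nt_reference()], its spec)
#' @param duration guess duration, s
#' @param n_points nodes
#' @return an `fns_trajectory`
#' @export
nt_step_guess <- function(model, ref, duration = 0.5, n_points = 21) {
  ik <- ref$ik
  if (is.null(ik)) stop("reference data has no ik table")
  stride <- ref$spec$stride_time %||% (2 * duration)
  t0 <- 0.25 * stride  # peak leg separation in the template
  tt <- t0 + seq(0, duration, length.out = n_points)
  if (max(tt) > max(ik$time)) {
    stop("reference too short for the requested step guess")
  }
  cn <- coord_names(model)
  nq <- length(cn)
  Q <- matrix(0, n_points, nq, dimnames = list(NULL, paste0("q_", cn)))
  for (j in seq_len(nq)) {
    if (cn[j] %in% colnames(ik)) {
      Q[, j] <- approx(ik$time, ik[[cn[j]]], xout = tt)$y
    }
  }
  tx <- paste0("q_", model$segments$name[1], "_tx")
  if (tx %in% colnames(Q)) Q[, tx] <- Q[, tx] - Q[1, tx]
  tau <- tt - tt[1]
  U <- matrix(0, n_points, nq, dimnames = list(NULL, paste0("u_", cn)))
  A <- U
  colnames(A) <- paste0("acc_", cn)
  for (j in seq_len(nq)) {
    U[, j] <- grad_time(tau, Q[, j])
    A[, j] <- grad_time(tau, U[, j])
  }
  nm <- n_muscle(model)
  nr <- n_reserve(model)
  S <- cbind(Q, U,
             matrix(0.01, n_points, nm,
                    dimnames = list(NULL, if (nm > 0L) {
                      paste0("act_", model$muscles$name)
                    })))
  Ctl <- cbind(matrix(0.01, n_points, nm,
                      dimnames = list(NULL, if (nm > 0L) {
                        paste0("exc_", model$muscles$name)
                      })),
               matrix(0, n_points, nr,
                      dimnames = list(NULL, if (nr > 0L) {
                        paste0("res_", model$reserves$name)
                      })),
               A)
  trajectory(tau, S, Ctl, model)
}

#' Run the staged optimization cascade
#'
#' Each stage's solution is the next stage's initial guess (interpolated
#' across mesh changes, channel-matched across muscle-set changes, and
#' mirrored-and-concatenated when moving from half- to full-stride
#' symmetry). The first stage starts from a balanced quiet-standing
#' trajectory. A stage whose final constraint violation exceeds
#' `fail_tol` halts the cascade; earlier solutions are preserved.
#'
#' @param config list of stage specs (see [cascade_config()])
#' @param ref an `fns_reference` for the tracking stages
#' @param weights base [cost_weights()]
#' @param fail_tol constraint-violation level treated as stage failure
#' @param options solver options forwarded to [oc_problem()]
#' @param models optional named list with pre-built `model_p` and
#'   `symmetric` model variants (defaults to [planar_biped()])
#' @param verbose print per-stage progress
#' @return list with `solutions` (named by stage) and `log` (data.frame)
#' @export
run_cascade <- function(config, ref, weights = cost_weights(),
                        fail_tol = 1e-3, options = list(),
                        models = NULL, verbose = FALSE) {
  models <- models %||% list(model_g = planar_biped("model_g"),
                             symmetric = planar_biped("symmetric"),
                             model_p = planar_biped("model_p"))
  options <- modifyList(list(rho0 = 1e4, max_outer = 24,
                             max_inner = 150), options)
  sols <- list()
  log <- NULL
  guess <- NULL
  prev_sym <- NULL
  prev_mode <- NULL
  for (si in seq_along(config)) {
    st <- config[[si]]
    model <- models[[st$muscle_set]]
    w <- weights
    w$reserve_weight <- st$reserve_weight
    tfarg <- if (length(st$tf) == 1L) st$tf else NULL
    prob <- oc_problem(model, mode = st$mode, weights = w,
                       constraints = stage_constraints(st),
                       mesh_intervals = st$mesh,
                       ref = if (st$mode == "tracking") ref else ref,
                       t_f = tfarg, options = options)
    g <- guess
    first_predictive <- st$mode == "predictive" &&
      (is.null(prev_mode) || prev_mode == "tracking")
    if (is.null(g)) {
      g <- balanced_standing_trajectory(
        model, duration = if (length(st$tf) == 1L) st$tf else
          mean(st$tf), stagger = 0.15)
    } else if (!is.null(prev_sym) && prev_sym == "half" &&
               st$sym == "full") {
      g <- double_stride_guess(g)
    }
    if (first_predictive) {
      # the predictive problems are seeded with a gait-template step (the
      # tracked solution under tight speed bounds stays near quiet
      # standing and lies in the wrong basin for a stride)
      g <- nt_step_guess(model, ref,
                         duration = if (length(st$tf) == 2L) {
                           mean(st$tf)
                         } else st$tf)
    }
    if (st$mode == "predictive") {
      # the forward translation is a gauge freedom of the predictive
      # problems; pin its start (and shift the guess accordingly) to
      # remove the null direction
      tx <- paste0("q_", model$segments$name[1], "_tx")
      g$states[, tx] <- g$states[, tx] - g$states[1, tx]
      prob$endpoint_conditions <- list(initial = setNames(0, tx))
    }
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_ocp(prob, guess = g)
    dt <- proc.time()[["elapsed"]] - t0
    edits <- paste0("mode=", st$mode, " mesh=", st$mesh,
                    " muscles=", st$muscle_set, " sym=", st$sym,
                    " speed%=", st$speed_percent,
                    if (!is.null(st$avg_speed)) {
                      paste0(" avg=", st$avg_speed)
                    } else "",
                    " tf=", paste(st$tf, collapse = ":"),
                    if (st$knees) " +knees" else "",
                    if (st$intersect) " +intersect" else "",
                    if (st$rest) " +rest" else "")
    log <- rbind(log, data.frame(
      stage = st$name, status = sol$status,
      objective = sol$objective, max_violation = sol$max_violation,
      initial_infeasibility = sol$infeasibility_history[1],
      iterations = sol$iterations, seconds = dt, edits = edits,
      stringsAsFactors = FALSE))
    if (verbose) {
      message(sprintf("[%s] %s obj=%.4g viol=%.2e (%.1fs)", st$name,
                      sol$status, sol$objective, sol$max_violation, dt))
    }
    sols[[st$name]] <- sol
    if (sol$max_violation > fail_tol) {
      warning("cascade halted at stage ", st$name,
              " (violation ", signif(sol$max_violation, 3), ")")
      break
    }
    guess <- sol$trajectory
    prev_sym <- st$sym
    prev_mode <- st$mode
  }
  list(solutions = sols, log = log)
}
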