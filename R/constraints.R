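# Constraint residual generators for the optimal-control problem: stride
# symmetry, speed bounds, average CoM speed, final-time bounds, leg
# clearance, straight knees at double-stance onset, and initial rest.

#' Declare a constraint
#'
#' @param kind one of `"sym_half"`, `"sym_full"`, `"speed_bound"`,
#'   `"avg_speed"`, `"tf_bound"`, `"intersect"`, `"knees"`, `"rest"`
#' @param ... kind-specific parameters: `percent` (fraction of the
#'   neurotypical speed range, speed_bound), `target` (m/s, avg_speed),
#'   `bounds` (length-2, s, tf_bound), `min_gap` (m, intersect),
#'   `tolerance` (rad, knees), `both_knees` (logical, knees),
#'   `state_exemptions`, `control_exemptions` (character, symmetry)
#' @return list of class `fns_constraint`
#' @export
constraint_spec <- function(kind = c("sym_half", "sym_full", "speed_bound",
                                     "avg_speed", "tf_bound", "intersect",
                                     "knees", "rest"), ...) {
  kind <- match.arg(kind)
  prm <- list(...)
  if (kind == "speed_bound") {
    if (is.null(prm$percent) || prm$percent <= 0) {
      stop("speed_bound requires percent > 0")
    }
  }
  if (kind == "avg_speed" && is.null(prm$target)) {
    stop("avg_speed requires a target speed")
  }
  if (kind == "tf_bound" &&
      (length(prm$bounds %||% NULL) != 2L || diff(prm$bounds) < 0)) {
    stop("tf_bound requires bounds = c(lo, hi)")
  }
  structure(c(list(kind = kind), prm), class = "fns_constraint")
}

# mirrored state/control vectors for stride symmetry
mirror_state_names <- function(model) {
  mm <- mirror_map(model)
  cn <- coord_names(model)
  list(
    q = paste0("q_", cn[mm$coord]),
    u = paste0("u_", cn[mm$coord]),
    act = if (n_muscle(model)) paste0("act_",
                                      model$muscles$name[mm$muscle]),
    exc = if (n_muscle(model)) paste0("exc_",
                                      model$muscles$name[mm$muscle]),
    res = if (n_reserve(model)) paste0("res_",
                                       model$reserves$name[mm$reserve])
  )
}

#' Stride symmetry residual
#'
#' Half-stride mode compares the trajectory end point to the left-right
#' mirrored start point; full-stride mode compares end to start
#' (periodicity). Exempt channels (by default the forward pelvis
#' translation state and the reserve-actuator controls, which represent
#' walker interaction and volitional effort) are skipped.
#'
#' @param traj an `fns_trajectory`
#' @param mode `"half"` or `"full"`
#' @param state_exemptions,control_exemptions character vectors of state /
#'   control column names to exempt (defaults: `q_pelvis_tx` state, all
#'   `res_*` controls in half mode; only `q_pelvis_tx` in full mode)
#' @return named residual vector (end minus mirrored/plain start)
#' @export
symmetry_residual <- function(traj, mode = c("half", "full"),
                              state_exemptions = NULL,
                              control_exemptions = NULL) {
  mode <- match.arg(mode)
  model <- traj$model
  base_tx <- paste0("q_", model$segments$name[1], "_tx")
  n <- length(traj$time)
  x0 <- traj$states[1, ]
  x1 <- traj$states[n, ]
  c0 <- traj$controls[1, ]
  c1 <- traj$controls[n, ]
  if (mode == "half") {
    mn <- mirror_state_names(model)
    perm <- c(setNames(mn$q, paste0("q_", coord_names(model))),
              setNames(mn$u, paste0("u_", coord_names(model))),
              if (n_muscle(model)) {
                setNames(mn$act, paste0("act_", model$muscles$name))
              })
    keep <- intersect(names(x0), names(perm))
    x0m <- x0
    x0m[keep] <- x0[perm[keep]]
    cperm <- c(if (n_muscle(model)) {
      setNames(mn$exc, paste0("exc_", model$muscles$name))
    }, if (n_reserve(model)) {
      setNames(mn$res, paste0("res_", model$reserves$name))
    })
    ckeep <- intersect(names(c0), names(cperm))
    c0m <- c0
    c0m[ckeep] <- c0[cperm[ckeep]]
    sex <- state_exemptions %||% base_tx
    cex <- control_exemptions %||%
      grep("^res_", names(c0), value = TRUE)
    rs <- (x1 - x0m)[setdiff(names(x0), sex)]
    rc <- (c1 - c0m)[setdiff(names(c0), c(cex, grep("^acc_", names(c0),
                                                    value = TRUE)))]
  } else {
    sex <- state_exemptions %||% base_tx
    cex <- control_exemptions %||% character()
    rs <- (x1 - x0)[setdiff(names(x0), sex)]
    rc <- (c1 - c0)[setdiff(names(c0), c(cex, grep("^acc_", names(c0),
                                                   value = TRUE)))]
  }
  c(rs, rc)
}

#' Per-coordinate speed bounds from neurotypical reference ranges
#'
#' @param nt_speed_ranges data.frame with `name`, `lo`, `hi` giving the
#'   speed range of each coordinate in the neurotypical reference motion
#' @param percent fraction (> 0) of the reference range to allow; 1 keeps
#'   the full range
#' @return data.frame with `name`, `lo`, `hi` bounds applied at every
#'   mesh node; zero-width ranges are widened to a minimal band and
#'   flagged with a warning
#' @export
speed_bounds <- function(nt_speed_ranges, percent) {
  if (percent <= 0) stop("percent must be > 0")
  lo <- percent * nt_speed_ranges$lo
  hi <- percent * nt_speed_ranges$hi
  degen <- hi - lo < 1e-9
  if (any(degen)) {
    warning("zero-width speed range for: ",
            paste(nt_speed_ranges$name[degen], collapse = ", "),
            "; widened to +/- 1e-6")
    lo[degen] <- lo[degen] - 1e-6
    hi[degen] <- hi[degen] + 1e-6
  }
  data.frame(name = nt_speed_ranges$name, lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Average center-of-mass speed residual
#'
#' @param traj an `fns_trajectory`
#' @param target target average forward CoM speed, m/s
#' @return scalar residual (achieved minus target)
#' @export
avg_speed_residual <- function(traj, target) {
  n <- length(traj$time)
  if (traj$time[n] <= traj$time[1]) stop("t_f must exceed t_i")
  com <- com_state(traj$model, traj_Q(traj)[, c(1, n), drop = FALSE])
  unname((com["x", 2] - com["x", 1]) /
           (traj$time[n] - traj$time[1]) - target)
}

# body-fixed points used for the leg clearance constraint
clearance_points <- function(model) {
  list(segments = c("thigh_l", "thigh_r", "shank_l", "shank_r"),
       offsets = rbind(c(0, 0, 0, 0), c(-0.45, -0.45, -0.43, -0.43)),
       pairs = rbind(c(1, 2), c(3, 4)))
}

#' Leg clearance (non-intersection) residual
#'
#' Euclidean gap between paired left/right leg landmark points (knee and
#' ankle centers by default) minus the minimum allowed gap, at every node;
#' values must stay >= 0 for feasibility. The gap is symmetric in the two
#' points of a pair.
#'
#' @param traj an `fns_trajectory`
#' @param min_gap minimum allowed distance, m
#' @return matrix (pairs x nodes) of gap residuals
#' @export
leg_clearance_residual <- function(traj, min_gap = 0.05) {
  model <- traj$model
  cp <- clearance_points(model)
  pos <- model_point_positions(model, traj_Q(traj), cp$segments,
                               cp$offsets)
  out <- matrix(NA_real_, nrow(cp$pairs), ncol(pos))
  for (k in seq_len(nrow(cp$pairs))) {
    i <- cp$pairs[k, 1]; j <- cp$pairs[k, 2]
    dx <- pos[2 * i - 1, ] - pos[2 * j - 1, ]
    dy <- pos[2 * i, ] - pos[2 * j, ]
    out[k, ] <- sqrt(dx^2 + dy^2 + 1e-12) - min_gap
  }
  rownames(out) <- c("knee", "ankle")[seq_len(nrow(out))]
  out
}

# nodes where a foot's normal contact force rises through the threshold
# after a sustained unloaded (swing) period and stays loaded: footstrike
# onsets of double stance. Requiring the surrounding nodes to agree keeps
# grazing-contact chatter from spawning spurious events.
double_stance_onsets <- function(traj, threshold_frac = 0.05) {
  model <- traj$model
  Fm <- foot_contact_forces(model, traj_Q(traj), traj_U(traj))
  thr <- threshold_frac * model$total_mass * model$gravity
  onsets <- list()
  for (side in c("left", "right")) {
    fy <- Fm[if (side == "left") "left_fy" else "right_fy", ]
    loaded <- fy > thr
    n <- length(loaded)
    on <- integer()
    for (i in seq_len(n)[-1]) {
      prev2 <- if (i >= 3L) !loaded[i - 2L] else TRUE
      next1 <- if (i < n) loaded[i + 1L] else TRUE
      if (loaded[i] && !loaded[i - 1L] && prev2 && next1) {
        on <- c(on, i)
      }
    }
    onsets[[side]] <- on
  }
  onsets
}

#' Straight-knee residual at double-stance onsets
#'
#' Requires (near) zero knee angles at the nodes where double stance
#' begins, i.e. where a foot's total normal contact force first rises
#' above 5% body weight.
#'
#' @param traj an `fns_trajectory`
#' @param tolerance allowed absolute knee angle, rad (default 1 degree)
#' @param both_knees require both knees straight (default) or only the
#'   striking leg's knee
#' @return data.frame with `node`, `knee`, `violation` (positive when the
#'   angle magnitude exceeds the tolerance)
#' @export
knee_extension_event <- function(traj, tolerance = pi / 180,
                                 both_knees = TRUE) {
  model <- traj$model
  on <- double_stance_onsets(traj)
  nodes <- sort(unique(unlist(on)))
  if (length(nodes) == 0L) {
    stop("no double-stance onset found in trajectory")
  }
  knees <- c("q_shank_l_q", "q_shank_r_q")
  out <- NULL
  for (nd in nodes) {
    use <- if (both_knees) knees else {
      striking <- c("left", "right")[vapply(on, function(x) nd %in% x,
                                            TRUE)]
      paste0("q_shank_", substr(striking, 1, 1), "_q")
    }
    for (k in use) {
      ang <- traj$states[nd, k]
      out <- rbind(out, data.frame(node = nd, knee = k,
                                   violation = abs(ang) - tolerance))
    }
  }
  out
}

#' Initial-rest residual
#'
#' The full speed vector at the initial time; zero when the model starts
#' at rest.
#' @param traj an `fns_trajectory`
#' @return named residual vector
#' @export
initial_rest_residual <- function(traj) {
  u <- traj$states[1, paste0("u_", coord_names(traj$model))]
  setNames(as.numeric(u), paste0("u_", coord_names(traj$model)))
}
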