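# Synthetic data generation: neurotypical-style reference trajectories
# for tracking, instrumented stepping trials with known ground truth, and
# excitation traces. All randomness flows from one explicit seed per call.

#' Neurotypical reference specification
#'
#' @param gait_speed average forward speed, m/s
#' @param cadence steps per minute
#' @param stride_length m; derived from speed and cadence when `NULL`
#'   (speed = stride_length * cadence / 120 is enforced)
#' @param grf_peak peak vertical ground reaction force as a fraction of
#'   body weight
#' @param body_mass kg (for force scaling)
#' @param marker_rate,force_rate sampling rates, Hz
#' @param n_strides number of strides to generate
#' @param seed integer seed
#' @return list of class `nt_reference_spec`
#' @export
nt_reference_spec <- function(gait_speed = 0.4, cadence = 120,
                              stride_length = NULL, grf_peak = 1.1,
                              body_mass = 76.2, marker_rate = 100,
                              force_rate = 1000, n_strides = 2,
                              seed = 1) {
  stride_time <- 120 / cadence
  if (is.null(stride_length)) {
    stride_length <- gait_speed * stride_time
  } else if (abs(gait_speed - stride_length / stride_time) > 1e-9) {
    stop("inconsistent spec: speed must equal stride_length * cadence/120")
  }
  if (marker_rate <= 0 || force_rate <= 0) stop("rates must be positive")
  structure(list(gait_speed = gait_speed, cadence = cadence,
                 stride_length = stride_length,
                 stride_time = stride_time, grf_peak = grf_peak,
                 body_mass = body_mass, marker_rate = marker_rate,
                 force_rate = force_rate, n_strides = n_strides,
                 seed = seed),
            class = "nt_reference_spec")
}

# smooth periodic joint-angle gait template; phase in [0, 1)
gait_angle_template <- function(phase) {
  list(
    hip = 0.05 + 0.22 * sin(2 * pi * phase),
    knee = 0.17 - 0.15 * cos(2 * pi * phase) + 0.05 * sin(4 * pi * phase),
    ankle = -0.08 * sin(2 * pi * phase) + 0.03 * sin(4 * pi * phase)
  )
}

#' Generate a neurotypical-style tracking reference
#'
#' Builds smooth periodic joint-angle trajectories (a truncated Fourier
#' gait template, left and right half a stride out of phase), realizes
#' marker trajectories by forward kinematics of the supplied model, and
#' synthesizes per-foot double-bump vertical ground-reaction forces
#' alternating at the stated cadence. The vertical impulse over a stride
#' is normalized to body weight times stride time.
#'
#' @param spec an [nt_reference_spec()]
#' @param model model whose markers are realized (default
#'   [planar_biped()])
#' @return an `fns_reference` with markers, forces and the joint-angle
#'   (`ik`) table
#' @export
generate_nt_reference <- function(spec = nt_reference_spec(),
                                  model = planar_biped()) {
  Ts <- spec$stride_time
  dur <- spec$n_strides * Ts
  tm <- seq(0, dur, by = 1 / spec$marker_rate)
  tff <- seq(0, dur, by = 1 / spec$force_rate)
  phase <- function(t) (t / Ts) %% 1

  q0 <- standing_pose(model)
  angles <- function(t) {
    ph <- phase(t)
    L <- gait_angle_template(ph)
    R <- gait_angle_template((ph + 0.5) %% 1)
    cbind(pelvis_tx = spec$gait_speed * t + 0.01 * sin(4 * pi * ph),
          pelvis_ty = q0[["pelvis_ty"]] + 0.008 * cos(4 * pi * ph),
          pelvis_rot = 0.04 * sin(2 * pi * ph),
          trunk_q = -0.03 + 0.02 * cos(2 * pi * ph),
          thigh_l_q = L$hip, shank_l_q = L$knee, foot_l_q = L$ankle,
          thigh_r_q = R$hip, shank_r_q = R$knee, foot_r_q = R$ankle)
  }
  ik <- as.data.frame(angles(tm))
  ik <- ik[, coord_names(model)[coord_names(model) %in% colnames(ik)],
           drop = FALSE]
  Q <- t(as.matrix(ik))
  pos <- model_marker_positions(model, Q)
  mk <- model$markers
  markers <- list()
  for (i in seq_len(nrow(mk))) {
    markers[[mk$name[i]]] <- cbind(pos[2 * i - 1, ], pos[2 * i, ])
  }

  # double-bump vertical GRF per foot; stance duty factor 0.6
  bw <- spec$body_mass * 9.81
  duty <- 0.6
  bump <- function(s) {
    # s in [0,1] within stance; M-shaped double bump
    pmax(sin(pi * s) * (1 + 0.25 * cos(2 * pi * s)), 0)
  }
  foot_fz <- function(t, side) {
    ph <- phase(t)
    if (side == "right") ph <- (ph + 0.5) %% 1
    s <- ph / duty
    ifelse(s <= 1, bump(s), 0)
  }
  fzl <- foot_fz(tff, "left")
  fzr <- foot_fz(tff, "right")
  # normalize total vertical impulse per stride to body weight * Ts
  imp <- trapz(tff, fzl + fzr) / spec$n_strides
  amp <- bw * Ts / imp
  fzl <- amp * fzl
  fzr <- amp * fzr
  fxl <- 0.08 * bw * sin(2 * pi * phase(tff) / duty) *
    (foot_fz(tff, "left") > 0)
  fxr <- 0.08 * bw * sin(2 * pi * ((phase(tff) + 0.5) %% 1) / duty) *
    (foot_fz(tff, "right") > 0)
  out <- reference_data(
    marker_time = tm, markers = markers,
    force_time = tff,
    forces = list(left = cbind(fxl, fzl), right = cbind(fxr, fzr)),
    marker_rate = spec$marker_rate, force_rate = spec$force_rate,
    ik = data.frame(time = tm, ik, check.names = FALSE)
  )
  out$spec <- spec
  out
}

#' Stepping-trial specification
#'
#' Ground-truth parameters for a synthetic instrumented walking trial.
#' Defaults mirror the magnitudes observed for FNS-assisted stepping with
#' a walker: very long step times dominated by double-stance dwell, step
#' lengths near half a meter, and upper-extremity loads of a few hundred
#' newtons.
#'
#' @param step_time_l,step_time_r footstrike-to-footstrike time per side, s
#' @param step_length_l,step_length_r m
#' @param ratio_l,ratio_r swing-to-stance duration ratio per side
#' @param n_steps steps per side
#' @param uee_baseline baseline handle resultant force, N
#' @param uee_peak peak handle resultant force during swing, N
#' @param uee_peak_frac swing-phase fraction at which the peak occurs
#' @param marker_noise_sd,force_noise_sd additive Gaussian noise SD (m, N)
#' @param outliers optional data.frame with `side`, `step`, `feature`
#'   (`"ml_vel"` or `"toe_travel"`) marking steps whose step-detection
#'   feature is pushed to the third quartile plus three interquartile
#'   ranges
#' @param seed integer seed
#' @return list of class `trial_spec`
#' @export
trial_spec <- function(step_time_l = 16.85, step_time_r = 16.80,
                       step_length_l = 0.539, step_length_r = 0.538,
                       ratio_l = 0.13, ratio_r = 0.15, n_steps = 8,
                       uee_baseline = 190, uee_peak = 440,
                       uee_peak_frac = 0.5, marker_noise_sd = 0,
                       force_noise_sd = 0, outliers = NULL, seed = 1) {
  vals <- c(step_time_l, step_time_r, step_length_l, step_length_r,
            ratio_l, ratio_r, n_steps, uee_baseline, uee_peak)
  if (any(vals <= 0)) stop("trial spec values must be positive")
  structure(list(step_time_l = step_time_l, step_time_r = step_time_r,
                 step_length_l = step_length_l,
                 step_length_r = step_length_r,
                 ratio_l = ratio_l, ratio_r = ratio_r, n_steps = n_steps,
                 uee_baseline = uee_baseline, uee_peak = uee_peak,
                 uee_peak_frac = uee_peak_frac,
                 marker_noise_sd = marker_noise_sd,
                 force_noise_sd = force_noise_sd,
                 outliers = outliers, seed = seed),
            class = "trial_spec")
}

smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

#' Generate a synthetic stepping trial with ground truth
#'
#' Realizes heel/toe marker trajectories, walker handle load-cell forces,
#' step events and per-step detection features exactly matching the
#' specification before noise is added; returns the ground-truth step
#' records alongside. Deterministic for a given seed.
#'
#' @param spec a [trial_spec()]
#' @param marker_rate,force_rate sampling rates, Hz
#' @return list of class `gait_trial` with `marker_time`, `markers`
#'   (named list of n x 3 matrices: x anterior, y up, z medio-lateral),
#'   `force_time`, `handle_forces` (`left`, `right`, n x 3), `events`
#'   (per side `fs` and `to` times), `features` (per-step `ml_vel` and
#'   `toe_travel` by side), `angles` (joint-angle table), and
#'   `ground_truth` (StepRecord data.frame)
#' @export
generate_trial <- function(spec = trial_spec(), marker_rate = 100,
                           force_rate = 1000) {
  restore <- local_seed(spec$seed)
  on.exit(restore())
  n <- spec$n_steps
  stance <- c(l = spec$step_time_l / (1 + spec$ratio_l),
              r = spec$step_time_r / (1 + spec$ratio_r))
  swing <- c(l = spec$step_time_l - stance[["l"]],
             r = spec$step_time_r - stance[["r"]])
  # alternating footstrikes; right leads half a left cycle after left FS
  fs_l <- spec$step_time_l * (0:n)
  fs_r <- spec$step_time_r * (0:n) + spec$step_time_l / 2
  to_l <- fs_l[-length(fs_l)] + stance[["l"]]
  to_r <- fs_r[-length(fs_r)] + stance[["r"]]
  dur <- max(fs_l, fs_r) + 1

  tm <- seq(0, dur, by = 1 / marker_rate)
  tf <- seq(0, dur, by = 1 / force_rate)

  # heel anterior positions: dwell during stance, advance during swing;
  # the advance completes one marker sample before footstrike so sampled
  # positions at the event times are exact
  heel_traj <- function(fs, to, start_pos, advance, lift) {
    x <- rep(start_pos, length(tm))
    y <- numeric(length(tm))
    pos <- start_pos
    for (k in seq_along(to)) {
      sw0 <- to[k]
      sw1 <- fs[k + 1] - 1 / marker_rate
      s <- (tm - sw0) / (sw1 - sw0)
      inswing <- s > 0 & s < 1
      x[inswing] <- pos + advance * smoothstep(s[inswing])
      y[inswing] <- lift * sin(pi * pmin(pmax(s[inswing], 0), 1))
      x[tm >= sw1] <- pos + advance
      pos <- pos + advance
    }
    cbind(x, y, 0)
  }
  stride_adv <- spec$step_length_l + spec$step_length_r
  # heel landing positions consistent with the step-length definition
  # (leading heel minus trailing heel at consecutive contralateral
  # footstrikes): the right heel starts one right step length ahead
  heel_l <- heel_traj(fs_l, to_l, 0, stride_adv, 0.03)
  heel_r <- heel_traj(fs_r, to_r, spec$step_length_r, stride_adv, 0.03)
  toe_l <- heel_l + cbind(rep(0.22, length(tm)), 0, 0)
  toe_r <- heel_r + cbind(rep(0.22, length(tm)), 0, 0)
  sacr <- cbind((heel_l[, 1] + heel_r[, 1]) / 2, 0.96, 0)

  # walker handle forces: vertical baseline split between handles plus a
  # swing-phase bump peaking at the stated swing fraction
  fy <- rep(spec$uee_baseline, length(tf))
  bump_amp <- spec$uee_peak - spec$uee_baseline
  add_bumps <- function(fy, to, fs_next, frac) {
    for (k in seq_along(to)) {
      sw0 <- to[k]
      sw1 <- fs_next[k + 1]
      tpk <- sw0 + frac * (sw1 - sw0)
      tpk <- round(tpk * force_rate) / force_rate  # land on a sample
      s <- (tf - sw0) / (sw1 - sw0)
      inswing <- s >= 0 & s <= 1
      shape <- ifelse(tf <= tpk,
                      smoothstep((tf - sw0) / (tpk - sw0)),
                      1 - smoothstep((tf - tpk) / (sw1 - tpk)))
      fy[inswing] <- fy[inswing] + bump_amp * shape[inswing]
    }
    fy
  }
  fy <- add_bumps(fy, to_l, fs_l, spec$uee_peak_frac)
  fy <- add_bumps(fy, to_r, fs_r, spec$uee_peak_frac)
  handle <- cbind(0, fy, 0)

  # per-step detection features with optional injected outliers
  mlv <- list(left = 0.04 + 0.005 * sin(seq_len(n)),
              right = 0.04 + 0.005 * cos(seq_len(n)))
  ttr <- list(left = rep(stride_adv, n), right = rep(stride_adv, n))
  if (!is.null(spec$outliers)) {
    for (i in seq_len(nrow(spec$outliers))) {
      o <- spec$outliers[i, ]
      tgt <- if (o$feature == "ml_vel") mlv else ttr
      vals <- unlist(tgt)
      fence <- quantile(vals, 0.75) + 3 * stats::IQR(vals)
      if (o$feature == "ml_vel") {
        mlv[[o$side]][o$step] <- fence
      } else {
        ttr[[o$side]][o$step] <- fence
      }
    }
  }

  # joint-angle table: one percent-cycle template time-warped per step
  ang <- data.frame(time = tm)
  for (side in c("left", "right")) {
    fs <- if (side == "left") fs_l else fs_r
    phase <- rep(NA_real_, length(tm))
    for (k in seq_len(length(fs) - 1L)) {
      inc <- tm >= fs[k] & tm < fs[k + 1]
      phase[inc] <- (tm[inc] - fs[k]) / (fs[k + 1] - fs[k])
    }
    tmpl <- gait_angle_template(ifelse(is.na(phase), 0, phase))
    sfx <- if (side == "left") "_l" else "_r"
    ang[[paste0("hip", sfx)]] <- tmpl$hip
    ang[[paste0("knee", sfx)]] <- tmpl$knee
    ang[[paste0("ankle", sfx)]] <- tmpl$ankle
  }

  if (spec$marker_noise_sd > 0) {
    nz <- function(mm) {
      mm[, 1:2] <- mm[, 1:2] +
        matrix(rnorm(2 * nrow(mm), 0, spec$marker_noise_sd), ncol = 2)
      mm
    }
    heel_l <- nz(heel_l); heel_r <- nz(heel_r)
    toe_l <- nz(toe_l); toe_r <- nz(toe_r); sacr <- nz(sacr)
  }
  if (spec$force_noise_sd > 0) {
    handle[, 2] <- handle[, 2] +
      rnorm(nrow(handle), 0, spec$force_noise_sd)
  }

  gt <- rbind(
    data.frame(side = "left", step = seq_len(n),
               step_time = spec$step_time_l,
               step_length = spec$step_length_l,
               swing_time = swing[["l"]], stance_time = stance[["l"]],
               ratio = swing[["l"]] / stance[["l"]]),
    data.frame(side = "right", step = seq_len(n),
               step_time = spec$step_time_r,
               step_length = spec$step_length_r,
               swing_time = swing[["r"]], stance_time = stance[["r"]],
               ratio = swing[["r"]] / stance[["r"]]))

  structure(list(
    marker_time = tm,
    markers = list(HEEL_l = heel_l, TOE_l = toe_l, HEEL_r = heel_r,
                   TOE_r = toe_r, SACR = sacr),
    force_time = tf,
    handle_forces = list(left = handle / 2, right = handle / 2),
    events = list(left = list(fs = fs_l, to = to_l),
                  right = list(fs = fs_r, to = to_r)),
    features = list(ml_vel = mlv, toe_travel = ttr),
    angles = ang,
    ground_truth = gt,
    spec = spec, label = "synthetic", id = paste0("seed", spec$seed)
  ), class = "gait_trial")
}

#' Generate per-group excitation traces
#'
#' @param groups character vector of group ids, or a model whose groups
#'   are used
#' @param duration trace duration, s
#' @param shape `"pulse"` (smooth burst), `"ramp"`, or `"custom"` (supply
#'   `values`)
#' @param rate sampling rate, Hz
#' @param amplitude peak excitation
#' @param synergy logical; `TRUE` returns identical traces for all
#'   members of a group
#' @param values custom trace (recycled), used when `shape = "custom"`
#' @param seed integer seed (randomizes burst timing across groups)
#' @return list with `time` and `excitations` (matrix time x channels,
#'   bounded to \[0.01, 1\]); channel names are `<group>` or
#'   `<group>.<member>`
#' @export
generate_excitations <- function(groups, duration = 1, shape = "pulse",
                                 rate = 100, amplitude = 1,
                                 synergy = TRUE, values = NULL,
                                 seed = 1) {
  if (duration <= 0) stop("duration must be > 0")
  restore <- local_seed(seed)
  on.exit(restore())
  if (inherits(groups, "msk_model")) {
    model <- groups
    members <- split(model$muscles$name, model$muscles$group)
  } else {
    members <- setNames(as.list(groups), groups)
  }
  t <- seq(0, duration, by = 1 / rate)
  out <- NULL
  nms <- character()
  for (g in names(members)) {
    tr <- switch(shape,
      pulse = {
        c0 <- runif(1, 0.2, 0.8) * duration
        w <- 0.15 * duration
        amplitude * exp(-0.5 * ((t - c0) / w)^2)
      },
      ramp = amplitude * t / duration,
      custom = rep_len(values, length(t)),
      stop("unknown shape"))
    tr <- pmin(pmax(tr, 0.01), 1)
    mem <- members[[g]]
    if (synergy || length(mem) == 1L) {
      block <- matrix(tr, length(t), length(mem))
    } else {
      block <- vapply(seq_along(mem), function(i) {
        pmin(pmax(tr * runif(1, 0.6, 1), 0.01), 1)
      }, numeric(length(t)))
    }
    out <- cbind(out, block)
    nms <- c(nms, if (length(mem) == 1L && mem[[1]] == g) g else
      paste0(g, ".", mem))
  }
  colnames(out) <- nms
  list(time = t, excitations = out)
}
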