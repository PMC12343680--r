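# Cost subterms evaluated on discretized trajectories, and their tracking
# and predictive compositions.

#' Marker set for tracking costs
#'
#' @param markers data.frame with `name`, `segment`, `x`, `y`, `bony` and
#'   optionally `weight`; when `weight` is missing, bony-prominence markers
#'   get weight 10 and all others weight 1.
#' @return validated marker-set data.frame
#' @export
marker_set <- function(markers) {
  if (is.null(markers$weight)) {
    markers$weight <- ifelse(markers$bony, 10, 1)
  }
  if (any(markers$weight <= 0)) stop("marker weights must be > 0")
  markers
}

#' Reference data for tracking costs
#'
#' Bundles measured (or synthesized) marker trajectories and per-foot
#' ground reaction forces, at their native sampling rates. Both are
#' linearly interpolated onto the trajectory mesh when evaluating costs.
#'
#' @param marker_time,force_time sampling time vectors, s
#' @param markers named list of n x 2 matrices (x, y in m), one per marker
#' @param forces list with `left` and `right` n x 2 matrices (fx, fy in N)
#' @param marker_rate,force_rate sampling rates, Hz
#' @param ik optional data.frame of joint angles (`time` plus coordinate
#'   columns) from inverse kinematics, used for speed-bound ranges
#' @return object of class `fns_reference`
#' @export
reference_data <- function(marker_time, markers, force_time, forces,
                           marker_rate = 100, force_rate = 1000,
                           ik = NULL) {
  stopifnot(is.list(markers), is.list(forces))
  for (mm in markers) check_finite(mm, "reference markers")
  for (ff in forces) check_finite(ff, "reference forces")
  structure(list(marker_time = marker_time, markers = markers,
                 force_time = force_time, forces = forces,
                 marker_rate = marker_rate, force_rate = force_rate,
                 ik = ik),
            class = "fns_reference")
}

#' Cost subterm weights
#'
#' @param w_mt,w_ct,w_s,w_e,w_p,w_ad non-negative subterm weights (marker
#'   tracking, contact tracking, synergy, effort, energy penalty,
#'   auxiliary derivatives)
#' @param reserve_weight effort weight multiplier for reserve-actuator
#'   channels relative to muscle channels
#' @return list of class `fns_cost_weights`
#' @export
cost_weights <- function(w_mt = 1, w_ct = 1, w_s = 1, w_e = 1, w_p = 1,
                         w_ad = 1, reserve_weight = 10) {
  w <- list(w_mt = w_mt, w_ct = w_ct, w_s = w_s, w_e = w_e, w_p = w_p,
            w_ad = w_ad, reserve_weight = reserve_weight)
  if (any(unlist(w) < 0)) stop("cost weights must be >= 0")
  structure(w, class = "fns_cost_weights")
}

ref_span_check <- function(ref_time, traj_time, what) {
  if (min(ref_time) > min(traj_time) + 1e-9 ||
      max(ref_time) < max(traj_time) - 1e-9) {
    stop(what, " reference does not cover the trajectory time span")
  }
}

#' Marker tracking cost
#'
#' Integral over the trajectory of the weighted squared distances between
#' model markers and reference markers (m^2 s).
#'
#' @param traj an `fns_trajectory`
#' @param ref an `fns_reference`
#' @param markers marker set (defaults to the model's); weights follow the
#'   bony-prominence convention
#' @param quadrature `"trapezoid"` (default) or `"simpson"`
#' @return non-negative scalar
#' @export
eval_marker_tracking <- function(traj, ref, markers = NULL,
                                 quadrature = "trapezoid") {
  model <- traj$model
  markers <- marker_set(markers %||% model$markers)
  miss <- setdiff(markers$name, names(ref$markers))
  if (length(miss)) {
    stop("markers absent from reference data: ",
         paste(miss, collapse = ", "))
  }
  ref_span_check(ref$marker_time, traj$time, "marker")
  seg_idx <- setNames(seq_len(nrow(model$segments)) - 1L,
                      model$segments$name)
  pos <- cpp_point_positions(model$compiled, traj_Q(traj),
                             as.integer(seg_idx[markers$segment]),
                             rbind(markers$x, markers$y))
  w <- quadrature_weights(traj$time, quadrature)
  total <- 0
  for (i in seq_len(nrow(markers))) {
    rm <- ref$markers[[markers$name[i]]]
    rx <- approx(ref$marker_time, rm[, 1], xout = traj$time, rule = 2)$y
    ry <- approx(ref$marker_time, rm[, 2], xout = traj$time, rule = 2)$y
    d2 <- (pos[2 * i - 1, ] - rx)^2 + (pos[2 * i, ] - ry)^2
    total <- total + markers$weight[i] * sum(w * d2)
  }
  total
}

#' Contact force tracking cost
#'
#' Integral of the squared per-foot contact force error normalized by body
#' weight m g (dimensionless * s). Per-foot model force is the vector sum
#' over that foot's contact spheres.
#'
#' @inheritParams eval_marker_tracking
#' @param model optional model override (defaults to `traj$model`)
#' @export
eval_contact_tracking <- function(traj, ref, model = NULL,
                                  quadrature = "trapezoid") {
  model <- model %||% traj$model
  if (!all(c("left", "right") %in% names(ref$forces))) {
    stop("reference forces must contain feet 'left' and 'right'")
  }
  if (is.null(model$spheres) ||
      !all(c("left", "right") %in% model$spheres$foot)) {
    stop("model must group contact spheres into left and right feet")
  }
  ref_span_check(ref$force_time, traj$time, "force")
  Fm <- cpp_foot_forces_batch(model$compiled, traj_Q(traj), traj_U(traj))
  w <- quadrature_weights(traj$time, quadrature)
  mg <- model$total_mass * model$gravity
  total <- 0
  for (side in c("left", "right")) {
    rf <- ref$forces[[side]]
    fx <- approx(ref$force_time, rf[, 1], xout = traj$time, rule = 2)$y
    fy <- approx(ref$force_time, rf[, 2], xout = traj$time, rule = 2)$y
    rows <- if (side == "left") 1:2 else 3:4
    d2 <- (Fm[rows[1], ] - fx)^2 + (Fm[rows[2], ] - fy)^2
    total <- total + sum(w * d2)
  }
  total / mg
}

# per-group excitation-difference matrix rows: (e1-e2) and, for triples,
# (e1-e3); returns a matrix (n_terms x P)
synergy_differences <- function(E, muscles, groups = NULL) {
  out <- NULL
  labs <- character()
  for (g in unique(muscles$group)) {
    idx <- which(muscles$group == g)
    if (length(idx) == 1L) next
    out <- rbind(out, E[idx[1], ] - E[idx[2], ])
    labs <- c(labs, paste0(g, ":1-2"))
    if (length(idx) == 3L) {
      out <- rbind(out, E[idx[1], ] - E[idx[3], ])
      labs <- c(labs, paste0(g, ":1-3"))
    }
  }
  if (is.null(out)) out <- matrix(0, 0, ncol(E))
  rownames(out) <- labs
  out
}

#' Muscle-group synergy cost
#'
#' Because one stimulation channel drives all elements of a muscle group,
#' within-group excitation differences are penalized: for each group the
#' integrand is (e1 - e2)^2, plus (e1 - e3)^2 for three-element groups.
#' Singleton groups contribute zero (a message is emitted).
#'
#' @inheritParams eval_marker_tracking
#' @export
eval_synergy <- function(traj, quadrature = "trapezoid") {
  model <- traj$model
  if (n_muscle(model) == 0L) return(0)
  sizes <- table(model$muscles$group)
  if (any(sizes == 1L)) {
    message("singleton muscle groups contribute no synergy cost: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  }
  D <- synergy_differences(traj_EXC(traj), model$muscles)
  if (nrow(D) == 0L) return(0)
  w <- quadrature_weights(traj$time, quadrature)
  sum(colSums(D^2) * w)
}

# effort channel weights: muscles equal (1), reserves penalized
effort_channel_weights <- function(model, weights) {
  c(rep(1, n_muscle(model)),
    rep(weights$reserve_weight, n_reserve(model)))
}

#' Control effort cost
#'
#' Weighted integral of squared control signals over all channels (muscle
#' excitations weighted equally, reserve-actuator channels penalized).
#' With `divide_by_distance = TRUE` the integral is divided by the
#' center-of-mass travel distance `d`.
#'
#' @inheritParams eval_marker_tracking
#' @param weights an [cost_weights()] object (supplies the reserve channel
#'   penalty)
#' @param d center-of-mass travel distance, m
#' @param divide_by_distance logical
#' @export
eval_effort <- function(traj, weights = cost_weights(), d = 1,
                        divide_by_distance = TRUE,
                        quadrature = "trapezoid") {
  if (divide_by_distance && d <= 0) {
    stop("distance d must be > 0 when divide_by_distance is set")
  }
  E <- traj_EXC(traj)
  R <- traj_controls(traj, "res")
  C <- rbind(E, R)
  wch <- effort_channel_weights(traj$model, weights)[seq_len(nrow(C))]
  w <- quadrature_weights(traj$time, quadrature)
  val <- sum((wch %*% C^2) * w)
  if (divide_by_distance) val / d else val
}

#' Energy injection penalty
#'
#' Penalizes excitation of the rectus abdominus and external oblique
#' channels (integrand 10 (e_ra^2 + e_eo^2)); models without those muscles
#' contribute zero.
#'
#' @inheritParams eval_marker_tracking
#' @export
eval_energy_penalty <- function(traj, quadrature = "trapezoid") {
  nm <- colnames(traj$controls)
  chans <- nm[grepl("^exc_(rect_abd|ext_obl)", nm)]
  if (length(chans) == 0L) return(0)
  w <- quadrature_weights(traj$time, quadrature)
  E <- t(traj$controls[, chans, drop = FALSE])
  sum(10 * colSums(E^2) * w)
}

#' Auxiliary-derivative cost
#'
#' Integral of squared tendon-force time derivatives (N^2/s), used with the
#' implicit compliant-tendon formulation to encourage convergence. Uses
#' `dft_*` control columns when present (interpreted in N/s), otherwise
#' differentiates `ft_*` state columns numerically; rigid-tendon
#' trajectories contribute zero (a message is emitted).
#'
#' @inheritParams eval_marker_tracking
#' @export
eval_aux_deriv <- function(traj, quadrature = "trapezoid") {
  dft <- traj_controls(traj, "dft")
  if (nrow(dft) == 0L) {
    ft <- traj_states(traj, "ft")
    if (nrow(ft) == 0L) {
      message("rigid-tendon trajectory: auxiliary-derivative cost is 0")
      return(0)
    }
    dft <- t(apply(ft, 1, function(x) grad_time(traj$time, x)))
  }
  w <- quadrature_weights(traj$time, quadrature)
  sum(colSums(dft^2) * w)
}

#' Compose the total cost from subterm values
#'
#' Tracking mode: `w_mt J_mt + w_ct J_ct + w_s J_s + d w_e J_e + w_p J_p +
#' w_ad J_ad` (the distance factor cancels the 1/d inside the effort
#' subterm). Predictive mode: `w_s J_s + w_e J_e + w_p J_p + w_ad J_ad`
#' with the effort subterm retaining its 1/d normalization.
#'
#' @param subterms named list/vector with `J_mt`, `J_ct`, `J_s`, `J_e`,
#'   `J_p`, `J_ad` (missing entries treated as 0; tracking mode requires
#'   the tracking subterms)
#' @param weights an [cost_weights()] object
#' @param mode `"tracking"` or `"predictive"`
#' @param d center-of-mass travel distance, m (tracking mode)
#' @return scalar total cost
#' @export
compose_cost <- function(subterms, weights = cost_weights(),
                         mode = c("tracking", "predictive"), d = 1) {
  mode <- match.arg(mode)
  s <- function(k) {
    v <- subterms[[k]]
    if (is.null(v)) {
      if (mode == "tracking" && k %in% c("J_mt", "J_ct")) {
        stop("tracking mode requires subterm ", k,
             " (is reference data missing?)")
      }
      0
    } else v
  }
  if (mode == "tracking") {
    weights$w_mt * s("J_mt") + weights$w_ct * s("J_ct") +
      weights$w_s * s("J_s") + d * weights$w_e * s("J_e") +
      weights$w_p * s("J_p") + weights$w_ad * s("J_ad")
  } else {
    weights$w_s * s("J_s") + weights$w_e * s("J_e") +
      weights$w_p * s("J_p") + weights$w_ad * s("J_ad")
  }
}

#' Evaluate all cost subterms on a trajectory
#'
#' @inheritParams eval_marker_tracking
#' @param weights an [cost_weights()] object
#' @param mode `"tracking"` or `"predictive"`
#' @param d center-of-mass distance; `NULL` computes it from the trajectory
#' @return list with per-subterm values, weights, distance and the total
#' @export
cost_report <- function(traj, weights = cost_weights(),
                        mode = c("tracking", "predictive"), ref = NULL,
                        markers = NULL, d = NULL,
                        quadrature = "trapezoid") {
  mode <- match.arg(mode)
  if (is.null(d)) {
    com <- com_state(traj$model, traj_Q(traj))
    d <- abs(com["x", ncol(com)] - com["x", 1])
    if (d < 1e-6) d <- 1e-6
  }
  sub <- list(
    J_s = eval_synergy(traj, quadrature),
    J_e = eval_effort(traj, weights, d,
                      divide_by_distance = (mode == "predictive"),
                      quadrature = quadrature),
    J_p = eval_energy_penalty(traj, quadrature),
    J_ad = suppressMessages(eval_aux_deriv(traj, quadrature))
  )
  if (mode == "tracking") {
    if (is.null(ref)) stop("tracking mode requires reference data")
    sub$J_mt <- eval_marker_tracking(traj, ref, markers, quadrature)
    sub$J_ct <- eval_contact_tracking(traj, ref, quadrature = quadrature)
    # the tracked effort subterm is not distance-normalized; compose with
    # d = 1 so the printed composition matches the evaluated integrals
    total <- compose_cost(sub, weights, "tracking", d = 1)
  } else {
    total <- compose_cost(sub, weights, "predictive")
  }
  c(sub, list(weights = unclass(weights), distance = unname(d),
              mode = mode, total = unname(total)))
}

#' Write a cost report as JSON
#' @param report result of [cost_report()]
#' @param path output file
#' @export
write_cost_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
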