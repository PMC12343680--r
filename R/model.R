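# Musculoskeletal model container: planar multibody linkage actuated by
# Hill-type muscle-tendon units and idealized reserve actuators, with
# smoothed Hunt-Crossley foot-ground contact.

#' Construct a planar musculoskeletal gait model
#'
#' Builds a validated model object from its component tables. The model is a
#' planar (sagittal) open-chain linkage: segment 1 is the floating base
#' (pelvis) whose free coordinates are listed in `base_dofs`; every other
#' segment is attached to its parent by a revolute joint with one
#' coordinate. Muscles act through constant moment arms (`moment_arms`),
#' reserve actuators apply bounded generalized forces directly to
#' coordinates, and contact spheres interact with the ground plane y = 0.
#'
#' @param segments data.frame with columns `name`, `parent` (`NA` for the
#'   base), `mass` (kg), `inertia` (planar, kg m^2), `dx`, `dy` (joint
#'   position in the parent frame, m), `comx`, `comy` (center of mass in the
#'   segment frame, m), `qsign` (+1/-1 sign relating the joint coordinate to
#'   counterclockwise rotation), `length` (m). Parents must precede
#'   children.
#' @param base_dofs character subset of `c("tx", "ty", "rot")` naming the
#'   unconstrained base coordinates.
#' @param coord_ranges data.frame with `name`, `lo`, `hi` (rad or m) and
#'   `speed_lo`, `speed_hi` (rad/s or m/s) per coordinate.
#' @param muscles data.frame with `name`, `group`, `side` (`"left"`,
#'   `"right"` or `"center"`), `fmax` (N), `lopt` (m), `lslack` (m),
#'   `pennation` (rad), `tact`, `tdeact` (s), `vmax` (optimal fiber lengths
#'   per second). May be `NULL` for a muscle-free model.
#' @param moment_arms numeric matrix (coordinates x muscles, m); entry
#'   `r[j, m]` is minus the derivative of muscle path length with respect to
#'   coordinate `j`, so positive entries produce positive generalized force.
#' @param groups data.frame with `group`, `side`, `method` (`"implanted"` or
#'   `"surface"`); every muscle's `group` must appear here and each group
#'   must have 1 to 3 member muscles.
#' @param spheres data.frame of contact spheres: `name`, `segment`, `x`,
#'   `y` (segment frame, m), `radius` (m), `stiffness` (N/m^1.5),
#'   `dissipation` (s/m), `mu_d`, `mu_v`, `smoothing` (m), `v_smooth`
#'   (m/s), `foot` (`"left"`, `"right"` or `NA`).
#' @param reserves data.frame: `name`, `coordinate`, `max` (N or Nm),
#'   `tag` (`"normal"` or `"penalized"`).
#' @param markers data.frame: `name`, `segment`, `x`, `y` (m), `bony`
#'   (logical). Marker weights default to 10 for bony prominences and 1
#'   otherwise.
#' @param gravity gravitational acceleration magnitude (m/s^2)
#' @param rigid_tendon logical; `TRUE` (default) treats tendons as
#'   inextensible, `FALSE` adds normalized tendon-force states with an
#'   implicit equilibrium formulation.
#' @param symmetric logical; declares that contralateral segments are
#'   mirror copies (validated when `TRUE`).
#' @return an object of class `msk_model`
#' @export
msk_model <- function(segments, base_dofs, coord_ranges, muscles = NULL,
                      moment_arms = NULL, groups = NULL, spheres = NULL,
                      reserves = NULL, markers = NULL, gravity = 9.81,
                      rigid_tendon = TRUE, symmetric = TRUE) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  if (length(base_dofs)) {
    base_dofs <- match.arg(base_dofs, c("tx", "ty", "rot"),
                           several.ok = TRUE)
  }
  if (!is.na(segments$parent[1])) {
    stop("the first segment must be the base (parent NA)")
  }
  seg_idx <- setNames(seq_len(nrow(segments)), segments$name)
  parent_idx <- ifelse(is.na(segments$parent), 0L,
                       seg_idx[segments$parent])
  if (any(parent_idx >= seq_len(nrow(segments)))) {
    stop("segments must be listed parents before children")
  }

  # coordinate table: base dofs then one revolute coordinate per segment
  base_names <- if (length(base_dofs)) {
    paste0(segments$name[1], "_", base_dofs)
  } else character()
  rev_names <- if (nrow(segments) > 1L) {
    paste0(segments$name[-1], "_q")
  } else character()
  # allow coord_ranges to carry explicit names matching these
  coord_names <- c(base_names, rev_names)
  cr <- coord_ranges
  if (!all(coord_names %in% cr$name)) {
    missing <- setdiff(coord_names, cr$name)
    stop("coord_ranges missing coordinates: ",
         paste(missing, collapse = ", "))
  }
  cr <- cr[match(coord_names, cr$name), , drop = FALSE]

  nmus <- if (is.null(muscles)) 0L else nrow(muscles)
  if (nmus > 0L) {
    stopifnot(!is.null(moment_arms), !is.null(groups))
    moment_arms <- as.matrix(moment_arms)
    if (nrow(moment_arms) != length(coord_names) ||
        ncol(moment_arms) != nmus) {
      stop("moment_arms must be (n coordinates) x (n muscles)")
    }
    with_pos <- c("fmax", "lopt", "lslack", "tact", "tdeact", "vmax")
    for (f in with_pos) {
      if (any(muscles[[f]] <= 0)) stop("muscle field ", f, " must be > 0")
    }
    if (!all(muscles$group %in% groups$group)) {
      stop("every muscle must belong to a declared group")
    }
    sz <- table(muscles$group)
    if (any(sz < 1L | sz > 3L)) {
      stop("muscle groups must have 1 to 3 members")
    }
  }
  if (!is.null(spheres) && nrow(spheres) > 0L) {
    if (any(spheres$radius <= 0)) stop("sphere radius must be > 0")
    if (!all(spheres$segment %in% segments$name)) {
      stop("sphere attached to unknown segment")
    }
  }
  if (!is.null(reserves) && nrow(reserves) > 0L &&
      !all(reserves$coordinate %in% coord_names)) {
    stop("reserve actuator targets unknown coordinate")
  }
  if (!is.null(markers) && nrow(markers) > 0L) {
    if (!all(markers$segment %in% segments$name)) {
      stop("marker attached to unknown segment")
    }
    if (is.null(markers$weight)) {
      markers$weight <- ifelse(markers$bony, 10, 1)
    }
  }

  m <- structure(list(
    segments = segments, base_dofs = base_dofs,
    coordinates = data.frame(
      name = coord_names,
      type = c(if (length(base_dofs)) paste0("base_", base_dofs),
               rep("revolute", length(rev_names))),
      segment = c(rep(segments$name[1], length(base_dofs)),
                  segments$name[-1]),
      lo = cr$lo, hi = cr$hi,
      speed_lo = cr$speed_lo, speed_hi = cr$speed_hi,
      stringsAsFactors = FALSE),
    muscles = muscles, moment_arms = moment_arms, groups = groups,
    spheres = spheres, reserves = reserves, markers = markers,
    gravity = gravity, rigid_tendon = rigid_tendon,
    symmetric = symmetric,
    total_mass = sum(segments$mass)
  ), class = "msk_model")
  m$compiled <- compile_model(m)
  m
}

# Flatten the model into plain arrays for the C++ kernels (0-based indices).
compile_model <- function(m) {
  segs <- m$segments
  nseg <- nrow(segs)
  coord_names <- m$coordinates$name
  cidx <- setNames(seq_along(coord_names) - 1L, coord_names)
  base <- c(tx = -1L, ty = -1L, rot = -1L)
  for (d in m$base_dofs) {
    base[[d]] <- cidx[[paste0(segs$name[1], "_", d)]]
  }
  seg_idx <- setNames(seq_len(nseg) - 1L, segs$name)
  seg_parent <- ifelse(is.na(segs$parent), -1L, seg_idx[segs$parent])
  seg_coord <- c(-1L, if (nseg > 1L) {
    cidx[paste0(segs$name[-1], "_q")]
  })
  nmus <- if (is.null(m$muscles)) 0L else nrow(m$muscles)
  nsph <- if (is.null(m$spheres)) 0L else nrow(m$spheres)
  nres <- if (is.null(m$reserves)) 0L else nrow(m$reserves)
  cm <- list(
    nseg = nseg, ncoord = length(coord_names), nmus = nmus,
    nsph = nsph, nres = nres,
    base_coords = unname(as.integer(base)),
    seg_parent = as.integer(seg_parent),
    seg_coord = as.integer(seg_coord),
    seg_qsign = as.numeric(segs$qsign),
    seg_dloc = rbind(segs$dx, segs$dy),
    seg_com = rbind(segs$comx, segs$comy),
    seg_mass = segs$mass, seg_inertia = segs$inertia,
    gravity = m$gravity, rigid_tendon = m$rigid_tendon
  )
  if (nmus > 0L) {
    mu <- m$muscles
    # reference path length: optimal fiber + slack tendon at q = 0
    cm$mus_fmax <- mu$fmax
    cm$mus_lopt <- mu$lopt
    cm$mus_lslack <- mu$lslack
    cm$mus_tact <- mu$tact
    cm$mus_tdeact <- mu$tdeact
    cm$mus_vmax <- mu$vmax
    cm$mus_lmt0 <- mu$lopt * cos(mu$pennation) + mu$lslack
    cm$R_ma <- unname(m$moment_arms)
  }
  if (nsph > 0L) {
    sp <- m$spheres
    cm$sph_seg <- as.integer(seg_idx[sp$segment])
    cm$sph_foot <- as.integer(ifelse(is.na(sp$foot), 0L,
                                     ifelse(sp$foot == "left", 1L, 2L)))
    cm$sph_loc <- rbind(sp$x, sp$y)
    cm$sph_radius <- sp$radius
    cm$sph_stiff <- sp$stiffness
    cm$sph_diss <- sp$dissipation
    cm$sph_mud <- sp$mu_d
    cm$sph_muv <- sp$mu_v
    cm$sph_eps <- sp$smoothing
    cm$sph_vs <- sp$v_smooth
  }
  if (nres > 0L) {
    cm$res_coord <- as.integer(cidx[m$reserves$coordinate])
    cm$res_max <- m$reserves$max
  }
  cm
}

#' @export
print.msk_model <- function(x, ...) {
  cat("<msk_model>", nrow(x$segments), "segments,",
      nrow(x$coordinates), "coordinates,",
      if (is.null(x$muscles)) 0L else nrow(x$muscles), "muscles,",
      if (is.null(x$spheres)) 0L else nrow(x$spheres), "contact spheres,",
      if (is.null(x$reserves)) 0L else nrow(x$reserves), "reserves\n")
  cat("  total mass", format(x$total_mass), "kg; tendons",
      if (x$rigid_tendon) "rigid" else "compliant", "\n")
  invisible(x)
}

coord_names <- function(model) model$coordinates$name
n_coord <- function(model) nrow(model$coordinates)
n_muscle <- function(model) if (is.null(model$muscles)) 0L else nrow(model$muscles)
n_reserve <- function(model) if (is.null(model$reserves)) 0L else nrow(model$reserves)

#' Default planar biped gait model
#'
#' An eight-segment sagittal-plane biped (pelvis base with x/y/pitch,
#' trunk pitch, and hip-knee-ankle chains per side) actuated by the FNS
#' muscle groups of the participant-informed muscle set: iliopsoas (psoas +
#' iliacus elements), vasti (three elements) and tibialis anterior
#' bilaterally, plus sartorius and biceps femoris short head on the right
#' and tensor fasciae latae on the left. Three contact spheres per foot
#' (heel, metatarsal, toe) provide smoothed Hunt-Crossley ground contact.
#' Reserve actuators on the base and trunk stand in for walker support and
#' volitional upper-body effort; small penalized joint reserves represent
#' retained volitional control at the hips, knees and ankles. Segment and
#' muscle parameter values are representative literature-scale values for a
#' 76.2 kg, 1.84 m adult.
#'
#' @param muscle_set `"model_p"` (default, asymmetric participant-informed
#'   set), `"symmetric"` (bilateral iliopsoas, vasti, tibialis anterior
#'   only), or `"model_g"` (general-model surrogate: every group present
#'   bilaterally, used by the tracking and early predictive stages whose
#'   half-stride symmetry constraint needs left-right muscle pairing)
#' @param rigid_tendon logical, see [msk_model()]
#' @return an `msk_model`
#' @export
planar_biped <- function(muscle_set = c("model_p", "symmetric",
                                        "model_g"),
                         rigid_tendon = TRUE) {
  muscle_set <- match.arg(muscle_set)
  segments <- data.frame(
    name = c("pelvis", "trunk", "thigh_l", "shank_l", "foot_l",
             "thigh_r", "shank_r", "foot_r"),
    parent = c(NA, "pelvis", "pelvis", "thigh_l", "shank_l",
               "pelvis", "thigh_r", "shank_r"),
    mass = c(12.0, 38.4, 8.2, 3.6, 1.1, 8.2, 3.6, 1.1),
    inertia = c(0.08, 2.0, 0.14, 0.056, 0.010, 0.14, 0.056, 0.010),
    dx = c(0, 0, 0, 0, 0, 0, 0, 0),
    dy = c(0, 0.15, 0, -0.45, -0.43, 0, -0.45, -0.43),
    comx = c(0, 0, 0, 0, 0.07, 0, 0, 0.07),
    comy = c(0.05, 0.25, -0.20, -0.19, -0.04, -0.20, -0.19, -0.04),
    qsign = c(1, 1, 1, -1, 1, 1, -1, 1),
    length = c(0.15, 0.60, 0.45, 0.43, 0.20, 0.45, 0.43, 0.20),
    stringsAsFactors = FALSE
  )
  # revolute coordinate meaning: trunk pitch (+ posterior lean), hip
  # flexion (+), knee flexion (+), ankle dorsiflexion (+)
  coord_ranges <- data.frame(
    name = c("pelvis_tx", "pelvis_ty", "pelvis_rot", "trunk_q",
             "thigh_l_q", "shank_l_q", "foot_l_q",
             "thigh_r_q", "shank_r_q", "foot_r_q"),
    lo = c(-1.0, 0.60, -1.0, -1.0, -0.7, -0.05, -0.9, -0.7, -0.05, -0.9),
    hi = c(3.0, 1.20, 1.0, 1.0, 1.8, 2.2, 0.9, 1.8, 2.2, 0.9),
    speed_lo = rep(-10, 10), speed_hi = rep(10, 10),
    stringsAsFactors = FALSE
  )
  coord_ranges$speed_lo[1:2] <- -3
  coord_ranges$speed_hi[1:2] <- 3

  one_side <- function(s) {
    side <- if (s == "l") "left" else "right"
    list(
      # name, group, side, fmax, lopt, lslack, hip, knee, ankle arm
      list(paste0("psoas_", s), paste0("iliopsoas_", s), side,
           900, 0.10, 0.16, 0.045, 0, 0),
      list(paste0("iliacus_", s), paste0("iliopsoas_", s), side,
           850, 0.10, 0.10, 0.045, 0, 0),
      list(paste0("vas_med_", s), paste0("vasti_", s), side,
           1400, 0.09, 0.13, 0, -0.042, 0),
      list(paste0("vas_int_", s), paste0("vasti_", s), side,
           1400, 0.09, 0.13, 0, -0.042, 0),
      list(paste0("vas_lat_", s), paste0("vasti_", s), side,
           1700, 0.09, 0.13, 0, -0.042, 0),
      list(paste0("tib_ant_", s), paste0("ta_", s), side,
           900, 0.07, 0.22, 0, 0, 0.038),
      list(paste0("tfl_", s), paste0("tfl_", s), side,
           300, 0.095, 0.42, 0.032, 0, 0),
      list(paste0("sartorius_", s), paste0("sart_", s), side,
           400, 0.40, 0.12, 0.040, 0.035, 0),
      list(paste0("bfsh_", s), paste0("bfsh_", s), side,
           450, 0.11, 0.10, 0, 0.030, 0)
    )
  }
  mus <- c(one_side("l"), one_side("r"))
  core <- c("iliopsoas", "vasti", "ta")
  keep <- vapply(mus, function(x) {
    g <- sub("_(l|r)$", "", x[[2]])
    switch(muscle_set,
           model_g = TRUE,
           symmetric = g %in% core,
           model_p = g %in% core ||
             x[[2]] %in% c("tfl_l", "sart_r", "bfsh_r"))
  }, logical(1))
  mus <- mus[keep]
  muscles <- data.frame(
    name = vapply(mus, `[[`, "", 1),
    group = vapply(mus, `[[`, "", 2),
    side = vapply(mus, `[[`, "", 3),
    fmax = vapply(mus, `[[`, 0, 4),
    lopt = vapply(mus, `[[`, 0, 5),
    lslack = vapply(mus, `[[`, 0, 6),
    pennation = 0, tact = 0.015, tdeact = 0.060, vmax = 10,
    stringsAsFactors = FALSE
  )
  ncd <- nrow(coord_ranges)
  R <- matrix(0, ncd, nrow(muscles),
              dimnames = list(coord_ranges$name, muscles$name))
  hipc <- function(s) paste0("thigh_", s, "_q")
  kneec <- function(s) paste0("shank_", s, "_q")
  ankc <- function(s) paste0("foot_", s, "_q")
  for (i in seq_along(mus)) {
    side <- if (mus[[i]][[3]] == "left") "l" else "r"
    R[hipc(side), i] <- mus[[i]][[7]]
    R[kneec(side), i] <- mus[[i]][[8]]
    R[ankc(side), i] <- mus[[i]][[9]]
  }
  groups <- unique(data.frame(
    group = muscles$group, side = muscles$side,
    stringsAsFactors = FALSE))
  groups$method <- ifelse(groups$group %in% c("sart_r", "bfsh_r",
                                              "iliopsoas_r"),
                          "surface", "implanted")

  sph1 <- function(side) {
    data.frame(
      name = paste0(c("heel_", "met_", "toe_"), side),
      segment = paste0("foot_", side),
      x = c(-0.06, 0.10, 0.16), y = -0.06,
      radius = 0.02, stiffness = 5e4, dissipation = 1.0,
      mu_d = 0.8, mu_v = 1.0, smoothing = 1e-3, v_smooth = 0.05,
      foot = if (side == "l") "left" else "right",
      stringsAsFactors = FALSE)
  }
  spheres <- rbind(sph1("l"), sph1("r"))

  reserves <- data.frame(
    name = c("res_pelvis_tx", "res_pelvis_ty", "res_pelvis_rot",
             "res_trunk", "res_hip_l", "res_knee_l", "res_ankle_l",
             "res_hip_r", "res_knee_r", "res_ankle_r"),
    coordinate = c("pelvis_tx", "pelvis_ty", "pelvis_rot", "trunk_q",
                   "thigh_l_q", "shank_l_q", "foot_l_q",
                   "thigh_r_q", "shank_r_q", "foot_r_q"),
    max = c(250, 800, 150, 150, 60, 60, 60, 60, 60, 60),
    tag = "penalized",
    stringsAsFactors = FALSE
  )

  markers <- data.frame(
    name = c("SACR", "C7", "KNEE_l", "ANK_l", "HEEL_l", "TOE_l",
             "KNEE_r", "ANK_r", "HEEL_r", "TOE_r"),
    segment = c("pelvis", "trunk", "thigh_l", "shank_l", "foot_l",
                "foot_l", "thigh_r", "shank_r", "foot_r", "foot_r"),
    x = c(-0.10, -0.03, 0.04, 0.03, -0.06, 0.16,
          0.04, 0.03, -0.06, 0.16),
    y = c(0.03, 0.55, -0.45, -0.43, -0.04, -0.04,
          -0.45, -0.43, -0.04, -0.04),
    bony = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
             TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  msk_model(segments, base_dofs = c("tx", "ty", "rot"),
            coord_ranges = coord_ranges, muscles = muscles,
            moment_arms = R, groups = groups, spheres = spheres,
            reserves = reserves, markers = markers,
            rigid_tendon = rigid_tendon)
}

#' Neutral standing configuration of a model
#'
#' All coordinates zero except the base height, which is set so the foot
#' spheres just touch the ground.
#' @param model an `msk_model`
#' @return named coordinate vector
#' @export
standing_pose <- function(model) {
  q <- setNames(numeric(n_coord(model)), coord_names(model))
  ty <- paste0(model$segments$name[1], "_ty")
  if (ty %in% names(q) && !is.null(model$spheres)) {
    # lower the base until the deepest sphere touches
    q[ty] <- 1
    st <- cpp_sphere_state(model$compiled, q, numeric(length(q)))
    lowest <- min(st[2, ] - model$spheres$radius)
    q[ty] <- 1 - lowest
  }
  q
}

#' Left-right mirror map for states and controls
#'
#' Returns the permutation that exchanges left and right coordinates,
#' muscles and reserves (used by the stride-symmetry constraints). In the
#' planar model mirroring is a pure exchange; all signs are +1.
#'
#' @param model an `msk_model`
#' @return list with integer permutations `coord`, `muscle`, `reserve`
#' @export
mirror_map <- function(model) {
  swap_lr <- function(nms) {
    out <- nms
    li <- grepl("_l(_|$)", nms)
    ri <- grepl("_r(_|$)", nms)
    out[li] <- sub("_l(_|$)", "_r\\1", nms[li])
    out[ri] <- sub("_r(_|$)", "_l\\1", nms[ri])
    idx <- match(out, nms)
    if (anyNA(idx)) {
      stop("missing mirror pairing for: ",
           paste(nms[is.na(idx)], collapse = ", "))
    }
    idx
  }
  list(
    coord = swap_lr(coord_names(model)),
    muscle = if (n_muscle(model) > 0L) swap_lr(model$muscles$name)
             else integer(),
    reserve = if (n_reserve(model) > 0L) swap_lr(model$reserves$name)
              else integer()
  )
}

# ---------------------------------------------------------------------------
# model config round trip (YAML)
# ---------------------------------------------------------------------------

#' Read or write a model description file
#'
#' The model schema is a YAML document with sections `segments`,
#' `base_dofs`, `coordinates`, `muscles` (including per-coordinate moment
#' arms), `groups`, `spheres`, `reserves`, `markers`, `gravity` and
#' `rigid_tendon`, mirroring the arguments of [msk_model()].
#'
#' @param path file path
#' @return `read_msk_model` returns an `msk_model`
#' @export
read_msk_model <- function(path) {
  y <- yaml::read_yaml(path)
  df <- function(x) {
    if (is.null(x)) return(NULL)
    as.data.frame(do.call(rbind, lapply(x, function(r) {
      r[vapply(r, is.null, TRUE)] <- NA
      r
    })), stringsAsFactors = FALSE) -> d
    for (j in names(d)) d[[j]] <- unlist(d[[j]], use.names = FALSE)
    d
  }
  R <- NULL
  muscles <- NULL
  if (!is.null(y$muscles)) {
    plain <- lapply(y$muscles, function(r) {
      r$moment_arms <- NULL
      r
    })
    muscles <- df(plain)
    cn <- vapply(y$coordinates, `[[`, "", "name")
    R <- matrix(0, length(cn), length(y$muscles),
                dimnames = list(cn, muscles$name))
    for (i in seq_along(y$muscles)) {
      ma <- y$muscles[[i]]$moment_arms
      for (cname in names(ma)) R[cname, i] <- ma[[cname]]
    }
  }
  msk_model(
    segments = df(y$segments), base_dofs = unlist(y$base_dofs),
    coord_ranges = df(y$coordinates), muscles = muscles,
    moment_arms = R, groups = df(y$groups), spheres = df(y$spheres),
    reserves = df(y$reserves), markers = df(y$markers),
    gravity = y$gravity %||% 9.81,
    rigid_tendon = y$rigid_tendon %||% TRUE,
    symmetric = y$symmetric %||% TRUE
  )
}

#' @rdname read_msk_model
#' @param model an `msk_model`
#' @export
write_msk_model <- function(model, path) {
  rows <- function(d) {
    if (is.null(d)) return(NULL)
    lapply(seq_len(nrow(d)), function(i) {
      r <- as.list(d[i, , drop = FALSE])
      lapply(r, function(v) if (is.na(v)) NULL else unname(v))
    })
  }
  mus <- NULL
  if (!is.null(model$muscles)) {
    mus <- rows(model$muscles)
    for (i in seq_along(mus)) {
      arms <- model$moment_arms[, i]
      mus[[i]]$moment_arms <- as.list(arms[arms != 0])
    }
  }
  y <- list(
    segments = rows(model$segments),
    base_dofs = as.list(model$base_dofs),
    coordinates = rows(model$coordinates[, c("name", "lo", "hi",
                                             "speed_lo", "speed_hi")]),
    muscles = mus, groups = rows(model$groups),
    spheres = rows(model$spheres), reserves = rows(model$reserves),
    markers = rows(model$markers),
    gravity = model$gravity, rigid_tendon = model$rigid_tendon,
    symmetric = model$symmetric
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
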