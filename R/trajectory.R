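# Trajectory container and tab-delimited motion-file IO (STO/MOT-style
# time-series tables and TRC marker files).

#' Discretized model trajectory
#'
#' A time grid with per-node states (coordinates `q_*`, speeds `u_*`,
#' activations `act_*`, and in compliant-tendon mode normalized tendon
#' forces `ft_*`) and controls (muscle excitations `exc_*`, reserve
#' controls `res_*`, and optionally implicit accelerations `acc_*` and
#' tendon-force derivatives `dft_*`).
#'
#' @param time strictly increasing time grid, s
#' @param states numeric matrix (length(time) rows) with named columns
#' @param controls numeric matrix with named columns
#' @param model the `msk_model` the trajectory belongs to
#' @return object of class `fns_trajectory`
#' @export
trajectory <- function(time, states, controls, model) {
  states <- as.matrix(states)
  controls <- as.matrix(controls)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (nrow(states) != length(time) || nrow(controls) != length(time)) {
    stop("states/controls must have one row per time point")
  }
  qn <- paste0("q_", coord_names(model))
  un <- paste0("u_", coord_names(model))
  if (!all(c(qn, un) %in% colnames(states))) {
    stop("states must contain q_ and u_ columns for every coordinate")
  }
  if (n_muscle(model) > 0L) {
    en <- paste0("exc_", model$muscles$name)
    if (!all(en %in% colnames(controls))) {
      stop("controls must contain exc_ columns for every muscle")
    }
    e <- controls[, en, drop = FALSE]
    if (any(e < -1e-9 | e > 1 + 1e-9)) {
      stop("muscle excitations must lie within [0, 1]")
    }
  }
  structure(list(time = time, states = states, controls = controls,
                 model = model),
            class = "fns_trajectory")
}

#' @export
print.fns_trajectory <- function(x, ...) {
  cat("<fns_trajectory>", length(x$time), "nodes over [",
      format(x$time[1]), ",", format(x$time[length(x$time)]), "] s;",
      ncol(x$states), "states,", ncol(x$controls), "controls\n")
  invisible(x)
}

traj_states <- function(traj, prefix) {
  idx <- grepl(paste0("^", prefix, "_"), colnames(traj$states))
  t(traj$states[, idx, drop = FALSE])
}

traj_controls <- function(traj, prefix) {
  idx <- grepl(paste0("^", prefix, "_"), colnames(traj$controls))
  t(traj$controls[, idx, drop = FALSE])
}

# Q and U as (ncoord x P) in model coordinate order
traj_Q <- function(traj) {
  t(traj$states[, paste0("q_", coord_names(traj$model)), drop = FALSE])
}
traj_U <- function(traj) {
  t(traj$states[, paste0("u_", coord_names(traj$model)), drop = FALSE])
}
traj_ACT <- function(traj) {
  nm <- n_muscle(traj$model)
  if (nm == 0L) return(matrix(0, 0, length(traj$time)))
  t(traj$states[, paste0("act_", traj$model$muscles$name), drop = FALSE])
}
traj_EXC <- function(traj) {
  nm <- n_muscle(traj$model)
  if (nm == 0L) return(matrix(0, 0, length(traj$time)))
  t(traj$controls[, paste0("exc_", traj$model$muscles$name), drop = FALSE])
}

# ---------------------------------------------------------------------------
# STO/MOT-style tab-delimited tables
# ---------------------------------------------------------------------------

#' Read or write an STO/MOT-style time-series table
#'
#' Tab-delimited text with a small header (`name`, `nRows`, `nColumns`,
#' `endheader`) followed by column names; the first column is time.
#'
#' @param x data.frame whose first column is `time`
#' @param path file path
#' @param name table name recorded in the header
#' @return `read_sto` returns a data.frame
#' @export
write_sto <- function(x, path, name = "table") {
  stopifnot(is.data.frame(x) || is.matrix(x))
  x <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               paste0("nRows=", nrow(x)),
               paste0("nColumns=", ncol(x)),
               "inDegrees=no",
               "endheader",
               paste(colnames(x), collapse = "\t")), con)
  utils::write.table(format(x, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sto
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "endheader")[1]
  if (is.na(hdr_end)) stop("not an STO/MOT table: missing endheader")
  cn <- strsplit(lines[hdr_end + 1], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(text = lines[(hdr_end + 2):length(lines)],
                           sep = "\t", col.names = cn,
                           check.names = FALSE)
  dat
}

#' Convert a trajectory to and from a time-series table
#'
#' @param traj an `fns_trajectory`
#' @return data.frame with `time`, state and control columns
#' @export
trajectory_table <- function(traj) {
  data.frame(time = traj$time, traj$states, traj$controls,
             check.names = FALSE)
}

#' @rdname trajectory_table
#' @param tab data.frame as produced by [trajectory_table()] or
#'   [read_sto()]
#' @param model the model the trajectory belongs to
#' @export
table_trajectory <- function(tab, model) {
  state_cols <- grepl("^(q|u|act|ft)_", colnames(tab))
  ctrl_cols <- grepl("^(exc|res|acc|dft)_", colnames(tab))
  trajectory(tab$time,
             as.matrix(tab[, state_cols, drop = FALSE]),
             as.matrix(tab[, ctrl_cols, drop = FALSE]), model)
}

# ---------------------------------------------------------------------------
# TRC marker files
# ---------------------------------------------------------------------------

#' Read or write a TRC marker trajectory file
#'
#' Standard tab-delimited TRC layout: a five-line header describing rates
#' and marker names, then `Frame#`, `Time` and X/Y/Z triplets per marker.
#' Planar marker sets are written with Z = 0.
#'
#' @param markers named list of n x 2 or n x 3 matrices (m), or a
#'   data.frame with columns `<name>_x`, `<name>_y`
#' @param time time vector, s
#' @param path file path
#' @param rate sampling rate, Hz
#' @export
write_trc <- function(markers, time, path, rate = 100) {
  if (is.data.frame(markers)) {
    nm <- unique(sub("_[xyz]$", "", colnames(markers)))
    markers <- lapply(setNames(nm, nm), function(k) {
      cbind(markers[[paste0(k, "_x")]], markers[[paste0(k, "_y")]])
    })
  }
  nms <- names(markers)
  n <- length(time)
  mk3 <- lapply(markers, function(mm) {
    mm <- as.matrix(mm)
    if (ncol(mm) == 2L) mm <- cbind(mm, 0)
    mm
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
          sep = "\t"),
    paste(rate, rate, n, length(nms), "m", rate, 1, n, sep = "\t"),
    paste0("Frame#\tTime\t",
           paste(vapply(nms, function(k) paste0(k, "\t\t"), ""),
                 collapse = "\t")),
    paste0("\t\t", paste(unlist(lapply(seq_along(nms), function(i) {
      paste0(c("X", "Y", "Z"), i)
    })), collapse = "\t"))
  ), con)
  body <- cbind(seq_len(n), time, do.call(cbind, mk3))
  utils::write.table(format(body, digits = 12, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_trc
#' @return `read_trc` returns a list with `time`, `rate` and `markers` (a
#'   named list of n x 3 matrices)
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  rate <- as.numeric(meta[1])
  hdr <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  nms <- hdr[-(1:2)]
  nms <- nms[nms != ""]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t")
  time <- dat[[2]]
  markers <- list()
  for (i in seq_along(nms)) {
    markers[[nms[i]]] <- as.matrix(dat[, 2 + (3 * i - 2):(3 * i)])
  }
  markers <- lapply(markers, function(mm) {
    dimnames(mm) <- list(NULL, c("x", "y", "z"))
    mm
  })
  list(time = time, rate = rate, markers = markers)
}
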