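# Nonlinear-program solution by an augmented-Lagrangian method with
# sparse Levenberg-Marquardt inner iterations. All cost subterms are
# integrals of squares, so the objective is handled natively as a
# least-squares stack; equality constraints carry multipliers, inequality
# constraints (required >= 0) use the positive-part augmented form.

# sparse Jacobian machinery -------------------------------------------------

# Build column supports, the coloring and the dgCMatrix skeleton from the
# row -> collocation-point map produced by the transcription.
build_sparsity <- function(nlp) {
  rowcols <- nlp$row_columns()
  nrows <- length(rowcols)
  nvar <- nlp$n_decision
  # invert to column supports (sorted unique rows per column)
  col_rows <- vector("list", nvar)
  rlen <- lengths(rowcols)
  rr <- rep.int(seq_len(nrows), rlen)
  cc <- unlist(rowcols, use.names = FALSE)
  o <- order(cc, rr)
  cc <- cc[o]
  rr <- rr[o]
  keep <- c(TRUE, cc[-1] != cc[-length(cc)] | rr[-1] != rr[-length(rr)])
  cc <- cc[keep]
  rr <- rr[keep]
  splits <- split(rr, cc)
  col_rows[as.integer(names(splits))] <- splits
  col_rows[vapply(col_rows, is.null, TRUE)] <- list(integer())
  # greedy coloring: two columns share a color only if no residual row
  # depends on both
  color <- integer(nvar)
  occ <- list()
  ncolor <- 0L
  for (cl in seq_len(nvar)) {
    rows <- col_rows[[cl]]
    k <- 1L
    repeat {
      if (k > ncolor) {
        ncolor <- k
        occ[[k]] <- logical(nrows)
        break
      }
      if (!any(occ[[k]][rows])) break
      k <- k + 1L
    }
    color[cl] <- k
    occ[[k]][rows] <- TRUE
  }
  colors <- split(seq_len(nvar), color)
  # dgCMatrix skeleton (column compressed)
  nnz_col <- lengths(col_rows)
  ptr <- c(0L, cumsum(nnz_col))
  ivec <- unlist(col_rows, use.names = FALSE) - 1L
  color_rows <- lapply(colors, function(g) {
    unlist(col_rows[g], use.names = FALSE)
  })
  color_pos <- lapply(colors, function(g) {
    unlist(lapply(g, function(cl2) {
      if (nnz_col[cl2]) (ptr[cl2] + 1L):ptr[cl2 + 1L] else integer()
    }), use.names = FALSE)
  })
  template <- Matrix::sparseMatrix(i = ivec, p = ptr,
                                   x = numeric(length(ivec)),
                                   dims = c(nrows, nvar), index1 = FALSE)
  list(col_rows = col_rows, colors = colors, ptr = ptr, ivec = ivec,
       color_rows = color_rows, color_pos = color_pos,
       template = template, nrows = nrows, nvar = nvar)
}

fd_jacobian <- function(eval_stack, z, r0, sp, delta = 1e-6) {
  xvals <- numeric(length(sp$ivec))
  for (k in seq_along(sp$colors)) {
    zp <- z
    zp[sp$colors[[k]]] <- zp[sp$colors[[k]]] + delta
    d <- (eval_stack(zp) - r0) / delta
    xvals[sp$color_pos[[k]]] <- d[sp$color_rows[[k]]]
  }
  J <- sp$template
  J@x <- xvals
  J
}

# augmented-Lagrangian residual transform: raw stack -> ALM stack
alm_weight <- function(raw, idx, lam_eq, lam_in, rho) {
  r <- raw
  if (length(idx$eq)) {
    r[idx$eq] <- sqrt(rho / 2) * (raw[idx$eq] + lam_eq / rho)
  }
  if (length(idx$ineq)) {
    r[idx$ineq] <- sqrt(rho / 2) * pmax(0, lam_in / rho - raw[idx$ineq])
  }
  r
}

alm_row_scale <- function(raw, idx, lam_in, rho, nrows) {
  s <- rep(1, nrows)
  if (length(idx$eq)) s[idx$eq] <- sqrt(rho / 2)
  if (length(idx$ineq)) {
    act <- (lam_in / rho - raw[idx$ineq]) > 0
    s[idx$ineq] <- ifelse(act, -sqrt(rho / 2), 0)
  }
  s
}

#' Solve a transcribed optimal-control problem
#'
#' Augmented-Lagrangian outer iterations with sparse finite-difference
#' Levenberg-Marquardt inner solves. Deterministic for identical problem,
#' guess and tolerances. Failures (iteration limit, stalled infeasibility)
#' are reported in the solution status, never as an exception.
#'
#' @param problem an `fns_ocp`, or an already transcribed `fns_nlp`
#' @param guess optional `fns_trajectory` warm start (overrides
#'   `problem$guess`); the default initial iterate is the midpoint of the
#'   variable bounds
#' @return object of class `fns_ocs` with fields `trajectory`,
#'   `objective`, `subterms`, `status`, `max_violation`, `iterations`,
#'   `infeasibility_history`
#' @export
solve_ocp <- function(problem, guess = NULL) {
  nlp <- if (inherits(problem, "fns_nlp")) problem else transcribe(problem)
  prob <- nlp$problem
  opts <- nlp$options
  guess <- guess %||% prob$guess
  z <- nlp$guess_z(guess)

  kinds <- vapply(prob$constraints, `[[`, "", "kind")
  has_knees <- "knees" %in% kinds
  knees_con <- if (has_knees) {
    prob$constraints[[which(kinds == "knees")[1]]]
  } else NULL
  knee_events_of <- function(traj) {
    on <- tryCatch(double_stance_onsets(traj, opts$knee_threshold),
                   error = function(e) list())
    both <- isTRUE(knees_con$both_knees %||% FALSE)
    sn <- nlp$state_names
    col_of <- c(left = match("q_shank_l_q", sn),
                right = match("q_shank_r_q", sn))
    ev <- NULL
    for (side in c("left", "right")) {
      nodes <- on[[side]]
      if (!length(nodes)) next
      cols <- if (both) unname(col_of) else unname(col_of[[side]])
      ev <- rbind(ev, as.matrix(expand.grid(col = cols, node = nodes)))
    }
    if (is.null(ev)) {
      # no strike found in the current iterate: anchor both cycle ends
      ev <- cbind(rep(unname(col_of), 2), rep(c(1L, nlp$P), each = 2))
    }
    ev <- ev[!is.na(ev[, 1]), , drop = FALSE]
    ev[order(ev[, 2], ev[, 1]), , drop = FALSE]
  }
  if (has_knees) {
    # freeze knee events from the current iterate between outer
    # iterations; start from the guess trajectory
    nlp$set_knee_events(knee_events_of(nlp$build_trajectory(z)))
  }

  raw0 <- nlp$eval_raw(z)
  # equality block = fixed equalities plus slack-completed clearance rows;
  # inequality block = knee-event hinges only
  make_idx <- function(n_knee) {
    ne <- nlp$n_eq + nlp$n_slack
    list(cost = seq_len(nlp$n_cost),
         eq = nlp$n_cost + seq_len(ne),
         ineq = nlp$n_cost + ne + seq_len(n_knee))
  }
  idx <- make_idx(length(raw0$ineq))
  verbose <- isTRUE(opts$verbose)
  eval_stack <- nlp$eval_vec
  sp <- build_sparsity(nlp)
  stopifnot(sp$nrows == nlp$n_cost + length(raw0$eq) +
              length(raw0$clearance) + length(raw0$ineq))

  lam_eq <- numeric(nlp$n_eq + nlp$n_slack)
  lam_in <- numeric(length(raw0$ineq))
  rho <- opts$rho0
  infeas <- function(raw) {
    v <- 0
    if (length(idx$eq)) v <- max(v, max(abs(raw[idx$eq])))
    if (length(idx$ineq)) v <- max(v, max(pmax(0, -raw[idx$ineq])))
    v
  }
  raw <- eval_stack(z)
  inf_hist <- infeas(raw)
  total_inner <- 0L
  status <- "max_outer_reached"
  phi_prev <- Inf

  for (outer in seq_len(opts$max_outer)) {
    # ----- inner sparse LM on the ALM least-squares problem -------------
    mu <- 1e-3
    inner_ok <- FALSE
    r_alm <- alm_weight(raw, idx, lam_eq, lam_in, rho)
    phi <- sum(r_alm^2)
    for (it in seq_len(opts$max_inner)) {
      J <- fd_jacobian(eval_stack, z, raw, sp)
      rs <- alm_row_scale(raw, idx, lam_in, rho, sp$nrows)
      Js <- J * rs
      g <- as.numeric(Matrix::crossprod(Js, r_alm))
      gnorm <- max(abs(g))
      if (gnorm < opts$opt_tol * max(1, sqrt(phi))) {
        inner_ok <- TRUE
        break
      }
      H <- Matrix::crossprod(Js)
      dH <- Matrix::diag(H)
      accepted <- FALSE
      for (trial in 1:12) {
        Hd <- H + Matrix::Diagonal(x = mu * pmax(dH, 1e-8) + 1e-10)
        dz <- tryCatch(
          as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Hd),
                                                    perm = TRUE), -g)),
          error = function(e) NULL)
        if (!is.null(dz)) {
          stepn <- max(abs(dz))
          if (stepn > opts$max_step) dz <- dz * (opts$max_step / stepn)
          znew <- z + dz
          rawn <- eval_stack(znew)
          rn <- alm_weight(rawn, idx, lam_eq, lam_in, rho)
          phin <- sum(rn^2)
          if (is.finite(phin) && phin < phi) {
            z <- znew
            raw <- rawn
            r_alm <- rn
            phi <- phin
            mu <- max(mu / 3, 1e-10)
            accepted <- TRUE
            break
          }
        }
        mu <- mu * 8
      }
      total_inner <- total_inner + 1L
      if (!accepted) break
    }
    cur_inf <- infeas(raw)
    inf_hist <- c(inf_hist, cur_inf)
    if (verbose) {
      message(sprintf(
        "outer %2d: phi %.5g infeas %.3e rho %.1e inner %d%s",
        outer, phi, cur_inf, rho, it, if (inner_ok) " (inner ok)" else ""))
    }
    phi_rel <- abs(phi_prev - phi) / max(phi, 1e-12)
    phi_prev <- phi
    if (cur_inf < opts$feas_tol && (inner_ok || phi_rel < 1e-4)) {
      status <- "converged"
      break
    }
    # multiplier and penalty updates; multipliers advance only when the
    # inner solve actually reduced the infeasibility (otherwise they
    # accumulate bias), and are kept bounded
    prev <- inf_hist[length(inf_hist) - 1L]
    if (cur_inf <= prev) {
      if (length(idx$eq)) {
        lam_eq <- pmin(pmax(lam_eq + rho * raw[idx$eq], -1e6), 1e6)
      }
      if (length(idx$ineq)) {
        lam_in <- pmin(pmax(0, lam_in - rho * raw[idx$ineq]), 1e6)
      }
    }
    if (cur_inf > 0.5 * prev) rho <- min(rho * 5, 1e9)
    if (has_knees && outer <= opts$knee_refresh_outers) {
      traj_cur <- nlp$build_trajectory(z)
      nodes <- knee_events_of(traj_cur)
      if (nrow(nodes)) {
        old <- nlp$get_knee_events()
        if (!identical(unname(old), unname(matrix(as.integer(nodes),
                                                  ncol = 2)))) {
          nlp$set_knee_events(nodes)
          # inequality layout may change size; rebuild bookkeeping
          raw_l <- nlp$eval_raw(z)
          idx <- make_idx(length(raw_l$ineq))
          lam_in <- numeric(length(raw_l$ineq))
          sp <- build_sparsity(nlp)
          raw <- eval_stack(z)
        }
      }
    }
    if (outer == opts$max_outer) status <- "max_outer_reached"
  }

  traj <- nlp$build_trajectory(z)
  objective <- sum(raw[idx$cost]^2)
  breakdown <- eq_violation_breakdown(nlp, raw, idx)
  final_inf <- infeas(raw)
  if (status != "converged" && final_inf < opts$feas_tol * 100) {
    status <- "feasible_not_optimal"
  }
  sub <- tryCatch(
    solution_subterms(traj, prob),
    error = function(e) NULL)
  structure(list(
    trajectory = traj, objective = objective, subterms = sub,
    status = status, max_violation = final_inf,
    violation_breakdown = breakdown,
    iterations = total_inner, infeasibility_history = inf_hist,
    z = z, nlp = nlp
  ), class = "fns_ocs")
}

# max |residual| per equality-constraint family, for diagnostics
eq_violation_breakdown <- function(nlp, raw, idx) {
  eqv <- abs(raw[idx$eq])
  nxN <- nlp$nx * nlp$problem$mesh_intervals
  groups <- list(defect_hermite = seq_len(nxN),
                 defect_simpson = nxN + seq_len(nxN),
                 dynamics = 2 * nxN + seq_len(nlp$nq * nlp$P))
  used <- 2 * nxN + nlp$nq * nlp$P
  if (nlp$compliant) {
    groups$tendon <- used + seq_len(nlp$nmus * nlp$P)
    used <- used + nlp$nmus * nlp$P
  }
  n_bnd <- length(eqv) - used - nlp$n_slack
  if (n_bnd > 0L) groups$boundary <- used + seq_len(n_bnd)
  if (nlp$n_slack > 0L) {
    groups$clearance <- used + n_bnd + seq_len(nlp$n_slack)
  }
  out <- vapply(groups, function(ii) if (length(ii)) max(eqv[ii]) else 0,
                0)
  if (length(idx$ineq)) {
    out <- c(out, inequality = max(pmax(0, -raw[idx$ineq])))
  }
  out
}

# per-subterm cost report of a solution (Simpson quadrature, matching the
# transcription)
solution_subterms <- function(traj, prob) {
  w <- prob$weights
  sub <- list(
    J_s = suppressMessages(eval_synergy(traj, quadrature = "simpson")),
    J_p = eval_energy_penalty(traj, quadrature = "simpson"),
    J_ad = suppressMessages(eval_aux_deriv(traj, quadrature = "simpson"))
  )
  if (prob$mode == "tracking") {
    sub$J_mt <- eval_marker_tracking(traj, prob$ref, prob$markers,
                                     quadrature = "simpson")
    sub$J_ct <- eval_contact_tracking(traj, prob$ref,
                                      quadrature = "simpson")
    sub$J_e <- eval_effort(traj, w, divide_by_distance = FALSE,
                           quadrature = "simpson")
  } else {
    com <- com_state(traj$model, traj_Q(traj))
    d <- max(abs(com["x", ncol(com)] - com["x", 1]), 0.05)
    sub$J_e <- eval_effort(traj, w, d = d, divide_by_distance = TRUE,
                           quadrature = "simpson")
    sub$distance <- d
  }
  sub
}

#' @export
print.fns_ocs <- function(x, ...) {
  cat("<fns_ocs>", x$status, "| objective", format(x$objective),
      "| max violation", format(x$max_violation),
      "| inner iterations", x$iterations, "\n")
  invisible(x)
}
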