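# small numerical helpers shared across modules

#' Quadrature weights on a time grid
#'
#' Trapezoidal weights on an arbitrary strictly increasing grid, or Simpson
#' weights on a uniform grid with an odd number of points.
#'
#' @param time strictly increasing numeric vector
#' @param rule `"trapezoid"` (default) or `"simpson"`
#' @return numeric vector of weights such that `sum(w * f)` approximates the
#'   integral of `f` over the grid span
#' @export
quadrature_weights <- function(time, rule = c("trapezoid", "simpson")) {
  rule <- match.arg(rule)
  n <- length(time)
  if (n < 2L) stop("need at least two time points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (rule == "trapezoid") {
    dt <- diff(time)
    w <- numeric(n)
    w[1] <- dt[1] / 2
    w[n] <- dt[n - 1] / 2
    if (n > 2L) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
    return(w)
  }
  if (n %% 2L == 0L) stop("Simpson rule needs an odd number of points")
  h <- diff(time)
  if (diff(range(h)) > 1e-8 * mean(h)) {
    stop("Simpson rule needs a uniform grid")
  }
  h <- mean(h)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

#' @keywords internal
trapz <- function(time, values) {
  sum(quadrature_weights(time) * values)
}

# linear interpolation of the columns of a matrix onto a new grid
interp_cols <- function(time, values, new_time) {
  values <- as.matrix(values)
  out <- matrix(NA_real_, length(new_time), ncol(values))
  for (j in seq_len(ncol(values))) {
    out[, j] <- approx(time, values[, j], xout = new_time, rule = 2)$y
  }
  colnames(out) <- colnames(values)
  out
}

# numerical time derivative (central differences, one-sided at the ends)
grad_time <- function(time, values) {
  n <- length(time)
  if (n < 2L) stop("need at least two samples")
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / (time[2] - time[1])
  d[n] <- (values[n] - values[n - 1]) / (time[n] - time[n - 1])
  if (n > 2L) {
    d[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) /
      (time[3:n] - time[1:(n - 2)])
  }
  d
}

sigmoid <- function(z) 1 / (1 + exp(-z))
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed the RNG for the duration of a call, restoring global state after
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite values in ", what, call. = FALSE)
  }
  invisible(x)
}
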