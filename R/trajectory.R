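#' Uniform-grid time courses of model species
#'
#' A light container for simulated concentration time courses: a strictly
#' increasing uniform time grid (hours) and one non-negative series per
#' species.
#'
#' @param time Numeric time grid in hours, uniform step.
#' @param species Numeric matrix, one column per species (named).
#' @param dt Grid step in hours (checked against `time`).
#' @return An object of class `trajectory` with elements `time`, `species`
#'   and `dt`.
#' @export
trajectory <- function(time, species, dt = NULL) {
  species <- as.matrix(species)
  if (length(time) != nrow(species))
    stop("time grid and species series differ in length")
  steps <- diff(time)
  if (length(steps) && (any(steps <= 0) ||
                        max(steps) - min(steps) > 1e-8 * max(steps)))
    stop("time grid must be strictly increasing and uniform")
  if (is.null(dt)) dt <- steps[1]
  if (any(species < 0)) stop("concentrations must be non-negative")
  structure(list(time = time, species = species, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d points, dt = %g h, t in [%g, %g] h\n",
              length(x$time), x$dt, x$time[1], x$time[length(x$time)]))
  cat("species:", paste(colnames(x$species), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a trajectory to a time window
#' @param traj A `trajectory`.
#' @param from,to Window bounds in hours (inclusive).
#' @return A `trajectory`.
#' @export
window_trajectory <- function(traj, from = -Inf, to = Inf) {
  keep <- traj$time >= from & traj$time <= to
  trajectory(traj$time[keep], traj$species[keep, , drop = FALSE], traj$dt)
}

# species g at time t - tau, linearly interpolated on the uniform grid;
# times before the grid start fall back to the first value (the constant
# pre-simulation history)
delayed_series <- function(traj, g, tau) {
  x <- traj$species[, g]
  if (tau == 0) return(x)
  u <- (traj$time - tau - traj$time[1]) / traj$dt + 1
  u <- pmin(pmax(u, 1), length(x))
  lo <- floor(u)
  fr <- u - lo
  hi <- pmin(lo + 1, length(x))
  x[lo] * (1 - fr) + x[hi] * fr
}

#' Write or read a trajectory as TSV
#'
#' The format is a header line `time_h` plus one column per species,
#' tab-separated.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time_h = traj$time, traj$species, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (names(df)[1] != "time_h") stop("not a trajectory TSV (no time_h column)")
  trajectory(df[[1]], as.matrix(df[, -1, drop = FALSE]))
}

#' Integrate the delayed clock model
#'
#' Method-of-steps integration of the five coupled delay-differential
#' equations with classical fixed-step RK4; delayed regulator levels are
#' looked up by cubic interpolation of the accumulated solution grid. The
#' pre-simulation history is constant (default 1 for every species, the
#' basal steady state of the normalized model). Genes with `tau = 0` are
#' treated as instantaneous couplings, so the all-zero-delay limit of the
#' integrator is a plain ODE solve.
#'
#' @param params A [clock_parameters()] object.
#' @param history Constant history level(s): scalar or named numeric of
#'   length 5.
#' @param t_end Final time (hours); should cover the transient plus at
#'   least 5 cycles for descriptor extraction.
#' @param dt Step size in hours; must satisfy `dt <= 0.1` and
#'   `dt <= min(positive delay)/4`.
#' @return A [trajectory] with species `Bmal1`, `RevErba`, `Per2`, `Cry1`,
#'   `Dbp`.
#' @export
simulate_clock <- function(params, history = 1, t_end = 480, dt = 0.05) {
  stopifnot(inherits(params, "clock_parameters"))
  if (dt > 0.1) stop("dt must be <= 0.1 h")
  pos_tau <- params$delay[params$delay > 0]
  if (length(pos_tau) && dt > min(pos_tau) / 4)
    stop("dt must be <= min(positive delay)/4")
  if (length(history) == 1) history <- rep(history, 5)
  history <- unname(history[if (is.null(names(history))) 1:5 else GENES])
  if (anyNA(history) || any(history < 0))
    stop("history must be non-negative for all species")
  X <- simulate_clock_cpp(unname(params$degradation), unname(params$delay),
                          unname(params$strengths), unname(params$sites),
                          history, t_end, dt)
  colnames(X) <- GENES
  trajectory(seq(0, by = dt, length.out = nrow(X)), X, dt)
}
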