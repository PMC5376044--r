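#' Parameters of a clock-controlled gene
#'
#' A CCG is a single extra species driven by the core clock through one or
#' more modulation factors:
#' `dC/dt = d_ccg * (M_C(t) - C)` with `M_C` the product of the selected
#' drivers, each evaluated on clock species delayed by the driver's own
#' action delay. Gene-to-gene variability of `a_ccg` (promoter strength),
#' `d_ccg` (mRNA half-life) and the delays is what spreads the peak phases
#' of output genes.
#'
#' @param drivers List of driver configurations keyed by
#'   `"rre"`, `"ebox"`, `"dbox"`. Each driver is a list with elements
#'   `strength` (`a_ccg` for that element), `sites`, `delay` (h), and for
#'   the activating drivers `fold`; the E-box driver additionally takes
#'   repressor strengths `strength_per` and `strength_cry` (default 1).
#' @param d_ccg Degradation rate, per hour, in `(0, 2]`.
#' @return Object of class `ccg_parameters`.
#' @examples
#' ccg_parameters(list(rre = list(strength = 1, sites = 1, delay = 4)),
#'                d_ccg = 0.4)
#' @export
ccg_parameters <- function(drivers, d_ccg = 0.4) {
  if (!length(drivers)) stop("at least one driver is required")
  if (!all(names(drivers) %in% c("rre", "ebox", "dbox")))
    stop("drivers must be a subset of rre, ebox, dbox")
  if (d_ccg <= 0 || d_ccg > 2) stop("d_ccg must lie in (0, 2]")
  drivers <- lapply(drivers, function(d) {
    d$sites <- if (is.null(d$sites)) 1L else as.integer(d$sites)
    d$delay <- if (is.null(d$delay)) 0 else d$delay
    if (is.null(d$strength) || d$strength <= 0)
      stop("each driver needs a positive strength")
    d
  })
  structure(list(drivers = drivers, d_ccg = d_ccg),
            class = "ccg_parameters")
}

# production term of a CCG on the clock grid
ccg_modulation <- function(clock_traj, ccg) {
  M <- rep(1, length(clock_traj$time))
  dv <- ccg$drivers
  if (!is.null(dv$rre)) {
    R <- delayed_series(clock_traj, "RevErba", dv$rre$delay)
    M <- M * rre_modulator(R, dv$rre$strength, dv$rre$sites)
  }
  if (!is.null(dv$ebox)) {
    e <- dv$ebox
    B <- delayed_series(clock_traj, "Bmal1", e$delay)
    P <- delayed_series(clock_traj, "Per2", e$delay)
    C <- delayed_series(clock_traj, "Cry1", e$delay)
    aP <- if (is.null(e$strength_per)) 1 else e$strength_per
    aC <- if (is.null(e$strength_cry)) 1 else e$strength_cry
    M <- M * ebox_modulator(B, P, C, e$strength, aP, aC, e$fold, e$sites)
  }
  if (!is.null(dv$dbox)) {
    b <- dv$dbox
    D <- delayed_series(clock_traj, "Dbp", b$delay)
    M <- M * dbox_modulator(D, b$strength, b$fold, b$sites)
  }
  M
}

#' Simulate a clock-controlled gene on a clock trajectory
#'
#' Integrates `dC/dt = d_ccg * (M_C(t) - C)` exactly on the clock grid
#' (the linear equation is solved with an exponential step, treating
#' `M_C` as linear within each step).
#'
#' @param clock_traj A [trajectory] of the core clock covering the driver
#'   delays.
#' @param ccg A [ccg_parameters()] object.
#' @param c0 Initial level.
#' @return A single-species [trajectory] named `CCG`.
#' @export
simulate_ccg <- function(clock_traj, ccg, c0 = 1) {
  stopifnot(inherits(clock_traj, "trajectory"),
            inherits(ccg, "ccg_parameters"))
  needed <- c(rre = "RevErba", ebox = "Bmal1", dbox = "Dbp")
  miss <- setdiff(needed[names(ccg$drivers)], colnames(clock_traj$species))
  if (length(miss))
    stop("driver species absent from trajectory: ",
         paste(miss, collapse = ", "))
  M <- ccg_modulation(clock_traj, ccg)
  dt <- clock_traj$dt
  d <- ccg$d_ccg
  E <- exp(-d * dt)
  # exact step for M linear within [t, t+dt]:
  # C_{k+1} = (C_k - M_k + c/d) E + M_k + c dt - c/d, c = (M_{k+1}-M_k)/dt
  cc <- diff(M) / dt
  b <- (M[-length(M)] - cc / d) * (1 - E) + cc * dt
  C <- as.numeric(filter(b, E, method = "recursive", init = c0))
  trajectory(clock_traj$time, cbind(CCG = c(c0, C)), dt)
}

#' Peak phase and relative amplitude of a CCG
#'
#' Measured over the last clock cycle, with phases mapped through the
#' clock's CT anchor.
#'
#' @param clock_traj Clock [trajectory] the CCG was driven by.
#' @param ccg_traj Output of [simulate_ccg()].
#' @param ct CT mapping of the clock (attribute of
#'   [extract_rhythm_descriptors()] output).
#' @param period Clock period (h).
#' @return List with `phase` (CT h), `relamp`, and `flat` (logical: no
#'   measurable rhythm, relative amplitude below 1e-3).
#' @export
ccg_peak_phase <- function(clock_traj, ccg_traj, ct, period) {
  last <- window_trajectory(ccg_traj, from = max(ccg_traj$time) - period)
  x <- last$species[, 1]
  relamp <- (max(x) - min(x)) / (max(x) + min(x))
  if (!is.finite(relamp) || relamp < 1e-3)
    return(list(phase = NA_real_, relamp = relamp, flat = TRUE))
  pk <- find_peaks(last$time, x, min_level = min(x))
  if (!nrow(pk)) return(list(phase = NA_real_, relamp = relamp, flat = TRUE))
  list(phase = ct_of_time(ct, pk$time[which.max(pk$value)]),
       relamp = relamp, flat = FALSE)
}

#' Default sampling ranges for CCG populations
#'
#' Degradation rates are drawn uniformly from the literature range
#' 0.2-0.6 per hour. Promoter strength is parameterized as the
#' dimensionless *occupancy* of the element at the driver's geometric
#' mid level (strength times mid concentration) and sampled log-uniformly
#' over `[0.1, 10]` — two decades straddling half-occupancy, the range
#' over which the modulation factor actually responds; sampled repressor
#' strengths use the same occupancy scale. Activation folds are
#' log-uniform in `[2, 10]`. Driver action delays are sampled around the
#' delay of the corresponding core-model regulator: REV-ERB's delay
#' +/- 1 h for RRE drivers, the range spanned by the three E-box
#' regulators' delays for E-box drivers, and DBP's ~2 h action delay
#' +/- 1 h for D-box drivers.
#'
#' @param params The fitted core `clock_parameters`.
#' @return List of ranges used by [sample_ccg_population()].
#' @export
ccg_default_ranges <- function(params = default_clock_parameters()) {
  tau <- params$delay
  list(d_ccg = c(0.2, 0.6),
       occupancy = c(0.1, 10),
       fold = c(2, 10),
       delay_rre = pmax(tau[["RevErba"]] + c(-1, 1), 0),
       delay_ebox = range(tau[c("Bmal1", "Per2", "Cry1")]),
       delay_dbox = pmax(tau[["Dbp"]] + c(-1, 1), 0))
}

#' Simulate a population of clock-controlled genes
#'
#' Draws `n` independent CCGs with the given driver set, parameters
#' sampled from `ranges`, simulates each on the clock trajectory and
#' returns the peak phases. Flat outputs (relative amplitude below 1e-3)
#' are excluded and counted.
#'
#' @param clock_traj Clock [trajectory] (full simulation including
#'   transient).
#' @param drivers Character subset of `c("rre", "ebox", "dbox")`.
#' @param n Population size.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param ranges Sampling ranges, see [ccg_default_ranges()].
#' @param params Core model parameters (for default ranges).
#' @param transient Clock transient (h) used for descriptor extraction and
#'   CT anchoring.
#' @param sample_repressors Logical: also sample the E-box repressor
#'   strengths (gene-specific PER/CRY sensitivity); if `FALSE` they are
#'   fixed at 1.
#' @return Object of class `ccg_population`: list with `phases` (CT h),
#'   `relamps`, `n_excluded`, `mode` (circular mode of the phases on 4 h
#'   bins with 3 h overlap) and the sampled `parameters` data frame.
#' @export
sample_ccg_population <- function(clock_traj, drivers = "rre", n = 250,
                                  seed = 1,
                                  params = default_clock_parameters(),
                                  ranges = ccg_default_ranges(params),
                                  transient = 240,
                                  sample_repressors = TRUE) {
  stopifnot(all(drivers %in% c("rre", "ebox", "dbox")), length(drivers) >= 1)
  de <- extract_rhythm_descriptors(clock_traj, transient = transient)
  if (!isTRUE(attr(de, "oscillation_sustained")))
    stop("clock trajectory is not a sustained oscillation")
  ct <- attr(de, "ct")
  period <- mean(de$period)
  set.seed(seed)
  runif_log <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))
  # geometric mid level of each species over the post-transient cycle:
  # converts sampled occupancies into strength constants on this clock
  post <- window_trajectory(clock_traj, from = transient)
  mid <- apply(post$species, 2, function(x) sqrt(max(x) * max(min(x), 1e-12)))
  key <- c(rre = "RevErba", ebox = "Bmal1", dbox = "Dbp")
  draws <- data.frame(d_ccg = runif(n, ranges$d_ccg[1], ranges$d_ccg[2]))
  for (dv in drivers) {
    draws[[paste0(dv, "_strength")]] <-
      runif_log(n, ranges$occupancy) / mid[key[dv]]
    dr <- ranges[[paste0("delay_", dv)]]
    draws[[paste0(dv, "_delay")]] <- runif(n, dr[1], dr[2])
    if (dv != "rre") draws[[paste0(dv, "_fold")]] <- runif_log(n, ranges$fold)
    if (dv == "ebox" && sample_repressors) {
      draws$ebox_aP <- runif_log(n, ranges$occupancy) / mid["Per2"]
      draws$ebox_aC <- runif_log(n, ranges$occupancy) / mid["Cry1"]
    }
  }
  phases <- relamps <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dl <- list()
    for (dv in drivers) {
      cfg <- list(strength = draws[[paste0(dv, "_strength")]][i],
                  sites = 1L,
                  delay = draws[[paste0(dv, "_delay")]][i])
      if (dv != "rre") cfg$fold <- draws[[paste0(dv, "_fold")]][i]
      if (dv == "ebox" && sample_repressors) {
        cfg$strength_per <- draws$ebox_aP[i]
        cfg$strength_cry <- draws$ebox_aC[i]
      }
      dl[[dv]] <- cfg
    }
    cp <- ccg_parameters(dl, d_ccg = draws$d_ccg[i])
    res <- ccg_peak_phase(clock_traj, simulate_ccg(clock_traj, cp),
                          ct, period)
    phases[i] <- res$phase
    relamps[i] <- res$relamp
  }
  excluded <- sum(is.na(phases))
  ok <- !is.na(phases)
  structure(list(phases = phases[ok], relamps = relamps[ok],
                 n_excluded = excluded,
                 mode = circular_mode(phases[ok]),
                 parameters = draws, kept = ok),
            class = "ccg_population")
}

#' @export
print.ccg_population <- function(x, ...) {
  cat(sprintf("CCG population: %d phases (%d flat excluded), circular mode CT %g\n",
              length(x$phases), x$n_excluded, x$mode))
  invisible(x)
}

#' Fit CCG parameters to a target phase and amplitude
#'
#' Random search over the driver parameter ranges minimizing the circular
#' phase error (hours) plus the relative-amplitude error, used for
#' case studies of individual output genes. If no candidate lands within
#' 3 h of the target phase the result carries a no-fit flag.
#'
#' @param clock_traj Clock [trajectory].
#' @param target_phase Target peak phase (CT h).
#' @param target_relamp Target relative amplitude.
#' @param drivers Driver subset to use.
#' @param n_candidates Number of random candidates.
#' @param seed Integer seed.
#' @param params,ranges,transient,sample_repressors As in
#'   [sample_ccg_population()].
#' @return List with `phase`, `relamp`, `phase_error` (h), `parameters`
#'   (the winning sampled row) and `no_fit`.
#' @export
fit_ccg_to_target <- function(clock_traj, target_phase, target_relamp,
                              drivers = "rre", n_candidates = 400, seed = 1,
                              params = default_clock_parameters(),
                              ranges = ccg_default_ranges(params),
                              transient = 240, sample_repressors = TRUE) {
  pop <- sample_ccg_population(clock_traj, drivers, n = n_candidates,
                               seed = seed, params = params,
                               ranges = ranges, transient = transient,
                               sample_repressors = sample_repressors)
  if (!length(pop$phases)) return(list(parameters = NULL, no_fit = TRUE))
  err <- circular_difference(pop$phases, target_phase) +
    abs(pop$relamps - target_relamp) / max(target_relamp, 1e-6)
  best <- which.min(err)
  phase_error <- circular_difference(pop$phases[best], target_phase)
  list(phase = pop$phases[best], relamp = pop$relamps[best],
       phase_error = phase_error,
       parameters = pop$parameters[which(pop$kept)[best], , drop = FALSE],
       no_fit = phase_error > 3)
}

#' Product of two phase-shifted sinusoidal regulators
#'
#' `(1 + sin(omega t)) * (1 + A sin(omega t + alpha))`: the minimal model
#' of combinatorial regulation by two out-of-phase activators. Expanding
#' the product shows a constant `A/2 cos(alpha)` offset, 24 h terms, and a
#' `-(A/2) cos(2 omega t + alpha)` second harmonic; for `A` near 1 and
#' `alpha = 180` degrees the 24 h terms cancel and a pure 12 h rhythm
#' remains.
#'
#' @param t Time(s), hours.
#' @param A Amplitude of the second regulator, in `[0, 1]`.
#' @param alpha Phase shift of the second regulator, degrees.
#' @param omega Angular frequency, rad/h (default `2*pi/24`).
#' @return Numeric values of the product.
#' @export
harmonic_product <- function(t, A, alpha, omega = OMEGA24) {
  if (any(A < 0 | A > 1)) stop("A must lie in [0, 1]")
  a <- alpha * pi / 180
  (1 + sin(omega * t)) * (1 + A * sin(omega * t + a))
}

#' Dominant circadian harmonic of a signal
#'
#' Restricted Fourier analysis of a mean-subtracted uniform-grid signal at
#' the harmonics of 24 h (periods `24/k`); returns the period with maximal
#' spectral power. A 12 h dominant period indicates that the second
#' harmonic exceeds the fundamental.
#'
#' @param traj A single-species [trajectory] or numeric vector.
#' @param time Time grid (if `traj` is a plain vector).
#' @param k_max Highest harmonic examined.
#' @return Dominant period in hours, or `NA` with a warning for a flat
#'   signal.
#' @export
dominant_period <- function(traj, time = NULL, k_max = 6) {
  if (inherits(traj, "trajectory")) {
    x <- traj$species[, 1]
    time <- traj$time
  } else x <- traj
  if (diff(range(time)) < 4 * 24)
    stop("need at least 4 cycles of data")
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12) {
    warning("flat signal: dominant period undefined")
    return(NA_real_)
  }
  power <- vapply(seq_len(k_max), function(k) {
    z <- exp(-2i * pi * k * time / 24)
    Mod(sum(x * z))^2
  }, numeric(1))
  24 / which.max(power)
}
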