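#' Transcriptional modulation factors
#'
#' Modulation factors are the dimensionless multiplicative terms that carry
#' all transcriptional regulation in the model; a gene's production term is
#' the product of the factors for its promoter elements.
#'
#' `rre_modulator` describes repression through ROR elements,
#' `(1 + strength * R)^(-sites)`: equal to 1 without repressor, strictly
#' decreasing in the repressor level, with the exponent counting functional
#' ROR elements in the regulatory region.
#'
#' `ebox_modulator` describes the balance of activation and repression on
#' E-boxes. The effective activator is
#' `Bhat = strength_act * B / (1 + strength_per * P + strength_cry * C)`
#' (competitive inhibition of BMAL1 action by PER2 and CRY1) and the factor
#' is `((1 + fold * Bhat)/(1 + Bhat))^sites`, rising from 1 at `B = 0` to
#' `fold^sites` at saturation.
#'
#' `dbox_modulator` uses the same activating form with DBP as sole
#' activator, plus an optional competing repressor slot (E4BP4-like input,
#' off by default).
#'
#' @param repressor_level,activator_level,dbp_level Non-negative regulator
#'   concentrations (vectorized).
#' @param strength,strength_act,strength_per,strength_cry Positive binding
#'   strength constants.
#' @param sites Positive integer count of promoter elements.
#' @param fold Activation fold (>= 1) of a fully occupied element.
#' @param per_level,cry_level Non-negative repressor concentrations.
#' @param repressor_level_dbox,repressor_strength Optional competing
#'   repressor on the D-box.
#' @return Numeric factor(s): in `(0, 1]` for `rre_modulator`, in
#'   `(0, fold^sites]` for the activating modulators.
#' @examples
#' rre_modulator(0, 1, 3)          # no repressor, no repression
#' rre_modulator(2, 0.5, 1)        # half-repression point
#' ebox_modulator(1, 0, 0, 1, 1, 1, fold = 10, sites = 2)
#' @export
rre_modulator <- function(repressor_level, strength, sites = 1L) {
  if (any(repressor_level < 0)) stop("regulator level must be non-negative")
  if (any(strength <= 0)) stop("strength must be positive")
  if (any(sites < 1)) stop("site count must be a positive integer")
  (1 + strength * repressor_level)^(-sites)
}

#' @rdname rre_modulator
#' @export
ebox_modulator <- function(activator_level, per_level, cry_level,
                           strength_act, strength_per, strength_cry,
                           fold, sites = 1L) {
  if (any(activator_level < 0) || any(per_level < 0) || any(cry_level < 0))
    stop("regulator levels must be non-negative")
  if (any(c(strength_act, strength_per, strength_cry) <= 0))
    stop("strengths must be positive")
  if (any(fold < 1)) stop("fold must be >= 1")
  bhat <- strength_act * activator_level /
    (1 + strength_per * per_level + strength_cry * cry_level)
  ((1 + fold * bhat) / (1 + bhat))^sites
}

#' @rdname rre_modulator
#' @export
dbox_modulator <- function(dbp_level, strength, fold, sites = 1L,
                           repressor_level_dbox = 0,
                           repressor_strength = 1) {
  if (any(dbp_level < 0) || any(repressor_level_dbox < 0))
    stop("regulator levels must be non-negative")
  if (any(strength <= 0)) stop("strength must be positive")
  if (any(fold < 1)) stop("fold must be >= 1")
  dhat <- strength * dbp_level /
    (1 + repressor_strength * repressor_level_dbox)
  ((1 + fold * dhat) / (1 + dhat))^sites
}

#' Right-hand side of the delayed clock equations
#'
#' Reference implementation of the model derivatives,
#' `dx/dt = d_x * (M_x(t) - x)`, used for contract tests against the
#' compiled integrator and for inspecting the wiring. Regulator `g` enters
#' every equation at its own delayed level (supplied by the caller).
#'
#' @param state_now Named numeric of current concentrations (all 5 genes).
#' @param delayed_states Named numeric of regulator concentrations at
#'   `t - tau_g` for each gene `g`.
#' @param params A [clock_parameters()] object.
#' @return Named numeric vector of derivatives (per hour).
#' @export
clock_rhs <- function(state_now, delayed_states, params) {
  stopifnot(inherits(params, "clock_parameters"))
  x <- state_now[GENES]
  z <- delayed_states[GENES]
  if (anyNA(x) || anyNA(z)) stop("missing state or delayed state")
  m <- clock_modulation(z[["Bmal1"]], z[["RevErba"]], z[["Per2"]],
                        z[["Cry1"]], z[["Dbp"]], params)
  M <- unlist(m)[GENES]
  setNames(params$degradation * (M - x), GENES)
}

# per-gene production terms from (delayed) regulator levels; vectorized
clock_modulation <- function(B, R, P, C, D, params) {
  s <- params$strengths
  n <- params$sites
  eb <- function(g, ns) {
    ebox_modulator(B, P, C, s[[paste0("b_", g)]], s[[paste0("aP_", g)]],
                   s[[paste0("aC_", g)]], s[["fold_ebox"]], ns)
  }
  db <- function(g, ns) {
    dbox_modulator(D, s[[paste0("s_", g)]], s[["fold_dbox"]], ns)
  }
  list(
    Bmal1 = rre_modulator(R, s[["ar1"]], n[["rre_Bmal1"]]),
    RevErba = eb("RevErba", n[["ebox_RevErba"]]) *
      db("RevErba", n[["dbox_RevErba"]]),
    Per2 = eb("Per2", n[["ebox_Per2"]]) * db("Per2", n[["dbox_Per2"]]),
    Cry1 = eb("Cry1", n[["ebox_Cry1"]]) * db("Cry1", n[["dbox_Cry1"]]) *
      rre_modulator(R, s[["gr3"]], n[["rre_Cry1"]]),
    Dbp = eb("Dbp", n[["ebox_Dbp"]])
  )
}

#' Modulation-factor time courses on a clock trajectory
#'
#' Evaluates each gene's production term `M_x(t)` along a simulated
#' trajectory, applying the model delays, e.g. to locate the time of
#' repression release on ROR elements.
#'
#' @param traj A [trajectory] from [simulate_clock()].
#' @param params The `clock_parameters` used to produce it.
#' @return A `trajectory`-like object whose species are the per-gene
#'   production terms.
#' @export
clock_modulation_series <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"))
  lagged <- function(g) delayed_series(traj, g, params$delay[g])
  m <- clock_modulation(lagged("Bmal1"), lagged("RevErba"), lagged("Per2"),
                        lagged("Cry1"), lagged("Dbp"), params)
  trajectory(traj$time, do.call(cbind, m), dt = traj$dt)
}
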