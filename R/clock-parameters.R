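#' Parameters of the five-gene core clock model
#'
#' The core clock network couples `Bmal1`, `Rev-erba` (written `RevErba` in
#' code), `Per2`, `Cry1` and `Dbp` through delayed transcriptional
#' regulation on three classes of cis-regulatory elements:
#'
#' * ROR elements (RRE): repression of `Bmal1` (strength `ar1`) and `Cry1`
#'   (strength `gr3`) by REV-ERB protein, modelled as `(1 + a*R)^(-n)`.
#' * E-boxes: activation by BMAL1 with competitive repression by PER2 and
#'   CRY1, `((1 + f*Bhat)/(1 + Bhat))^n` with
#'   `Bhat = b*B / (1 + aP*P + aC*C)`; drives `Rev-erba`, `Per2`, `Cry1`
#'   and `Dbp`, with gene-specific strengths.
#' * D-boxes: activation by DBP, same activating form with DBP as the sole
#'   activator; drives `Rev-erba`, `Per2` and `Cry1`.
#'
#' Each mRNA obeys `dx/dt = d_x * (M_x(t) - x)` where `M_x` is the product
#' of the gene's modulation factors, every regulator being evaluated at
#' `t - tau` of its own gene (the explicit delay lumping translation,
#' modification and nuclear import). Pre-multiplying the production by
#' `d_x` normalizes the model so that a gene with all factors at basal
#' level (`M = 1`) has steady state 1.
#'
#' @param degradation Named numeric of per-hour mRNA degradation rates for
#'   the five genes; must lie in `[0.05, 2]`.
#' @param delay Named numeric of protein-action delays in hours (mRNA peak
#'   to regulatory action); must lie in `[0, 12]`.
#' @param strengths Named numeric of the 19 free regulatory constants, in
#'   the order of [clock_strength_names()]: RRE strengths `ar1`, `gr3`;
#'   shared activation folds `fold_ebox`, `fold_dbox` (>= 1); per-target
#'   E-box activator (`b_*`) and repressor (`aP_*`, `aC_*`) strengths; and
#'   per-target D-box strengths `s_*`. All must be positive.
#' @param sites Named integer vector of promoter-element counts (the
#'   exponents of the modulation factors). Defaults: 3 RREs on `Bmal1`,
#'   2 on `Cry1`; 3 E-boxes on `Rev-erba` and `Dbp`, 2 on `Per2` and
#'   `Cry1`; 1 D-box each on `Rev-erba`, `Per2` and `Cry1`.
#'
#' @return An object of class `clock_parameters`.
#' @seealso [default_clock_parameters()], [simulate_clock()]
#' @export
clock_parameters <- function(degradation = c(Bmal1 = 0.18, RevErba = 1,
                                             Per2 = 0.15, Cry1 = 0.15,
                                             Dbp = 0.12),
                             delay = c(Bmal1 = 4.5, RevErba = 2, Per2 = 8,
                                       Cry1 = 4, Dbp = 2),
                             strengths = default_clock_strengths(),
                             sites = default_clock_sites()) {
  degradation <- degradation[GENES]
  delay <- delay[GENES]
  strengths <- strengths[clock_strength_names()]
  sites <- sites[clock_site_names()]
  if (anyNA(degradation) || anyNA(delay) || anyNA(strengths) || anyNA(sites))
    stop("missing or misnamed parameter entries")
  if (any(degradation <= 0)) stop("degradation rates must be positive")
  if (any(degradation < 0.05 | degradation > 2))
    stop("degradation rates must lie in [0.05, 2] per hour")
  if (any(delay < 0 | delay > 12)) stop("delays must lie in [0, 12] hours")
  if (any(strengths <= 0)) stop("strength constants must be positive")
  if (any(strengths[c("fold_ebox", "fold_dbox")] < 1))
    stop("activation folds must be >= 1")
  if (any(sites < 1) || any(sites != round(sites)))
    stop("site counts must be positive integers")
  structure(list(degradation = degradation, delay = delay,
                 strengths = strengths,
                 sites = setNames(as.integer(sites), names(sites))),
            class = "clock_parameters")
}

#' Names of the free regulatory constants, in canonical order
#' @return Character vector of length 19.
#' @export
clock_strength_names <- function() {
  c("ar1", "gr3", "fold_ebox", "fold_dbox",
    "b_RevErba", "aP_RevErba", "aC_RevErba",
    "b_Per2", "aP_Per2", "aC_Per2",
    "b_Cry1", "aP_Cry1", "aC_Cry1",
    "b_Dbp", "aP_Dbp", "aC_Dbp",
    "s_RevErba", "s_Per2", "s_Cry1")
}

clock_site_names <- function() {
  c("rre_Bmal1", "rre_Cry1",
    "ebox_RevErba", "ebox_Per2", "ebox_Cry1", "ebox_Dbp",
    "dbox_RevErba", "dbox_Per2", "dbox_Cry1")
}

#' Default promoter-element counts of the wiring diagram
#' @return Named integer vector.
#' @export
default_clock_sites <- function() {
  c(rre_Bmal1 = 3L, rre_Cry1 = 2L,
    ebox_RevErba = 3L, ebox_Per2 = 2L, ebox_Cry1 = 2L, ebox_Dbp = 3L,
    dbox_RevErba = 1L, dbox_Per2 = 1L, dbox_Cry1 = 1L)
}

#' Default regulatory strengths (liver-like oscillatory regime)
#'
#' These values were obtained once by evolutionary optimization against the
#' default rhythm-descriptor targets and are shipped as the initial point
#' of the fit; they yield a sustained limit cycle with a period close to
#' 24 h and the canonical phase order of the five genes.
#'
#' @return Named numeric vector of length 19.
#' @export
default_clock_strengths <- function() {
  .default_strengths
}

#' Clock parameters of the shipped consensus-like model
#' @return A `clock_parameters` object.
#' @export
default_clock_parameters <- function() clock_parameters()

#' @export
print.clock_parameters <- function(x, ...) {
  cat("Five-gene core clock parameters\n")
  cat("  degradation (1/h):",
      paste(sprintf("%s=%.3g", GENES, x$degradation), collapse = " "), "\n")
  cat("  delay (h):        ",
      paste(sprintf("%s=%.3g", GENES, x$delay), collapse = " "), "\n")
  cat("  strengths:\n")
  print(round(x$strengths, 4))
  invisible(x)
}

#' Read or write clock parameters as JSON
#'
#' @param params A `clock_parameters` object.
#' @param path File path.
#' @return `write_clock_parameters` returns `path` invisibly;
#'   `read_clock_parameters` returns a `clock_parameters` object.
#' @export
write_clock_parameters <- function(params, path) {
  stopifnot(inherits(params, "clock_parameters"))
  jsonlite::write_json(lapply(unclass(params), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clock_parameters
#' @export
read_clock_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clock_parameters(degradation = unlist(x$degradation),
                   delay = unlist(x$delay),
                   strengths = unlist(x$strengths),
                   sites = unlist(x$sites))
}
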