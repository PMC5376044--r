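#' Circular helpers on the 24 h clock face
#'
#' `circular_difference` returns the shortest arc (in hours, `[0, 12]`)
#' between two circadian phases. `circular_phase_histogram` builds the
#' overlapping-bin histogram used for peak-phase distributions: bins of
#' `bin_width` hours advanced by `bin_width - overlap` hours (default 4 h
#' bins with 3 h overlap, i.e. centers at every integer CT); each bin is
#' the half-open circular interval `[center - w/2, center + w/2)`, so every
#' phase is counted in exactly `bin_width / step` bins and the histogram
#' mass equals `4 * n` with the defaults. `circular_mode` is the center of
#' the fullest bin (ties: earliest center).
#'
#' @param a,b Phases in circadian hours.
#' @param phases Numeric vector of phases in `[0, 24)`.
#' @param bin_width Bin width in hours.
#' @param overlap Overlap between consecutive bins in hours.
#' @return `circular_phase_histogram`: data frame with `bin_center_CT` and
#'   `count`; `circular_mode`: a single CT value.
#' @export
circular_difference <- function(a, b) {
  d <- (a - b) %% 24
  pmin(d, 24 - d)
}

#' @rdname circular_difference
#' @export
circular_phase_histogram <- function(phases, bin_width = 4, overlap = 3) {
  if (any(phases < 0 | phases >= 24)) stop("phases must lie in [0, 24)")
  step <- bin_width - overlap
  if (step <= 0) stop("overlap must be smaller than bin_width")
  centers <- seq(0, 24 - step, by = step)
  counts <- vapply(centers, function(cc) {
    sum(((phases - (cc - bin_width / 2)) %% 24) < bin_width)
  }, numeric(1))
  data.frame(bin_center_CT = centers, count = counts)
}

#' @rdname circular_difference
#' @export
circular_mode <- function(phases, bin_width = 4, overlap = 3) {
  h <- circular_phase_histogram(phases, bin_width, overlap)
  h$bin_center_CT[which.max(h$count)]
}

# circular mean in hours (used for summaries, not for the histogram mode)
circular_mean <- function(phases) {
  z <- complex(argument = phases * pi / 12)
  (Arg(mean(z)) * 12 / pi) %% 24
}
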