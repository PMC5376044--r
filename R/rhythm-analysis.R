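#' Expression time-course dataset
#'
#' Container for a probes-by-samples expression matrix on a linear scale,
#' with the sampling time (hours) of every column. Replicates are columns
#' sharing a time.
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids).
#' @param times Numeric vector of sampling times, one per column.
#' @param probes Probe identifiers (default: rownames).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, times, probes = rownames(values)) {
  values <- as.matrix(values)
  if (length(times) != ncol(values))
    stop("one sampling time per column is required")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(probes)) probes <- paste0("probe_", seq_len(nrow(values)))
  rownames(values) <- probes
  structure(list(values = values, times = as.numeric(times),
                 probes = probes), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression dataset: %d probes x %d samples, %d timepoints over %g h\n",
              nrow(x$values), ncol(x$values), length(unique(x$times)),
              diff(range(x$times))))
  invisible(x)
}

biharmonic_design <- function(times, base_period = 24) {
  w <- 2 * pi / base_period
  cbind(mean = 1, a1 = cos(w * times), b1 = sin(w * times),
        a2 = cos(2 * w * times), b2 = sin(2 * w * times))
}

#' Biharmonic (24 h + 12 h) harmonic regression
#'
#' Least-squares fit of
#' `y = m + a1 cos(wt) + b1 sin(wt) + a2 cos(2wt) + b2 sin(2wt)` with
#' `w = 2 pi / base_period`, and an F test of the four rhythm coefficients
#' against the intercept-only model (df 4 and N - 5). The peak phase is
#' the argmax of the full fitted curve over one period (so profiles
#' dominated by the 12 h component still get a meaningful peak), and the
#' relative amplitude is the fitted peak-to-trough range over twice the
#' fitted mean.
#'
#' @param times Sampling times in hours (at least 6, not all identical).
#' @param values Numeric vector (one probe) for `biharmonic_fit`, or a
#'   probes-by-samples matrix for `biharmonic_fit_matrix`.
#' @param base_period Fundamental period, hours.
#' @return A one-row (or per-probe) data frame with columns `mean`, `a1`,
#'   `b1`, `a2`, `b2`, `amplitude24` (`sqrt(a1^2+b1^2)`), `phase` (h in
#'   `[0, base_period)`), `relative_amplitude`, `F`, `p`.
#'   `relative_amplitude` is `NA` when the fitted mean is not positive.
#' @export
biharmonic_fit <- function(times, values, base_period = 24) {
  res <- biharmonic_fit_matrix(times, matrix(values, nrow = 1,
                                             dimnames = list("y", NULL)),
                               base_period)
  res
}

#' @rdname biharmonic_fit
#' @export
biharmonic_fit_matrix <- function(times, values, base_period = 24) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("probe_", seq_len(nrow(values)))
  n <- length(times)
  if (ncol(values) != n) stop("values must have one column per time")
  if (n <= 5) stop("insufficient data: need more than 5 samples")
  if (length(unique(times)) < 2) stop("times must not all be identical")
  X <- biharmonic_design(times, base_period)
  fit <- lm.fit(X, t(values))
  beta <- t(as.matrix(fit$coefficients))  # probes x 5
  resid <- t(as.matrix(fit$residuals))
  rss1 <- rowSums(resid^2)
  rss0 <- rowSums((values - rowMeans(values))^2)
  df2 <- n - 5
  Fstat <- ((rss0 - rss1) / 4) / (rss1 / df2)
  p <- pf(Fstat, 4, df2, lower.tail = FALSE)
  # fitted-curve extrema on a fine grid over one period
  tg <- seq(0, base_period, length.out = 481)[-481]
  G <- biharmonic_design(tg, base_period)
  out <- data.frame(probe = rownames(values),
                    mean = beta[, "mean"], a1 = beta[, "a1"],
                    b1 = beta[, "b1"], a2 = beta[, "a2"], b2 = beta[, "b2"],
                    amplitude24 = sqrt(beta[, "a1"]^2 + beta[, "b1"]^2),
                    phase = NA_real_, relative_amplitude = NA_real_,
                    F = Fstat, p = p, row.names = NULL)
  # chunk to bound memory on large matrices
  idx <- seq_len(nrow(values))
  for (ch in split(idx, ceiling(idx / 2000))) {
    curves <- G %*% t(beta[ch, , drop = FALSE])  # grid x probes
    i_max <- max.col(t(curves), ties.method = "first")
    pk <- tg[i_max]
    # quadratic refinement around the grid argmax (circular neighbours)
    ng <- length(tg)
    il <- (i_max - 2) %% ng + 1
    ir <- i_max %% ng + 1
    sel <- cbind(seq_along(ch), i_max)
    y0 <- t(curves)[sel]
    ym <- t(curves)[cbind(seq_along(ch), il)]
    yp <- t(curves)[cbind(seq_along(ch), ir)]
    den <- ym - 2 * y0 + yp
    off <- ifelse(den < 0, 0.5 * (ym - yp) / den, 0)
    dtg <- tg[2] - tg[1]
    out$phase[ch] <- (pk + off * dtg) %% base_period
    cmax <- apply(curves, 2, max)
    cmin <- apply(curves, 2, min)
    m <- beta[ch, "mean"]
    out$relative_amplitude[ch] <-
      ifelse(m > 0, (cmax - cmin) / (2 * m), NA_real_)
  }
  out
}

#' Select rhythmic probes with the standard filters
#'
#' A probe is called rhythmic when it passes all three filters, each a
#' strict inequality: maximum expression above `expression_cutoff`,
#' F-test p below `p_cutoff` and relative amplitude above
#' `relamp_cutoff`.
#'
#' @param dataset An [expression_dataset()].
#' @param fits Per-probe fits from [biharmonic_fit_matrix()].
#' @param expression_cutoff Minimum (exclusive) of the probe's maximum
#'   expression; 600 for liver-style data, 500 for adrenal-style data.
#' @param p_cutoff,relamp_cutoff Rhythmicity filters.
#' @return Character vector of rhythmic probe identifiers.
#' @export
classify_rhythmic <- function(dataset, fits, expression_cutoff = 600,
                              p_cutoff = 0.01, relamp_cutoff = 0.3) {
  stopifnot(inherits(dataset, "expression_dataset"))
  fits <- fits[match(dataset$probes, fits$probe), ]
  max_expr <- apply(dataset$values, 1, max)
  ok <- max_expr > expression_cutoff &
    !is.na(fits$p) & fits$p < p_cutoff &
    !is.na(fits$relative_amplitude) &
    fits$relative_amplitude > relamp_cutoff
  dataset$probes[ok]
}

#' Top-k probes by relative amplitude
#'
#' @param fits Per-probe fits.
#' @param probes Probe set to rank (e.g. the rhythmic set).
#' @param k Number to keep; if the set is smaller than `k`, all are
#'   returned with a message.
#' @return Character vector of probe ids, amplitude-descending, ties
#'   broken lexicographically by probe id.
#' @export
top_by_amplitude <- function(fits, probes = fits$probe, k = 500) {
  f <- fits[fits$probe %in% probes, ]
  ord <- order(-f$relative_amplitude, f$probe)
  if (nrow(f) < k)
    message("set smaller than k = ", k, ": returning all ", nrow(f))
  head(f$probe[ord], k)
}

#' Identifier overlap of two probe sets
#' @param set_a,set_b Character vectors.
#' @return Common identifiers.
#' @export
set_overlap <- function(set_a, set_b) intersect(set_a, set_b)
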