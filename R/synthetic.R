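#' Specification of a synthetic expression experiment
#'
#' Describes the planted ground truth of a probes-by-samples matrix
#' emulating 2 h-resolution circadian profiling: a rhythmic fraction with
#' phases drawn from a mixture of von Mises components (default bimodal
#' near CT 0 and CT 10, the shape typical of peripheral-tissue phase
#' distributions), uniform relative amplitudes, a small fraction of
#' probes carrying an additional 12 h harmonic, and multiplicative
#' lognormal (microarray-like) noise.
#'
#' @param n_probes Number of probes.
#' @param rhythmic_fraction Fraction of probes with a planted rhythm.
#' @param phase_mixture Either `"uniform"` or a list with `means` (CT h),
#'   `kappa` (concentrations) and `weights`.
#' @param relamp_range Range of planted relative amplitudes.
#' @param harmonic_fraction Fraction of rhythmic probes with an added
#'   12 h component.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param times Sampling times (hours), replicates as repeated values;
#'   default: every 2 h over 24 h, 4 replicates per timepoint.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression
#'   parameters.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_probes = 1000, rhythmic_fraction = 0.15,
                           phase_mixture = list(means = c(0, 10),
                                                kappa = c(2, 2),
                                                weights = c(0.5, 0.5)),
                           relamp_range = c(0.3, 0.8),
                           harmonic_fraction = 0,
                           noise_cv = 0.1,
                           times = rep(seq(0, 24, by = 2), each = 4),
                           baseline_meanlog = log(1000),
                           baseline_sdlog = 1) {
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1 ||
      harmonic_fraction < 0 || harmonic_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (diff(range(times)) < 24)
    stop("sampling design must span at least 24 h")
  structure(as.list(environment()), class = "synthetic_spec")
}

# von Mises sampler (Best & Fisher rejection method), mean mu radians,
# concentration kappa
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out
}

sample_phases <- function(n, mixture) {
  if (identical(mixture, "uniform")) return(runif(n, 0, 24))
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  th <- vapply(seq_len(n), function(i) {
    rvonmises(1, mixture$means[comp[i]] * pi / 12, mixture$kappa[comp[i]])
  }, numeric(1))
  (th * 12 / pi) %% 24
}

#' Generate an expression matrix with planted rhythms
#'
#' Rhythmic probes follow
#' `baseline * (1 + relamp * cos(w(t - phase)) [+ harmonic])` with
#' multiplicative lognormal noise; the remaining probes are noisy
#' constants. Deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (data frame: `probe`, `rhythmic`, `phase`, `relamp`, `harmonic`,
#'   `baseline`).
#' @export
generate_expression_matrix <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_probes
  t <- spec$times
  probes <- sprintf("probe_%05d", seq_len(n))
  n_r <- round(n * spec$rhythmic_fraction)
  rhythmic <- seq_len(n) <= n_r
  baseline <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  phase <- rep(NA_real_, n)
  relamp <- rep(NA_real_, n)
  harmonic <- rep(FALSE, n)
  if (n_r) {
    phase[1:n_r] <- sample_phases(n_r, spec$phase_mixture)
    relamp[1:n_r] <- runif(n_r, spec$relamp_range[1], spec$relamp_range[2])
    harmonic[1:n_r] <- runif(n_r) < spec$harmonic_fraction
  }
  w <- OMEGA24
  signal <- matrix(1, n, length(t))
  if (n_r) {
    for (i in seq_len(n_r)) {
      s <- 1 + relamp[i] * cos(w * (t - phase[i]))
      if (harmonic[i])
        s <- s + 0.5 * relamp[i] * cos(2 * w * (t - phase[i]))
      signal[i, ] <- s
    }
  }
  vals <- baseline * signal
  if (spec$noise_cv > 0) {
    sdl <- sqrt(log(1 + spec$noise_cv^2))
    vals <- vals * matrix(rlnorm(length(vals), -sdl^2 / 2, sdl),
                          nrow = n)
  }
  list(dataset = expression_dataset(vals, t, probes),
       truth = data.frame(probe = probes, rhythmic = rhythmic,
                          phase = phase, relamp = relamp,
                          harmonic = harmonic, baseline = baseline))
}

#' Generate a qPCR Cp table from known abundance profiles
#'
#' The inverse of [normalize_qpcr()]: for true relative quantities `q`,
#' `Cp = -log(q)/log(efficiency) + drift_sample + noise`. Reference genes
#' (constant abundance 1) are appended; the per-sample drift emulates
#' loading/RT variation that reference normalization must remove.
#'
#' @param true_profiles Numeric gene-by-sample matrix of true abundances
#'   (rownames = genes, colnames = samples).
#' @param efficiencies Named fold-per-cycle efficiencies for all genes
#'   including references.
#' @param reference_genes Names of the reference genes to append.
#' @param reference_drift Per-sample drift in cycles (scalar or vector);
#'   default 0.
#' @param noise_sd Gaussian Cp noise in cycles.
#' @param seed Integer seed.
#' @return List with `cp_table` (long data frame `gene`, `sample`, `cp`)
#'   and `truth` (the input profiles).
#' @export
generate_qpcr_dataset <- function(true_profiles, efficiencies,
                                  reference_genes = c("Hmbs", "Eif2a",
                                                      "Ppib"),
                                  reference_drift = 0, noise_sd = 0,
                                  seed = 1) {
  set.seed(seed)
  samples <- colnames(true_profiles)
  if (is.null(samples))
    samples <- paste0("s", seq_len(ncol(true_profiles)))
  drift <- rep_len(reference_drift, length(samples))
  refs <- matrix(1, length(reference_genes), length(samples),
                 dimnames = list(reference_genes, samples))
  q <- rbind(true_profiles, refs)
  eff <- efficiencies[rownames(q)]
  if (anyNA(eff)) stop("missing efficiencies")
  cp <- -log(q) / log(eff) + matrix(drift, nrow(q), ncol(q), byrow = TRUE)
  if (noise_sd > 0) cp <- cp + rnorm(length(cp), 0, noise_sd)
  long <- data.frame(gene = rep(rownames(q), times = ncol(q)),
                     sample = rep(samples, each = nrow(q)),
                     cp = as.vector(cp))
  list(cp_table = long, truth = true_profiles)
}

#' Generate a synthetic annotation and matching ChIP-seq peak files
#'
#' Plants known target memberships for two factors (A with TFAS cutoff
#' 10, B with cutoff 0.5): every planted target receives one or more
#' peaks within 5 kb of its start codon, peak-to-gene distances
#' exponential with the given mean, and scores drawn so the resulting
#' TFAS clears the factor's cutoff; non-targets receive either no peak or
#' a sub-cutoff decoy. Deterministic given the seed. Files are plain BED5.
#'
#' @param n_genes Number of genes.
#' @param n_a_only,n_b_only,n_both Planted target counts per class.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param distance_mean Mean peak-to-start-codon distance (bp).
#' @param decoy_fraction Fraction of non-targets receiving a sub-cutoff
#'   decoy peak in file A.
#' @param cutoff_a,cutoff_b TFAS cutoffs the planted targets must clear.
#' @param d0 TFAS distance scale used to calibrate planted scores.
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, `genes.bed`,
#'   `peaks_A.bed` and `peaks_B.bed` are written there.
#' @return List with `annotation`, `peaks_a`, `peaks_b` (data frames as
#'   returned by the readers), `truth` (per-gene class: `"a_only"`,
#'   `"b_only"`, `"both"` or `"none"`), and `files` (paths or `NULL`).
#' @export
generate_annotation_and_peaks <- function(n_genes = 200, n_a_only = 20,
                                          n_b_only = 30, n_both = 10,
                                          chrom_lengths = c(chr1 = 2e6,
                                                            chr2 = 2e6),
                                          distance_mean = 1000,
                                          decoy_fraction = 0.1,
                                          cutoff_a = 10, cutoff_b = 0.5,
                                          d0 = 500, seed = 1, dir = NULL) {
  set.seed(seed)
  n_t <- n_a_only + n_b_only + n_both
  if (n_t > n_genes) stop("more planted targets than genes")
  spacing <- 12000  # keeps neighbouring genes > 5 kb apart
  per_chrom <- floor(chrom_lengths / spacing) - 1
  if (sum(per_chrom) < n_genes)
    stop("chromosomes too short for the requested gene count")
  chrom <- rep(names(chrom_lengths), per_chrom)[seq_len(n_genes)]
  idx <- unlist(lapply(per_chrom, seq_len))[seq_len(n_genes)]
  pos <- idx * spacing + sample(0:2000, n_genes, replace = TRUE)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ann <- data.frame(gene = genes, chrom = chrom, strand = strand,
                    start_codon = pos)
  cls <- rep("none", n_genes)
  planted <- sample.int(n_genes, n_t)
  cls[planted[seq_len(n_a_only)]] <- "a_only"
  if (n_b_only) cls[planted[n_a_only + seq_len(n_b_only)]] <- "b_only"
  if (n_both) cls[planted[n_a_only + n_b_only + seq_len(n_both)]] <- "both"

  make_peaks <- function(which_genes, target_tfas, label) {
    if (!length(which_genes))
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), name = character(0),
                        score = numeric(0), center = numeric(0)))
    d <- pmin(rexp(length(which_genes), 1 / distance_mean), 4800)
    side <- sample(c(-1, 1), length(which_genes), replace = TRUE)
    center <- round(pos[which_genes] + side * d)
    dist <- abs(center - pos[which_genes])
    score <- target_tfas * exp(dist / d0)
    halfw <- 150
    data.frame(chrom = chrom[which_genes], start = center - halfw,
               end = center + halfw,
               name = sprintf("%s_pk_%04d", label, seq_along(which_genes)),
               score = score, center = center)
  }
  a_genes <- which(cls %in% c("a_only", "both"))
  b_genes <- which(cls %in% c("b_only", "both"))
  peaks_a <- make_peaks(a_genes, runif(length(a_genes), 1.5, 3) * cutoff_a,
                        "A")
  peaks_b <- make_peaks(b_genes, runif(length(b_genes), 1.5, 3) * cutoff_b,
                        "B")
  # sub-cutoff decoys near some non-targets (file A)
  none <- which(cls == "none")
  n_decoy <- round(length(none) * decoy_fraction)
  if (n_decoy) {
    dg <- sample(none, n_decoy)
    decoys <- make_peaks(dg, runif(n_decoy, 0.05, 0.5) * cutoff_a, "Adecoy")
    peaks_a <- rbind(peaks_a, decoys)
  }
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(genes = file.path(dir, "genes.bed"),
                  peaks_a = file.path(dir, "peaks_A.bed"),
                  peaks_b = file.path(dir, "peaks_B.bed"))
    write_bed5 <- function(df, path) {
      write.table(df[, c("chrom", "start", "end", "name", "score")],
                  path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write_bed5(peaks_a, files$peaks_a)
    write_bed5(peaks_b, files$peaks_b)
    gb <- data.frame(chrom = ann$chrom, start = ann$start_codon,
                     end = ann$start_codon + 1, name = ann$gene,
                     score = 0, strand = ann$strand)
    write.table(gb, files$genes, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  list(annotation = ann, peaks_a = peaks_a, peaks_b = peaks_b,
       truth = data.frame(gene = genes, class = cls), files = files)
}
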