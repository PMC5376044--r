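#' Read ChIP-seq peaks from a BED file
#'
#' Expects BED5 (chrom, start, end, name, score) with 0-based half-open
#' coordinates; the score column carries the peak score measure used for
#' TFAS. Peak centers are the interval midpoints (possibly half-integer).
#'
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `score`, `center`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  score <- gr$score
  if (is.null(score)) stop("peak file has no score column")
  if (any(score < 0)) stop("peak scores must be non-negative")
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("peak_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, name = nm, score = score,
             center = (start0 + end0) / 2)
}

#' Read gene annotation with start-codon coordinates
#'
#' Either a BED-like file whose 1 bp intervals mark the first base of each
#' start codon (name column = gene id, strand column required), or a GFF3
#' file with `start_codon` features carrying a `gene_id` (or `ID`)
#' attribute. The first base of the start codon is the lower coordinate on
#' the `+` strand and the higher coordinate on the `-` strand.
#'
#' @param path File path.
#' @param format `"bed"` or `"gff3"`.
#' @return Data frame `gene`, `chrom`, `strand`, `start_codon` (0-based
#'   coordinate of the first base).
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    pos0 <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                   GenomicRanges::end(gr) - 1,
                   GenomicRanges::start(gr) - 1)
    df <- data.frame(gene = gr$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start_codon = pos0)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "start_codon"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    pos0 <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                   GenomicRanges::end(gr) - 1,
                   GenomicRanges::start(gr) - 1)
    df <- data.frame(gene = ids,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start_codon = pos0)
  }
  if (any(!df$strand %in% c("+", "-")))
    stop("annotation strand must be + or -")
  df
}

#' Assign ChIP-seq peaks to nearby genes
#'
#' Associates every (peak, gene) pair on the same chromosome whose
#' distance — unstranded absolute distance between the peak center and the
#' first base of the gene's start codon — is strictly smaller than
#' `max_distance`. A peak may map to several genes and a gene to several
#' peaks; both mapping counts are attached. Peaks on chromosomes absent
#' from the annotation are skipped and counted.
#'
#' @param peaks Data frame from [read_peaks_bed()] (or equivalent with
#'   columns `chrom`, `name`, `score`, `center`).
#' @param annotation Data frame from [read_gene_annotation()].
#' @param max_distance Exclusive distance cutoff in bp (default 5000).
#' @return Object of class `peak_gene_associations`: data frame `gene`,
#'   `peak`, `distance`, `score`, with attributes `gene2peak_count`
#'   (named, all annotation genes), `peak2gene_count` (named, all peaks)
#'   and `n_skipped_peaks`.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_distance = 5000) {
  if (max_distance <= 0) stop("max_distance must be positive")
  skipped <- !peaks$chrom %in% annotation$chrom
  rows <- list()
  for (ch in intersect(unique(peaks$chrom), unique(annotation$chrom))) {
    pk <- peaks[peaks$chrom == ch, ]
    gn <- annotation[annotation$chrom == ch, ]
    ord <- order(gn$start_codon)
    gn <- gn[ord, ]
    # gene start codons within (center - max_distance, center + max_distance)
    lo <- findInterval(pk$center - max_distance, gn$start_codon) + 1
    hi <- findInterval(pk$center + max_distance, gn$start_codon,
                       left.open = TRUE)
    n_hits <- pmax(hi - lo + 1, 0)
    if (!sum(n_hits)) next
    p_idx <- rep(seq_len(nrow(pk)), n_hits)
    g_idx <- unlist(lapply(which(n_hits > 0),
                           function(i) seq(lo[i], hi[i])))
    d <- abs(pk$center[p_idx] - gn$start_codon[g_idx])
    keep <- d < max_distance  # strict, guards the boundary exactly
    rows[[ch]] <- data.frame(gene = gn$gene[g_idx][keep],
                             peak = pk$name[p_idx][keep],
                             distance = d[keep],
                             score = pk$score[p_idx][keep])
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), peak = character(0),
               distance = numeric(0), score = numeric(0))
  rownames(assoc) <- NULL
  g2p <- table(factor(assoc$gene, levels = unique(annotation$gene)))
  p2g <- table(factor(assoc$peak, levels = unique(peaks$name)))
  structure(assoc,
            gene2peak_count = setNames(as.integer(g2p), names(g2p)),
            peak2gene_count = setNames(as.integer(p2g), names(p2g)),
            n_skipped_peaks = sum(skipped),
            class = c("peak_gene_associations", "data.frame"))
}

#' Transcription factor association score per gene
#'
#' `TFAS(gene) = sum over associated peaks of score * exp(-distance/d0)`:
#' peak evidence decays exponentially with the peak-to-start-codon
#' distance. Genes without associated peaks score 0.
#'
#' @param associations Output of [assign_peaks_to_genes()].
#' @param d0 Distance scale in bp (default 500).
#' @return Named numeric vector over all annotation genes.
#' @export
compute_tfas <- function(associations, d0 = 500) {
  if (d0 <= 0) stop("d0 must be positive")
  genes <- names(attr(associations, "gene2peak_count"))
  contrib <- associations$score * exp(-associations$distance / d0)
  s <- tapply(contrib, factor(associations$gene, levels = genes), sum)
  out <- setNames(as.numeric(s), genes)
  out[is.na(out)] <- 0
  out
}

#' Exclusive and joint target sets of two factors
#'
#' Targets of factor A are genes with `TFAS_A > cutoff_a` (strict), and
#' likewise for B; the three returned sets (A only, B only, both)
#' partition the union of targets.
#'
#' @param tfas_a,tfas_b Named TFAS vectors on the same annotation. Either
#'   may be a list of vectors from replicate peak sets, in which case a
#'   gene is a target if it passes the cutoff in any replicate (union
#'   rule).
#' @param cutoff_a,cutoff_b Strict TFAS cutoffs (defaults 10 and 0.5).
#' @return List with `a_only`, `b_only`, `both` (character vectors).
#' @export
build_target_sets <- function(tfas_a, tfas_b, cutoff_a = 10,
                              cutoff_b = 0.5) {
  pass <- function(x, cut) {
    if (is.list(x))
      unique(unlist(lapply(x, function(v) names(v)[v > cut])))
    else names(x)[x > cut]
  }
  a <- pass(tfas_a, cutoff_a)
  b <- pass(tfas_b, cutoff_b)
  list(a_only = setdiff(a, b), b_only = setdiff(b, a),
       both = intersect(a, b))
}
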