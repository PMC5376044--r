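#' Normalize qPCR Cp values by reference genes
#'
#' Cp values are transformed into relative quantities using the per-primer
#' amplification efficiency, `quantity = efficiency^(-Cp)` (one cycle less
#' at efficiency 2 doubles the quantity). Each sample is then divided by
#' its normalization factor, the geometric mean of the three reference
#' genes' quantities, which removes sample-wise drift (loading, reverse
#' transcription). Finally each gene is rescaled to its maximum (or mean)
#' across samples.
#'
#' @param cp_table Data frame with columns `gene`, `sample`, `cp` (long
#'   format).
#' @param efficiencies Named numeric of fold-per-cycle amplification
#'   factors per gene (e.g. 1.95), each in `(0, 2]`.
#' @param reference_genes Character vector of reference gene identifiers
#'   (three in the standard design); all must be present in a sample for
#'   it to be kept, otherwise the sample is dropped with a warning.
#' @param rescale `"max"`, `"mean"` or `"none"` per-gene rescaling.
#' @return Data frame `gene`, `sample`, `quantity` (normalized).
#' @export
normalize_qpcr <- function(cp_table, efficiencies, reference_genes,
                           rescale = c("max", "mean", "none")) {
  rescale <- match.arg(rescale)
  need <- c("gene", "sample", "cp")
  if (!all(need %in% names(cp_table)))
    stop("cp_table needs columns gene, sample, cp")
  genes <- unique(cp_table$gene)
  eff <- efficiencies[genes]
  if (anyNA(eff)) stop("missing efficiency for: ",
                       paste(genes[is.na(eff)], collapse = ", "))
  if (any(eff <= 0 | eff > 2))
    stop("efficiencies must lie in (0, 2] fold per cycle")
  if (!all(reference_genes %in% genes))
    stop("reference genes absent from the table")
  q <- efficiencies[cp_table$gene]^(-cp_table$cp)
  df <- data.frame(gene = cp_table$gene, sample = cp_table$sample,
                   quantity = q)
  # per-sample normalization factor: geometric mean of reference genes
  samples <- unique(df$sample)
  ref <- df[df$gene %in% reference_genes, ]
  nf <- tapply(ref$quantity, factor(ref$sample, levels = samples),
               function(x) exp(mean(log(x))))
  n_ref <- tapply(ref$gene, factor(ref$sample, levels = samples),
                  function(g) length(unique(g)))
  bad <- samples[is.na(n_ref) | n_ref < length(unique(reference_genes))]
  if (length(bad)) {
    warning("dropping sample(s) missing a reference gene: ",
            paste(bad, collapse = ", "))
    df <- df[!df$sample %in% bad, ]
  }
  df$quantity <- as.numeric(df$quantity / nf[as.character(df$sample)])
  if (rescale != "none") {
    f <- if (rescale == "max") max else mean
    sc <- tapply(df$quantity, df$gene, f)
    df$quantity <- df$quantity / sc[df$gene]
  }
  rownames(df) <- NULL
  df
}
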