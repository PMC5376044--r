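mk_peaks <- function(center, score, chrom = "chr1",
                     name = sprintf("pk%02d", seq_along(center))) {
  data.frame(chrom = chrom, start = center - 100, end = center + 100,
             name = name, score = score, center = center)
}
mk_genes <- function(pos, chrom = "chr1",
                     gene = sprintf("g%02d", seq_along(pos))) {
  data.frame(gene = gene, chrom = chrom, strand = "+", start_codon = pos)
}

test_that("the 5 kb rule is a strict inequality on center distance", {
  genes <- mk_genes(10000)
  at_bound <- mk_peaks(15000, 5)    # exactly 5000 away
  inside <- mk_peaks(14999, 5)
  expect_equal(nrow(assign_peaks_to_genes(at_bound, genes)), 0)
  a <- assign_peaks_to_genes(inside, genes)
  expect_equal(nrow(a), 1)
  expect_equal(a$distance, 4999)
})

test_that("peaks map to every gene in range, with mapping counts", {
  genes <- mk_genes(c(9000, 11000))
  peak <- mk_peaks(10000, 3)        # 1 kb from both genes
  a <- assign_peaks_to_genes(peak, genes)
  expect_equal(nrow(a), 2)
  expect_equal(unname(attr(a, "peak2gene_count")["pk01"]), 2L)
  expect_equal(unname(attr(a, "gene2peak_count")), c(1L, 1L))
  # chromosome absent from the annotation: skipped and counted
  far <- mk_peaks(10000, 3, chrom = "chrX")
  a2 <- assign_peaks_to_genes(rbind(peak, far), genes)
  expect_equal(attr(a2, "n_skipped_peaks"), 1L)
  expect_equal(nrow(a2), 2)
})

test_that("TFAS has the exponential-decay arithmetic", {
  genes <- mk_genes(10000)
  expect_equal(unname(compute_tfas(
    assign_peaks_to_genes(mk_peaks(10000, 7), genes))), 7)
  expect_equal(unname(compute_tfas(
    assign_peaks_to_genes(mk_peaks(10500, 7), genes), d0 = 500)),
    7 * exp(-1))
  both <- rbind(mk_peaks(10000, 7, name = "a"),
                mk_peaks(10500, 7, name = "b"))
  expect_equal(unname(compute_tfas(assign_peaks_to_genes(both, genes))),
               7 + 7 * exp(-1))
})

test_that("TFAS matches a brute-force quadratic oracle exactly", {
  set.seed(77)
  n_g <- 80; n_p <- 150
  genes <- data.frame(gene = sprintf("g%03d", 1:n_g),
                      chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                      strand = "+",
                      start_codon = sample.int(3e5, n_g))
  centers <- sample.int(3e5, n_p)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n_p, TRUE),
                      start = centers - 50, end = centers + 50,
                      name = sprintf("p%03d", 1:n_p),
                      score = runif(n_p, 0, 20), center = centers)
  got <- assign_peaks_to_genes(peaks, genes, max_distance = 5000)
  tfas <- compute_tfas(got, d0 = 500)
  # oracle: all-pairs scan
  oracle <- setNames(numeric(n_g), genes$gene)
  pairs <- 0L
  for (i in seq_len(n_p)) for (j in seq_len(n_g)) {
    if (peaks$chrom[i] != genes$chrom[j]) next
    d <- abs(peaks$center[i] - genes$start_codon[j])
    if (d < 5000) {
      pairs <- pairs + 1L
      oracle[j] <- oracle[j] + peaks$score[i] * exp(-d / 500)
    }
  }
  expect_equal(nrow(got), pairs)
  expect_equal(tfas, oracle, tolerance = 1e-12)
})

test_that("TFAS is monotone in peaks and in d0", {
  genes <- mk_genes(c(10000, 50000))
  base <- mk_peaks(c(10800, 49000), c(4, 6))
  t1 <- compute_tfas(assign_peaks_to_genes(base, genes))
  t2 <- compute_tfas(assign_peaks_to_genes(
    rbind(base, mk_peaks(11500, 2, name = "extra")), genes))
  expect_true(all(t2 >= t1))
  t3 <- compute_tfas(assign_peaks_to_genes(base, genes), d0 = 1000)
  expect_true(all(t3 >= t1))
})

test_that("target sets use strict cutoffs and partition the union", {
  tf_a <- c(g1 = 10, g2 = 10.01, g3 = 50, g4 = 0)
  tf_b <- c(g1 = 0.5, g2 = 0.49, g3 = 2, g4 = 0.6)
  sets <- build_target_sets(tf_a, tf_b)
  expect_false("g1" %in% unlist(sets))  # exactly at both cutoffs
  expect_setequal(sets$a_only, "g2")
  expect_setequal(sets$b_only, "g4")
  expect_setequal(sets$both, "g3")
  expect_length(intersect(sets$a_only, sets$b_only), 0)
  expect_length(intersect(sets$a_only, sets$both), 0)
  # identical inputs leave only joint targets
  same <- build_target_sets(tf_a, tf_a, cutoff_a = 5, cutoff_b = 5)
  expect_length(same$a_only, 0)
  expect_length(same$b_only, 0)
  # replicate union rule
  reps <- build_target_sets(list(c(g1 = 11, g2 = 1), c(g1 = 1, g2 = 12)),
                            tf_b)
  expect_true(all(c("g1", "g2") %in% c(reps$a_only, reps$both)))
})

test_that("planted synthetic targets are recovered through the file round trip", {
  dir <- tempfile("tfasdata")
  gen <- generate_annotation_and_peaks(n_genes = 120, n_a_only = 15,
                                       n_b_only = 20, n_both = 8,
                                       seed = 13, dir = dir)
  ann <- read_gene_annotation(gen$files$genes, format = "bed")
  pa <- read_peaks_bed(gen$files$peaks_a)
  pb <- read_peaks_bed(gen$files$peaks_b)
  # round-trip parse equality against the in-memory objects
  expect_equal(ann$start_codon, gen$annotation$start_codon)
  expect_equal(ann$gene, gen$annotation$gene)
  expect_equal(pa$center, gen$peaks_a$center)
  expect_equal(pa$score, gen$peaks_a$score, tolerance = 1e-6)
  tf_a <- compute_tfas(assign_peaks_to_genes(pa, ann))
  tf_b <- compute_tfas(assign_peaks_to_genes(pb, ann))
  sets <- build_target_sets(tf_a, tf_b)
  truth <- split(gen$truth$gene, gen$truth$class)
  expect_setequal(sets$a_only, truth$a_only)
  expect_setequal(sets$b_only, truth$b_only)
  expect_setequal(sets$both, truth$both)
})
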