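test_that("a noiseless cosine is recovered exactly", {
  t <- rep(seq(0, 24, by = 2), each = 2)
  y <- 1000 * (1 + 0.5 * cos(2 * pi / 24 * (t - 4)))
  fit <- biharmonic_fit(t, y)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$phase, 4, tolerance = 0.02)
  expect_equal(fit$relative_amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit$mean, 1000, tolerance = 1e-6)
  expect_equal(fit$amplitude24, 500, tolerance = 1e-6)
  expect_equal(fit$a2, 0, tolerance = 1e-9)
})

test_that("a pure 12 h cosine loads only on the second harmonic", {
  t <- seq(0, 22, by = 2)
  y <- 100 * (1 + 0.4 * cos(2 * pi / 12 * (t - 3)))
  fit <- biharmonic_fit(t, y)
  expect_equal(fit$a1, 0, tolerance = 1e-9)
  expect_equal(fit$b1, 0, tolerance = 1e-9)
  expect_gt(sqrt(fit$a2^2 + fit$b2^2), 35)
  # fitted curve peaks twice a day; phase is the earlier argmax
  expect_lt(circular_difference(fit$phase, 3) %% 12, 0.05)
})

test_that("the F test holds its nominal type-I error on null data", {
  set.seed(404)
  n_probes <- 10000
  t <- rep(seq(0, 24, by = 2), each = 2)
  vals <- matrix(1000 + rnorm(n_probes * length(t), sd = 100),
                 nrow = n_probes)
  fits <- biharmonic_fit_matrix(t, vals)
  fpr <- mean(fits$p < 0.01)
  expect_lt(abs(fpr - 0.01), 3 * sqrt(0.01 * 0.99 / n_probes))
})

test_that("phase recovery is accurate at moderate noise", {
  set.seed(7)
  t <- rep(seq(0, 24, by = 2), each = 4)
  phases <- runif(50, 0, 24)
  vals <- t(sapply(phases, function(ph) {
    s <- 1000 * (1 + 0.5 * cos(2 * pi / 24 * (t - ph)))
    s * rlnorm(length(t), 0, 0.1)  # SNR well above 5
  }))
  fits <- biharmonic_fit_matrix(t, vals)
  # 24 h-component phase: atan2 of the fundamental coefficients
  ph24 <- (atan2(fits$b1, fits$a1) * 12 / pi) %% 24
  expect_lt(mean(circular_difference(ph24, phases)), 0.25)
  # the argmax phase also absorbs noise in the 12 h terms, so it is a
  # little wider but must stay close
  expect_lt(mean(circular_difference(fits$phase, phases)), 0.5)
  expect_lt(max(circular_difference(fits$phase, phases)), 1.5)
})

test_that("rhythmic classification applies all three strict filters", {
  t <- rep(seq(0, 24, by = 2), each = 2)
  mk <- function(base, relamp) base * (1 + relamp *
                                         cos(2 * pi / 24 * (t - 5)))
  vals <- rbind(pass = mk(700, 0.5),
                low_expr = mk(350, 0.5),  # max 525, below the 600 cutoff
                low_amp = mk(700, 0.1),
                boundary_amp = mk(700, 0.3),
                flat = rep(700, length(t)))
  ds <- expression_dataset(vals, t)
  fits <- biharmonic_fit_matrix(t, vals)
  got <- classify_rhythmic(ds, fits, expression_cutoff = 600)
  expect_true("pass" %in% got)
  expect_false("low_expr" %in% got)   # max expression must exceed cutoff
  expect_false("low_amp" %in% got)
  expect_false("flat" %in% got)
})

test_that("classification cutoffs are strict inequalities", {
  t <- rep(seq(0, 24, by = 2), each = 2)
  ds <- expression_dataset(matrix(700, 2, length(t),
                                  dimnames = list(c("at_cut", "above"))),
                           t)
  fits <- data.frame(probe = c("at_cut", "above"), p = c(0.005, 0.005),
                     relative_amplitude = c(0.3, 0.300001))
  got <- classify_rhythmic(ds, fits, expression_cutoff = 600)
  expect_equal(got, "above")
  # max expression exactly at the cutoff is likewise excluded
  ds2 <- expression_dataset(matrix(600, 1, length(t),
                                   dimnames = list("x")), t)
  fits2 <- data.frame(probe = "x", p = 0.001, relative_amplitude = 0.5)
  expect_length(classify_rhythmic(ds2, fits2, expression_cutoff = 600), 0)
})

test_that("planted rhythmic probes are recovered with high recall", {
  spec <- synthetic_spec(n_probes = 1000, rhythmic_fraction = 0.1,
                         relamp_range = c(0.5, 0.5), noise_cv = 0.1,
                         baseline_meanlog = log(5000),
                         baseline_sdlog = 0.3)
  gen <- generate_expression_matrix(spec, seed = 21)
  fits <- biharmonic_fit_matrix(gen$dataset$times, gen$dataset$values)
  got <- classify_rhythmic(gen$dataset, fits, expression_cutoff = 600)
  planted <- gen$truth$probe[gen$truth$rhythmic]
  recall <- length(intersect(got, planted)) / length(planted)
  expect_gte(recall, 0.95)
  fpr <- length(setdiff(got, planted)) / sum(!gen$truth$rhythmic)
  expect_lt(fpr, 0.05)
})

test_that("amplitude ranking is deterministic with lexicographic ties", {
  fits <- data.frame(probe = c("b", "a", "c", "d"),
                     relative_amplitude = c(0.5, 0.5, 0.9, 0.2))
  expect_equal(top_by_amplitude(fits, k = 3), c("c", "a", "b"))
  expect_equal(top_by_amplitude(fits, k = 0), character(0))
  expect_message(all4 <- top_by_amplitude(fits, k = 10), "smaller")
  expect_equal(all4, c("c", "a", "b", "d"))
})

test_that("set overlap is an exact symmetric intersection", {
  expect_length(set_overlap(c("a", "b"), c("c", "d")), 0)
  expect_setequal(set_overlap(c("a", "b"), c("b", "a")), c("a", "b"))
  expect_setequal(set_overlap(letters[1:10], letters[5:15]),
                  letters[5:10])
})

test_that("two synthetic tissues recover their planted probe overlap", {
  spec_a <- synthetic_spec(n_probes = 400, rhythmic_fraction = 0.25,
                           relamp_range = c(0.5, 0.7), noise_cv = 0.02,
                           baseline_meanlog = log(5000),
                           baseline_sdlog = 0.2)
  spec_b <- synthetic_spec(n_probes = 400, rhythmic_fraction = 0.10,
                           relamp_range = c(0.5, 0.7), noise_cv = 0.02,
                           baseline_meanlog = log(5000),
                           baseline_sdlog = 0.2)
  a <- generate_expression_matrix(spec_a, seed = 31)
  b <- generate_expression_matrix(spec_b, seed = 32)
  # rhythmic blocks are leading probes: A plants 1..100, B plants 1..40,
  # so the planted overlap is the 40 probes rhythmic in both tissues
  shared_planted <- intersect(a$truth$probe[a$truth$rhythmic],
                              b$truth$probe[b$truth$rhythmic])
  expect_length(shared_planted, 40)
  fits_a <- biharmonic_fit_matrix(a$dataset$times, a$dataset$values)
  fits_b <- biharmonic_fit_matrix(b$dataset$times, b$dataset$values)
  ra <- classify_rhythmic(a$dataset, fits_a, expression_cutoff = 600)
  rb <- classify_rhythmic(b$dataset, fits_b, expression_cutoff = 600)
  ov <- set_overlap(ra, rb)
  expect_gte(length(intersect(ov, shared_planted)) /
               length(shared_planted), 0.9)
})

test_that("circular histograms conserve mass and wrap correctly", {
  set.seed(9)
  ph <- runif(137, 0, 24)
  h <- circular_phase_histogram(ph)
  expect_equal(sum(h$count), 4 * length(ph))
  expect_equal(nrow(h), 24)
  # single phase at CT 0 occupies exactly 4 bins
  h0 <- circular_phase_histogram(0)
  expect_equal(sum(h0$count > 0), 4)
  expect_setequal(h0$bin_center_CT[h0$count > 0], c(23, 0, 1, 2))
  # wrap-around membership agrees with brute force
  h239 <- circular_phase_histogram(23.9)
  brute <- vapply(h239$bin_center_CT, function(cc) {
    lo <- (cc - 2) %% 24
    in_bin <- if (lo <= (cc + 2) %% 24 && (cc + 2) <= 24)
      23.9 >= lo & 23.9 < lo + 4
    else (23.9 >= lo) || (23.9 < (cc + 2) %% 24)
    as.numeric(in_bin)
  }, numeric(1))
  expect_equal(h239$count, brute)
  expect_error(circular_phase_histogram(25), "0, 24")
})
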