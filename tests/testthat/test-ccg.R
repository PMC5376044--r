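const_clock <- function(levels, t_end = 200, dt = 0.05) {
  t <- seq(0, t_end, by = dt)
  trajectory(t, sapply(levels, rep, length(t)), dt)
}

test_that("an RRE-only CCG on a frozen clock reaches the closed-form level", {
  rbar <- 3
  tr <- const_clock(c(Bmal1 = 1, RevErba = rbar, Per2 = 1, Cry1 = 1,
                      Dbp = 1))
  ccg <- ccg_parameters(list(rre = list(strength = 0.8, sites = 2,
                                        delay = 4)), d_ccg = 0.4)
  out <- simulate_ccg(tr, ccg)
  expect_equal(tail(out$species[, 1], 1), (1 + 0.8 * rbar)^(-2),
               tolerance = 1e-6)
})

test_that("a missing driver species is an error", {
  t <- seq(0, 100, by = 0.05)
  tr <- trajectory(t, cbind(Bmal1 = rep(1, length(t))))
  ccg <- ccg_parameters(list(rre = list(strength = 1, delay = 2)))
  expect_error(simulate_ccg(tr, ccg), "absent")
})

test_that("output peaks lag sinusoidal production by arctan(omega/d)/omega", {
  # drive a CCG so that its production term is 1 + eps*cos(omega t):
  # RevErba is prescribed to invert the RRE modulator exactly
  w <- 2 * pi / 24
  eps <- 0.05
  t <- seq(0, 480, by = 0.05)
  M <- 0.5 * (1 + eps * cos(w * t))  # stays in (0, 1]: invertible via RRE
  R <- (1 / M - 1)                   # strength 1, one site
  tr <- trajectory(t, cbind(Bmal1 = rep(1, length(t)), RevErba = R,
                            Per2 = rep(1, length(t)),
                            Cry1 = rep(1, length(t)),
                            Dbp = rep(1, length(t))))
  for (d in c(0.2, 0.6)) {
    ccg <- ccg_parameters(list(rre = list(strength = 1, sites = 1,
                                          delay = 0)), d_ccg = d)
    out <- simulate_ccg(tr, ccg)
    last <- window_trajectory(out, from = 480 - 24)
    pk <- find_peaks(last$time, last$species[, 1],
                     min_level = min(last$species[, 1]))
    lag <- (pk$time[which.max(pk$value)] %% 24) - 0  # M peaks at t = 0 mod 24
    lag <- lag %% 24
    expect_equal(lag, atan(w / d) / w, tolerance = 0.1)
  }
})

test_that("faster mRNA decay strictly advances CCG peak phases", {
  tr <- default_traj()
  de <- default_descriptors()
  ct <- attr(de, "ct")
  per <- mean(de$period)
  phases <- vapply(seq(0.2, 0.6, by = 0.1), function(d) {
    ccg <- ccg_parameters(list(rre = list(strength = 1, sites = 1,
                                          delay = 2)), d_ccg = d)
    ccg_peak_phase(tr, simulate_ccg(tr, ccg), ct, per)$phase
  }, numeric(1))
  steps <- (diff(phases) + 12) %% 24 - 12  # signed circular steps
  expect_true(all(steps < 0))
})

test_that("the harmonic product equals its trigonometric expansion", {
  t <- seq(0, 96, by = 0.1)
  w <- 2 * pi / 24
  set.seed(1)
  for (i in 1:5) {
    A <- runif(1)
    al <- runif(1, 0, 360)
    a <- al * pi / 180
    expansion <- 1 + sin(w * t) + A * sin(w * t + a) +
      (A / 2) * (cos(a) - cos(2 * w * t + a))
    expect_equal(harmonic_product(t, A, al), expansion, tolerance = 1e-12)
  }
  expect_equal(harmonic_product(t, 0, 90), 1 + sin(w * t))
  # out-of-phase unit regulators: pure 12 h rhythm 1/2 + cos(2wt)/2
  expect_equal(harmonic_product(t, 1, 180), 0.5 + 0.5 * cos(2 * w * t),
               tolerance = 1e-12)
})

test_that("dominant_period separates 24 h from harmonic 12 h signals", {
  t <- seq(0, 96, by = 0.1)
  expect_equal(dominant_period(harmonic_product(t, 1, 180), t), 12)
  expect_equal(dominant_period(harmonic_product(t, 0, 0), t), 24)
  expect_equal(dominant_period(harmonic_product(t, 0.3, 90), t), 24)
  expect_warning(pd <- dominant_period(rep(1, length(t)), t), "flat")
  expect_true(is.na(pd))
  expect_error(dominant_period(sin(seq(0, 47, by = 0.1)),
                               seq(0, 47, by = 0.1)), "4 cycles")
})

test_that("combinatorial E-box/D-box drive can generate 12 h harmonics", {
  # out-of-phase matched drivers cancel the circadian fundamental: pick
  # the E-box delay and D-box strength so the two log-factor fundamentals
  # oppose, then scan a small grid around that point for a regime where
  # the second harmonic dominates
  tr <- default_traj()
  post <- window_trajectory(tr, from = 480 - 96)
  mid <- apply(window_trajectory(tr, from = 240)$species, 2,
               function(x) sqrt(max(x) * max(min(x), 1e-12)))
  t <- post$time
  four1 <- function(x) sum((x - mean(x)) * exp(-2i * pi * t / 24))
  sp <- post$species
  zE <- four1(log(ebox_modulator(sp[, "Bmal1"], sp[, "Per2"],
                                 sp[, "Cry1"], 1 / mid["Bmal1"],
                                 1 / mid["Per2"], 1 / mid["Cry1"], 3, 1)))
  zD <- four1(log(dbox_modulator(sp[, "Dbp"], 1 / mid["Dbp"], 3, 1)))
  de <- ((Arg(zE) - Arg(-zD)) * 12 / pi) %% 24
  ratio <- Mod(zE) / Mod(zD)
  found <- FALSE
  for (r in ratio * c(0.7, 1, 1.5)) for (dccg in c(0.5, 1)) {
    ccg <- ccg_parameters(list(
      ebox = list(strength = 1 / mid["Bmal1"],
                  strength_per = 1 / mid["Per2"],
                  strength_cry = 1 / mid["Cry1"],
                  fold = 3, sites = 1, delay = de),
      dbox = list(strength = r / mid["Dbp"], fold = 3, sites = 1,
                  delay = 0)),
      d_ccg = dccg)
    out <- simulate_ccg(tr, ccg)
    pd <- dominant_period(window_trajectory(out, from = 480 - 96))
    if (isTRUE(all.equal(pd, 12))) found <- TRUE
  }
  expect_true(found)
})

test_that("CCG populations are seed-stable with distinct driver modes", {
  tr <- default_traj()
  rre1 <- sample_ccg_population(tr, "rre", n = 80, seed = 1)
  rre2 <- sample_ccg_population(tr, "rre", n = 80, seed = 1)
  expect_identical(rre1$phases, rre2$phases)
  rre3 <- sample_ccg_population(tr, "rre", n = 80, seed = 2)
  expect_lt(circular_difference(rre1$mode, rre3$mode), 2)
  ebox <- sample_ccg_population(tr, "ebox", n = 80, seed = 1)
  expect_gt(circular_difference(rre1$mode, ebox$mode), 6)
  expect_equal(length(rre1$phases) + rre1$n_excluded, 80)
})

test_that("CCG target fitting recovers a known gene and flags misfits", {
  tr <- default_traj()
  de <- default_descriptors()
  ct <- attr(de, "ct")
  per <- mean(de$period)
  truth <- ccg_parameters(list(rre = list(strength = 2, sites = 1,
                                          delay = 4)), d_ccg = 0.35)
  ref <- ccg_peak_phase(tr, simulate_ccg(tr, truth), ct, per)
  fit <- fit_ccg_to_target(tr, ref$phase, ref$relamp, drivers = "rre",
                           n_candidates = 200, seed = 5)
  expect_false(fit$no_fit)
  expect_lt(fit$phase_error, 0.5)
  # an RRE-only promoter cannot put a high-amplitude peak at mid-day CT 8
  bad <- fit_ccg_to_target(tr, 8, 0.8, drivers = "rre",
                           n_candidates = 200, seed = 5)
  good <- fit_ccg_to_target(tr, 8, 0.8, drivers = c("rre", "ebox"),
                            n_candidates = 200, seed = 5)
  expect_true(bad$no_fit || bad$phase_error > good$phase_error)
  expect_false(good$no_fit)
})
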