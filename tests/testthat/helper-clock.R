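# shared fixtures: simulate the shipped default model once per session
.fixture_env <- new.env(parent = emptyenv())

default_traj <- function() {
  if (is.null(.fixture_env$traj))
    .fixture_env$traj <- simulate_clock(default_clock_parameters(),
                                        t_end = 480, dt = 0.05)
  .fixture_env$traj
}

default_descriptors <- function() {
  if (is.null(.fixture_env$descr))
    .fixture_env$descr <- extract_rhythm_descriptors(default_traj())
  .fixture_env$descr
}

# a trajectory whose species are prescribed sinusoids (for oracle tests)
cosine_trajectory <- function(t_end = 480, dt = 0.05, mean = 1, amp = 0.5,
                              period = 24, peaks = c(Bmal1 = 0, RevErba = 6,
                                                     Per2 = 10, Cry1 = 18,
                                                     Dbp = 11)) {
  t <- seq(0, t_end, by = dt)
  X <- sapply(names(peaks), function(g) {
    mean * (1 + amp * cos(2 * pi / period * (t - peaks[g])))
  })
  trajectory(t, X, dt)
}
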