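test_that("instantaneous phase interpolates linearly within each cycle", {
  ps <- instantaneous_phase(event_series(c(0, 1, 2)), fs_phase = 100)
  expect_equal(ps$phi[ps$t == 0.5], pi, tolerance = 1e-12)
  expect_equal(ps$phi[ps$t == 1.75], 3 * pi / 2, tolerance = 1e-12)
  # denominator is the local cycle length
  ps2 <- instantaneous_phase(event_series(c(0, 2)), fs_phase = 100)
  expect_equal(ps2$phi[ps2$t == 0.5], pi / 2, tolerance = 1e-12)
  # wraps exactly at events, stays in [0, 2*pi)
  expect_equal(ps$phi[ps$t == 1], 0)
  expect_true(all(ps$phi >= 0 & ps$phi < 2 * pi))
  expect_lt(2 * pi - ps$phi[ps$t == 0.99], 0.1)
  expect_error(instantaneous_phase(event_series(1)),
               class = "insufficient_data_error")
})

test_that("relative phase of matched trains is constant; detuning drifts", {
  inp <- instantaneous_phase(periodic_events(1, 21, label = "input"))
  # identical event series
  rp0 <- relative_phase(instantaneous_phase(periodic_events(1, 21)), inp)
  expect_equal(max(abs(rp0$dphi)), 0)
  # constant-lag output: dphi is constant at 2*pi*(1 - lag/T)
  rp1 <- relative_phase(
    instantaneous_phase(periodic_events(1, 20, t0 = 0.25)), inp)
  expect_equal(unique(round(rp1$dphi, 9)), 3 * pi / 2, tolerance = 1e-9)
  rp3 <- relative_phase(
    instantaneous_phase(periodic_events(1, 20, t0 = 0.75)), inp)
  expect_equal(unique(round(rp3$dphi, 9)), pi / 2, tolerance = 1e-9)
  # 1.1 Hz output vs 1.0 Hz input: unwrapped slope 2*pi*0.1 per second
  out <- instantaneous_phase(periodic_events(1 / 1.1, 133, label = "output"))
  rp <- relative_phase(out, instantaneous_phase(periodic_events(1, 121,
                                                label = "input")))
  n <- length(rp$t)
  slope <- (rp$dphi_unwrapped[n] - rp$dphi_unwrapped[1]) / (rp$t[n] - rp$t[1])
  expect_equal(slope, 2 * pi * 0.1, tolerance = 1e-6)
})

test_that("relative-phase histogram is a probability over 21 bins", {
  h <- relative_phase_histogram(make_rp(rep(1.3, 500)))
  expect_equal(sum(h$prob), 1)
  expect_equal(h$max_prob, 1)
  # uniform midpoint grid with n divisible by 21: all bins equal
  n <- 210
  h2 <- relative_phase_histogram(make_rp(2 * pi * ((0:(n - 1)) + 0.5) / n))
  expect_equal(h2$prob, rep(1 / 21, 21))
  expect_equal(h2$max_prob, 1 / 21)
  # the maximum can never fall below 1/n_bins
  for (s in 1:20) {
    set.seed(2000 + s)
    h3 <- relative_phase_histogram(runif(97, 0, 2 * pi))
    expect_gte(h3$max_prob, 1 / 21)
  }
})

test_that("Rayleigh test matches its closed-form extremes", {
  rt <- rayleigh_test(rep(1.1, 20))
  expect_equal(rt$r_bar, 1, tolerance = 1e-12)
  expect_equal(rt$Z, 20, tolerance = 1e-9)
  expect_lt(rt$p, 1e-6)
  # a uniform grid of n = 21 angles has zero resultant
  rt2 <- rayleigh_test(2 * pi * (0:20) / 21)
  expect_lt(rt2$r_bar, 1e-12)
  expect_equal(rt2$p, 1, tolerance = 1e-9)
  expect_error(rayleigh_test(1), class = "insufficient_data_error")
})

test_that("Rayleigh test is calibrated on uniform angles", {
  set.seed(314)
  rej <- vapply(1:2000, function(i) {
    rayleigh_test(runif(100, 0, 2 * pi))$p < 0.05
  }, logical(1))
  # binomial 99% CI around 0.05 at n = 2000
  expect_gte(sum(rej), qbinom(0.005, 2000, 0.05))
  expect_lte(sum(rej), qbinom(0.995, 2000, 0.05))
})

test_that("phase coherence matches closed-form windows", {
  # constant relative phase: gamma = 1
  cs <- phase_coherence(make_rp(rep(0.7, 400)), window_w = 3)
  expect_equal(max(abs(cs$gamma - 1)), 0, tolerance = 1e-9)
  expect_equal(cs$t[1], 3)  # defined only once the window is complete
  # one full uniform sweep inside the window: vectors cancel
  N <- 301
  cs2 <- phase_coherence(make_rp(2 * pi * (0:(N - 1)) / N), window_w = 3)
  expect_lt(max(cs2$gamma), 1e-12)
  # antipodal half-half window (even sample count): exact cancellation
  cs3 <- phase_coherence(make_rp(rep(c(0, pi), each = 50), fs = 33),
                         window_w = 3)
  expect_lt(cs3$gamma[1], 1e-24)
  expect_error(phase_coherence(make_rp(rep(0, 10)), window_w = 3),
               class = "insufficient_data_error")
})

test_that("bout detection reports exact boundaries on a square wave", {
  fs <- 100
  gam <- c(rep(1, 10 * fs), rep(0, 5 * fs), rep(1, 10 * fs))
  bouts <- detect_bouts(make_cs(gam, fs = fs, t0 = 0),
                        rp = make_rp(rep(0.2, length(gam)), fs = fs),
                        stim_start = 0)
  expect_equal(bouts$n_bouts, 2L)
  expect_equal(bouts$bouts$duration, c(10, 10))
  expect_equal(bouts$bouts$start, c(0, 15))
  expect_equal(bouts$latency, 0)
  expect_equal(bouts$n_slips, 0L)
  expect_equal(bouts$mean_bout_duration, 10)
  # no bout: empty list, censored latency
  none <- detect_bouts(make_cs(rep(0.5, 100)), stim_start = 0)
  expect_equal(none$n_bouts, 0L)
  expect_true(is.na(none$latency))
})

test_that("phase slips count completed 2*pi excursions", {
  fs <- 100
  # relative phase that advances by exactly 3 cycles over the epoch
  dphi <- (2 * pi * 3) * (0:999) / 1000
  b <- detect_bouts(make_cs(rep(0, 1000), fs = fs),
                    rp = make_rp(dphi %% (2 * pi), fs = fs), stim_start = 0)
  expect_equal(b$n_slips, 3L)
})

test_that("a fully locked trial yields one bout spanning the epoch", {
  p <- osc_params(2, cv_period = 0, coupling_k = 1, seed = 9)
  tr <- simulate_forced_trial(p, std_stim())
  ph <- phases_of(tr)
  rp <- relative_phase(ph$out, ph$inp)
  cs <- phase_coherence(rp)
  b <- detect_bouts(cs, rp, stim_start = 0)
  expect_equal(b$n_bouts, 1L)
  expect_equal(b$n_slips, 0L)
  # latency is about the window fill time at the start of the domain
  expect_lt(b$latency, cs$window_w + 1.5)
  expect_gt(b$total_bout_duration, 100)
})

test_that("synchronization index matches closed-form constructions", {
  inp <- instantaneous_phase(periodic_events(1, 101, label = "input"))
  outp <- instantaneous_phase(periodic_events(1, 101))
  expect_equal(synchronization_index(outp, inp), 1.0, tolerance = 1e-12)
  # independent uniform phases: Rayleigh-statistic null ~ 0.0089 at N = 1e4
  set.seed(41)
  val <- entrainkit:::sync_from_phases(runif(1e4, 0, 2 * pi),
                                       runif(1e4, 0, 2 * pi))
  expect_lt(val, 0.05)
  # output at exactly twice the input frequency: 1:2 locking
  out2 <- instantaneous_phase(periodic_events(0.5, 201))
  expect_equal(synchronization_index(out2, inp, n = 1, m = 2), 1.0,
               tolerance = 1e-9)
  expect_lt(synchronization_index(out2, inp, n = 1, m = 1), 0.01)
})

test_that("phase metrics are invariant under a common time shift", {
  tr <- preset_trial("wildtype", seed = 21)
  ph <- phases_of(tr)
  sync0 <- synchronization_index(ph$out, ph$inp)
  mi0 <- mutual_information(joint_phase_histogram(ph$out, ph$inp))$mi
  shift <- 12.34
  inp2 <- instantaneous_phase(
    event_series(tr$input_events$times + shift, "input"))
  out2 <- instantaneous_phase(
    event_series(tr$output_events$times + shift))
  expect_equal(synchronization_index(out2, inp2), sync0, tolerance = 1e-6)
  expect_equal(mutual_information(joint_phase_histogram(out2, inp2))$mi,
               mi0, tolerance = 0.01)
})
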