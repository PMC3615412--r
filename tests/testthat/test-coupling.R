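test_that("square wave is 1 exactly on each pulse", {
  ev <- event_series(c(0.2, 1.0, 2.5), "input")
  sw <- square_wave(ev, pulse_width = 0.1, fs = 1000, t_range = c(0, 3))
  on <- sw$value == 1
  expect_true(all(on[sw$time >= 0.2 & sw$time < 0.3]))
  expect_true(all(on[sw$time >= 1.0 & sw$time < 1.1]))
  expect_false(any(on[sw$time < 0.2 - 1e-9 | (sw$time >= 0.3 + 1e-9 &
                                              sw$time < 1.0 - 1e-9)]))
})

test_that("cross-correlogram peaks at unit correlation for identical input", {
  ev <- event_series(c(0.2, 1.1, 2.7, 3.4, 5.0, 6.2), "input")
  sw <- square_wave(ev, 0.2, fs = 500, t_range = c(0, 7))
  xc <- normalized_cross_correlogram(sw, sw, max_lag = 1)
  expect_equal(xc$peak, 1, tolerance = 1e-9)
  expect_equal(xc$peak_lag, 0)
})

test_that("cross-correlogram locates a constant lag", {
  ev <- event_series(c(0.2, 1.1, 2.7, 3.4, 5.0, 6.2), "input")
  lag <- 0.3
  sw_in <- square_wave(ev, 0.2, fs = 500, t_range = c(0, 7.5))
  sw_out <- square_wave(event_series(ev$times + lag), 0.2, fs = 500,
                        t_range = c(0, 7.5))
  xc <- normalized_cross_correlogram(sw_out, sw_in, max_lag = 1)
  expect_equal(xc$peak_lag, lag, tolerance = 1e-9)
  expect_gt(xc$peak, 0.9)
  # amplitude rescaling of either raw signal is absorbed by min-max scaling
  big <- continuous_trace(sw_out$time, sw_out$value * 37 + 5)
  xc2 <- normalized_cross_correlogram(big, sw_in, max_lag = 1)
  expect_equal(xc2$peak, xc$peak, tolerance = 1e-12)
})

test_that("a constant signal is rejected as degenerate", {
  flat <- continuous_trace(seq(0, 5, by = 0.01), rep(1, 501))
  ev <- event_series(c(1, 2, 3), "input")
  sw <- square_wave(ev, 0.1, fs = 100, t_range = c(0, 5))
  expect_error(normalized_cross_correlogram(flat, sw, max_lag = 1),
               class = "parameter_error")
})

test_that("joint phase histogram concentrates on the (shifted) diagonal", {
  inp <- instantaneous_phase(periodic_events(0.5, 101, label = "input"))
  outp <- instantaneous_phase(periodic_events(0.5, 101))
  jh <- joint_phase_histogram(outp, inp, L = 50)
  expect_equal(sum(diag(jh$counts)), jh$n)
  expect_equal(sum(jh$P), 1)
  # marginals equal the individual phase histograms
  expect_equal(colSums(jh$counts),
               tabulate(entrainkit:::wrap_bins(inp$phi, 50), 50))
  # constant relative phase of a whole number of bins: shifted diagonal
  phi <- 2 * pi * ((0:9999) %% 50 + 0.5) / 50
  jh2 <- entrainkit:::joint_hist_from_phases((phi + 2 * pi * 7 / 50) %%
                                               (2 * pi), phi, 50)
  shifted_mass <- sum(jh2$counts[cbind((((0:49) + 7) %% 50) + 1, 1:50)])
  expect_equal(shifted_mass, jh2$n)
})

test_that("independent drifting phases fill the joint histogram uniformly", {
  ok <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    jh <- entrainkit:::joint_hist_from_phases(runif(5e4, 0, 2 * pi),
                                              runif(5e4, 0, 2 * pi), 50)
    E <- jh$n / 2500
    x2 <- sum((jh$counts - E)^2 / E)
    stats::pchisq(x2, df = 2499, lower.tail = FALSE) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("entropy matches closed forms and validates input", {
  expect_equal(entropy(rep(1 / 50, 50)), log(50), tolerance = 1e-12)
  expect_equal(entropy(c(1, rep(0, 9))), 0)
  expect_equal(entropy(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)
  expect_error(entropy(c(-0.1, 1.1)), class = "format_error")
  expect_error(entropy(c(0.3, 0.3)), class = "format_error")
})

test_that("mutual information obeys its information-theoretic identities", {
  # exact product joint: zero MI
  p <- c(0.1, 0.2, 0.3, 0.4)
  q <- c(0.25, 0.25, 0.4, 0.1)
  jh <- structure(list(counts = outer(p, q) * 1000, P = outer(p, q),
                       L = 4L, n = 1000L),
                  class = "joint_phase_histogram")
  expect_equal(mutual_information(jh)$mi, 0, tolerance = 1e-9)
  # deterministic 1:1 locking: MI -> ln L (diagonal joint histogram);
  # events offset from the grid so samples fall strictly inside bins
  inp <- instantaneous_phase(periodic_events(0.5, 481, t0 = 0.003,
                                             label = "input"))
  outp <- instantaneous_phase(periodic_events(0.5, 481, t0 = 0.003))
  mi <- mutual_information(joint_phase_histogram(outp, inp, L = 50))
  expect_equal(mi$mi, log(50), tolerance = 0.01)
  expect_equal(mi$mi, min(mi$h_in, mi$h_out), tolerance = 1e-9)
  # symmetry and whole-bin rotation invariance on a noisy trial
  tr <- preset_trial("intermediate", seed = 31)
  ph <- phases_of(tr)
  jh_oi <- joint_phase_histogram(ph$out, ph$inp)
  jh_io <- joint_phase_histogram(ph$inp, ph$out)
  expect_equal(mutual_information(jh_oi)$mi, mutual_information(jh_io)$mi,
               tolerance = 1e-12)
  # whole-bin rotation of both axes leaves MI unchanged (generic phases,
  # no samples on bin edges)
  set.seed(91)
  pa <- runif(1e4, 0, 2 * pi)
  pb <- (pa + rnorm(1e4, 0, 0.3)) %% (2 * pi)
  rot <- 2 * pi * 13 / 50
  expect_equal(entrainkit:::mi_from_phases((pa + rot) %% (2 * pi),
                                           (pb + rot) %% (2 * pi), 50),
               entrainkit:::mi_from_phases(pa, pb, 50), tolerance = 1e-9)
  expect_lte(mutual_information(jh_oi)$mi,
             min(mutual_information(jh_oi)$h_in,
                 mutual_information(jh_oi)$h_out) + 1e-9)
  # literal conditional-entropy variant
  mp <- mutual_information(jh_oi, formula = "as_printed")
  expect_equal(mp$mi, mp$h_in + 2 * mp$h_out - mp$h_joint, tolerance = 1e-12)
})

test_that("binned MI on independent phases shows the finite-sample bias", {
  # Miller-Madow: bias ~ (L-1)^2 / (2N) = 0.12 nats at L = 50, N = 1e4
  set.seed(55)
  mis <- vapply(1:200, function(i) {
    entrainkit:::mi_from_phases(runif(1e4, 0, 2 * pi),
                                runif(1e4, 0, 2 * pi), 50)
  }, numeric(1))
  bias <- (50 - 1)^2 / (2 * 1e4)
  expect_gt(mean(mis), 0.5 * bias)
  expect_lt(mean(mis), 1.5 * bias)
})
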