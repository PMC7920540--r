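test_that("spike detection finds injected waveforms and respects the criterion", {
  t <- seq(0, 500, by = 0.025)
  # flat trace: nothing
  flat <- make_trace(t, rep(-70, length(t)), stimulus(total_ms = 500))
  expect_equal(nrow(detect_spikes(flat)), 0L)
  # three injected spike waveforms at known times
  tr <- make_trace(t, inject_spikes(t, -70, c(100, 200, 300)),
                   stimulus(total_ms = 500))
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$spike_time_ms, c(100, 200, 300), tolerance = 1)
  expect_true(all(sp$threshold_mV > -70 & sp$threshold_mV < 0))
  # slow ramp never crossing 10 mV/ms: no spikes even though V gets high
  ramp <- make_trace(t, -70 + 0.15 * t, stimulus(total_ms = 500))
  expect_equal(nrow(detect_spikes(ramp)), 0L)
  # invariance to a uniform voltage offset
  tr_off <- make_trace(t, inject_spikes(t, -60, c(100, 200, 300)),
                       stimulus(total_ms = 500))
  expect_equal(nrow(detect_spikes(tr_off)), 3L)
  # invariance to resampling from 0.025 to 0.05 ms
  t2 <- seq(0, 500, by = 0.05)
  tr2 <- make_trace(t2, inject_spikes(t2, -70, c(100, 200, 300)),
                    stimulus(total_ms = 500))
  expect_equal(nrow(detect_spikes(tr2)), 3L)
  # non-uniform sampling is rejected
  bad <- make_trace(c(0, 1, 3, 4), rep(-70, 4), stimulus(total_ms = 4))
  expect_error(detect_spikes(bad), "uniform")
})

test_that("firing rate applies the 50 ms onset exclusion", {
  sp <- tibble::tibble(spike_time_ms = 230, threshold_mV = -40)
  # a spike 30 ms after onset is excluded entirely
  expect_equal(firing_rate(sp, step_onset = 200, step_duration = 2000), 0)
  # six spikes uniformly spread after the exclusion window
  sp6 <- tibble::tibble(spike_time_ms = seq(300, 2100, length.out = 6),
                        threshold_mV = -40)
  expect_equal(firing_rate(sp6, 200, 2000), 6 / 1.95, tolerance = 1e-9)
  expect_equal(firing_rate(sp6, 200, 2000), 3.08, tolerance = 1e-2)
  expect_equal(firing_rate(sp6[0, ], 200, 2000), 0)
})

test_that("Boltzmann F-I fitting recovers generating parameters", {
  gen <- function(i, fmax = 30, i_half = 200, k = 40)
    fmax / (1 + exp((i_half - i) / k))
  amps <- seq(30, 360, by = 30)
  fi <- tibble::tibble(current_pA = amps, rate_Hz = gen(amps))
  fit <- fit_fi_boltzmann(fi)
  expect_true(fit$converged)
  expect_equal(fit$fmax, 30, tolerance = 0.01)
  expect_equal(fit$i_half, 200, tolerance = 0.01 * 200)
  expect_equal(fit$k, 40, tolerance = 0.01 * 40)
  # noiseless round trip: inversion at the generating rate is exact
  expect_equal(rheobase(fit, target_rate_Hz = gen(137)), 137, tolerance = 0.1)
  # noisy recovery within 10% at fixed seed
  set.seed(1)
  fin <- tibble::tibble(current_pA = amps,
                        rate_Hz = pmax(gen(amps) + rnorm(12, 0, 1), 0))
  fitn <- fit_fi_boltzmann(fin)
  expect_true(fitn$converged)
  expect_lt(abs(fitn$fmax - 30) / 30, 0.1)
  expect_lt(abs(fitn$i_half - 200) / 200, 0.1)
  expect_lt(abs(fitn$k - 40) / 40, 0.1)
  # degenerate data: no fit, rheobase undefined
  fi0 <- tibble::tibble(current_pA = amps, rate_Hz = 0)
  fit0 <- fit_fi_boltzmann(fi0)
  expect_false(fit0$converged)
  expect_true(is.na(rheobase(fit0)))
  expect_error(fit_fi_boltzmann(fi[1:3, ]), "4")
  # tidy/glance accessors
  expect_equal(tidy(fit)$term, c("fmax", "i_half", "k"))
  expect_true(glance(fit)$converged)
})

test_that("rheobase inversion matches the closed form", {
  fit <- structure(list(converged = TRUE, fmax = 30, i_half = 200, k = 40,
                        sigma = 0, data = NULL), class = "fi_fit")
  expect_equal(rheobase(fit, 15), 200)                      # half-max point
  expect_equal(rheobase(fit, 3), 200 - 40 * log(9), tolerance = 1e-9)
  expect_equal(rheobase(fit, 3), 112.1, tolerance = 1e-3)
  expect_warning(r <- rheobase(fit, 30), "undefined")
  expect_true(is.na(r))
  # monotone: lower target rate, lower current
  expect_lt(rheobase(fit, 3), rheobase(fit, 10))
  # linear-interpolation fallback on raw points
  pts <- tibble::tibble(current_pA = c(100, 200, 300),
                        rate_Hz = c(0, 6, 20))
  expect_equal(rheobase(pts, 3, method = "linear"), 150)
  expect_true(is.na(rheobase(pts, 25, method = "linear")))
})

test_that("sag percentage and classification follow their definitions", {
  st <- stimulus(step_pA = -100, onset_ms = 200, dur_ms = 2000,
                 total_ms = 2400)
  t <- seq(0, 2400, by = 0.05)
  # constructed trace: baseline -70, peak deflection 20 mV, ss 15 mV
  v <- rep(-70, length(t))
  in_step <- t > 200 & t <= 2200
  v[in_step] <- -85
  v[t > 200 & t <= 400] <- -70 - 20 * ((t[t > 200 & t <= 400] - 200) / 200)
  v[t > 400 & t <= 700] <- -90 + 5 * ((t[t > 400 & t <= 700] - 400) / 300)
  tr <- make_trace(t, v, st)
  s <- sag_percent(tr)
  expect_equal(s$v_peak_mV, 20)
  expect_equal(s$v_ss_mV, 15)
  expect_equal(s$sag_percent, 25)
  # scale invariance
  tr2 <- make_trace(t, -70 + 2 * (v + 70), st)
  expect_equal(sag_percent(tr2)$sag_percent, 25)
  # no sag when steady state equals peak
  vf <- rep(-70, length(t)); vf[in_step] <- -90
  expect_equal(sag_percent(make_trace(t, vf, st))$sag_percent, 0)
  # wrong protocol
  expect_error(sag_percent(make_trace(t, v, stimulus(step_pA = 100,
                                                     onset_ms = 200,
                                                     dur_ms = 2000,
                                                     total_ms = 2400))),
               "hyperpolarizing")
  # classification threshold is strict
  expect_equal(classify_sag(25), "sag_expressing")
  expect_equal(classify_sag(14.9), "no_sag")
  expect_equal(classify_sag(15), "no_sag")
})

test_that("rebound metrics bin by end-of-step hyperpolarization", {
  st <- stimulus(step_pA = -100, onset_ms = 200, dur_ms = 500,
                 total_ms = 1300)
  t <- seq(0, 1300, by = 0.05)
  v <- rep(-60, length(t))
  v[t > 200 & t <= 700] <- -90            # 30 mV hyperpolarization
  v <- v + inject_spikes(t, 0, c(720, 740, 760)) - 0  # 3 rebound spikes
  tr <- make_trace(t, v, st)
  rm <- rebound_metrics(tr)
  expect_equal(rm$end_hyperpolarization_mV, 30, tolerance = 0.5)
  expect_equal(rm$bin, "20-40")
  expect_equal(rm$rebound_spike_count, 3)
  # no post-step spikes
  tr0 <- make_trace(t, replace(rep(-60, length(t)), t > 200 & t <= 700, -90),
                    st)
  expect_equal(rebound_metrics(tr0)$rebound_spike_count, 0)
  # bin edges: 15 mV -> 0-20, 45 -> 40-60
  for (hyp in c(15, 45)) {
    trh <- make_trace(t, replace(rep(-60, length(t)), t > 200 & t <= 700,
                                 -60 - hyp), st)
    expect_equal(rebound_metrics(trh)$bin,
                 if (hyp < 20) "0-20" else "40-60")
  }
})

test_that("time-constant estimators match closed forms", {
  st <- stimulus(step_pA = -1000, onset_ms = 50, dur_ms = 0.5,
                 total_ms = 300)
  t <- seq(0, 300, by = 0.025)
  # pure single exponential, tau 20 ms
  d <- ifelse(t > 50.5, 5 * exp(-(t - 50.5) / 20), 0)
  tr <- make_trace(t, -75 - d, st)
  expect_equal(estimate_tau(tr, "decay33"), 20 * log(1 / 0.33),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(estimate_tau(tr, "decay33"), 22.2, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(estimate_tau(tr, "double_exp"), 20, tolerance = 0.02,
               ignore_attr = TRUE)
  # two-exponential mixture: slowest recovered within 2%
  d2 <- ifelse(t > 50.5,
               5 * (0.7 * exp(-(t - 50.5) / 20) + 0.3 * exp(-(t - 50.5) / 2)),
               0)
  tr2 <- make_trace(t, -75 - d2, st)
  expect_equal(estimate_tau(tr2, "double_exp"), 20, tolerance = 0.02,
               ignore_attr = TRUE)
  # flat trace: failure
  expect_error(estimate_tau(make_trace(t, rep(-75, length(t)), st)),
               "failed|deflection")
})

test_that("input resistance and capacitance are simple ratios", {
  st <- stimulus(step_pA = -10, onset_ms = 100, dur_ms = 100, total_ms = 250)
  t <- seq(0, 250, by = 0.05)
  v <- rep(-75, length(t))
  v[t > 100 & t <= 200] <- -77  # -2 mV deflection
  expect_equal(input_resistance(make_trace(t, v, st)), 200)
  v2 <- replace(rep(-75, length(t)), t > 100 & t <= 200, -77.182)
  expect_equal(input_resistance(make_trace(t, v2, st)), 218.2)
  expect_error(input_resistance(make_trace(t, v, stimulus(step_pA = 0,
                                                          onset_ms = 100,
                                                          dur_ms = 100,
                                                          total_ms = 250))),
               "zero")
  expect_equal(capacitance(19.1, 218.2), 87.5, tolerance = 0.05)
  expect_equal(capacitance(20, 200), 100)
  expect_warning(c0 <- capacitance(0, 200), "degenerate")
  expect_equal(c0, 0)
})
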