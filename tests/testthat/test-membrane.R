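test_that("M-current activation follows the offset sigmoid", {
  # midpoint: offset + half
  expect_equal(km_steady_state(-36.7), 0.525, tolerance = 1e-12)
  # hyperpolarized limit equals the additive constant
  expect_equal(km_steady_state(-200), 0.025, tolerance = 1e-5)
  # one slope-width above midpoint (independent hand evaluation)
  expect_equal(km_steady_state(-36.7 + 9.48), 0.025 + 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(km_steady_state(-36.7 + 9.48), 0.756, tolerance = 1e-3)
  # saturates above 1 by design (not clamped)
  expect_equal(km_steady_state(40), 1.025, tolerance = 1e-3)
})

half_activation_v <- function(gate, lo = -150, hi = 20) {
  lim <- range(gate_inf(gate, c(lo, hi)))
  mid <- mean(lim)
  uniroot(function(v) gate_inf(gate, v) - mid, c(lo, hi))$root
}

test_that("NaP derivation shifts both curves hyperpolarizingly", {
  cat <- kinetics_catalogue()
  naf <- cat$NaF
  nap0 <- derive_nap_from_naf(naf, shift = 0)
  v <- seq(-100, 20, by = 7)
  expect_equal(gate_inf(nap0$gates$m, v), gate_inf(naf$gates$m, v))
  expect_equal(gate_inf(nap0$gates$h, v), gate_inf(naf$gates$h, v))
  nap <- derive_nap_from_naf(naf, shift = 14)
  # half-activation moved 14 mV negative (located numerically on both
  # curves; the absolute shift is compared, with a small allowance for the
  # asymmetric truncation of the curves at the search-window edges)
  expect_lt(abs((half_activation_v(nap$gates$m) -
                   half_activation_v(naf$gates$m)) - (-14)), 0.05)
  expect_lt(abs((half_activation_v(nap$gates$h) -
                   half_activation_v(naf$gates$h)) - (-14)), 0.05)
  # +14 then -14 is the identity to machine precision
  round_trip <- derive_nap_from_naf(derive_nap_from_naf(naf, 14), -14)
  expect_equal(gate_inf(round_trip$gates$m, v), gate_inf(naf$gates$m, v),
               tolerance = 1e-12)
})

test_that("IH shift translates only the inactivation gate by exactly dv", {
  cat <- kinetics_catalogue(ih_shift = 0)
  ih <- cat$IH
  ident <- shift_ih_inactivation(ih, 0)
  expect_equal(gate_inf(ident$gates$h, -95), gate_inf(ih$gates$h, -95))
  shifted <- shift_ih_inactivation(ih, -11)
  expect_lt(abs((half_activation_v(shifted$gates$h, lo = -200) -
                   half_activation_v(ih$gates$h, lo = -200)) - (-11)), 0.05)
  # activation untouched
  expect_equal(gate_inf(shifted$gates$m, seq(-110, -50, by = 5)),
               gate_inf(ih$gates$m, seq(-110, -50, by = 5)))
  # availability at the deepest step voltages is restored by the shift
  expect_gt(gate_inf(shifted$gates$h, -100), gate_inf(ih$gates$h, -100))
})

test_that("channel currents follow the conductance formalism", {
  cat <- kinetics_catalogue()
  # zero density gives zero current for any channel and state
  for (ch in names(cat))
    expect_equal(channel_current(cat[[ch]], 0, -50, ca_uM = 5), 0)
  # ANO2 reversal: zero current at -86 mV regardless of calcium
  expect_equal(channel_current(cat$ANO2, 0.00275, -86, ca_uM = 100), 0)
  expect_gt(channel_current(cat$ANO2, 0.00275, -50, ca_uM = 100), 0)
  # KM at -50 mV with E_K = -100: hand evaluation of the gate product
  g <- cat$KM$gates$m
  expected <- 0.00033 * gate_inf(g, -50)^g$power *
    (-50 - cat$KM$conduction$erev)
  expect_equal(channel_current(cat$KM, 0.00033, -50), expected,
               tolerance = 1e-12)
  expect_error(channel_current(cat$KM, -1, -50), "non-negative")
  # GHK calcium current is inward at negative voltages
  expect_lt(channel_current(cat$CaT, 1e-4, -60,
                            gate_states = list(m = 0.5, h = 0.5)), 0)
})

test_that("steady-state curves are monotone over the physiological range", {
  cat <- kinetics_catalogue()
  v <- seq(-120, 40, by = 0.5)
  # note IH's availability ("h") rises with voltage: HCN inactivates only
  # at extreme hyperpolarization
  increasing <- c("NaF.m", "NaP.m", "KDR.n", "KA.m", "KM.m", "CaL.m",
                  "CaT.m", "IH.h")
  decreasing <- c("NaF.h", "NaP.h", "KA.h", "CaT.h", "IH.m")
  for (key in c(increasing, decreasing)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    curve <- gate_inf(cat[[parts[1]]]$gates[[parts[2]]], v)
    d <- diff(curve)
    if (key %in% increasing) expect_true(all(d >= -1e-12), info = key)
    else expect_true(all(d <= 1e-12), info = key)
    tau <- gate_tau(cat[[parts[1]]]$gates[[parts[2]]], v)
    expect_true(all(tau > 0), info = key)
  }
})

test_that("calcium pools decay exponentially and superpose", {
  p <- calcium_pools()
  expect_equal(p$pools$fraction[p$pools$source == "cal"], c(0.258, 0.742))
  expect_equal(sum(p$pools$fraction[p$pools$source == "cal"]), 1)
  expect_equal(p$pools$tau_ms, c(14, 50, 50))
  # fixed point: zero influx at rest leaves pools unchanged
  p2 <- update_calcium(p, 0, 0, dt = 1)
  expect_equal(p2$pools$conc_uM, p$pools$conc_uM)
  # displaced pool relaxes with its stated tau (14 ms pool halves in 14 ln 2)
  pd <- calcium_pools(conc_uM = c(sk = 1.05, ano = 0.05, t = 0.05))
  t_half <- 14 * log(2)
  ph <- update_calcium(pd, 0, 0, dt = t_half)
  expect_equal(ph$pools$conc_uM[1], 0.05 + 0.5 * 1.0, tolerance = 1e-9)
  # constant influx reaches rest + f * drive * tau; compare the iterated
  # update against the closed form
  i_cal <- -0.01  # mA/cm^2 inward
  pc <- calcium_pools()
  for (k in 1:4000) pc <- update_calcium(pc, i_cal, 0, dt = 0.25)
  k_influx <- 1e4 / (2 * 96485.332 * pc$depth_um) * 1e3  # uM
  expect_equal(pc$pools$conc_uM[1], 0.05 + 0.258 * (-i_cal) * k_influx * 14,
               tolerance = 1e-6)
  expect_equal(pc$pools$conc_uM[2], 0.05 + 0.742 * (-i_cal) * k_influx * 50,
               tolerance = 1e-6)
  # T-pool fed only by the T current
  expect_equal(pc$pools$conc_uM[3], 0.05)
  # superposition of the linear dynamics
  pa <- update_calcium(calcium_pools(), -0.01, 0, dt = 5)
  pb <- update_calcium(calcium_pools(), -0.02, 0, dt = 5)
  pab <- update_calcium(calcium_pools(), -0.03, 0, dt = 5)
  expect_equal(pab$pools$conc_uM - 0.05,
               (pa$pools$conc_uM - 0.05) + (pb$pools$conc_uM - 0.05),
               tolerance = 1e-9)
})

test_that("the density table matches the published distribution", {
  tb <- distribution_table()
  expect_equal(tb$ais[tb$channel == "KM"], 0.0165)
  expect_equal(tb$soma[tb$channel == "KM"], 0.00033)
  expect_equal(tb$dend_class_3[tb$channel == "KM"], 0.00033)
  expect_equal(tb$soma[tb$channel == "NaF"], 0.152)
  expect_equal(tb$ais[tb$channel == "NaF"], 0.008)
  expect_equal(tb$soma[tb$channel == "KDR"], 1.52)
  expect_equal(tb$ais[tb$channel == "CaT"], 0)
  expect_equal(tb$soma[tb$channel == "CaT"], 0)
  expect_true(all(tb[tb$channel == "CaT",
                     c("dend_class_1", "dend_class_2", "dend_class_3")] > 0))
  expect_equal(unlist(tb[tb$channel == "IH", -1], use.names = FALSE),
               c(0, 0, 3.5e-5, 3.5e-5, 3.5e-5))
  # overrides and validation
  tb2 <- distribution_table(overrides = list(KM = c(soma = 0)))
  expect_equal(tb2$soma[tb2$channel == "KM"], 0)
  expect_error(distribution_table(overrides = list(XX = c(soma = 1))),
               "unknown channel")
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  distribution_table_json(tb, f)
  expect_equal(distribution_table_from_json(f), tb)
})
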