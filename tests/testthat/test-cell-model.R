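test_that("effective conductance and ionic current follow the HH forms", {
  expect_identical(effective_conductance(0.05, 1.0), 0.05)
  expect_identical(effective_conductance(1.0, 0.0), 0.0)
  expect_equal(effective_conductance(0.02, 2.5), 0.05)
  expect_error(effective_conductance(-0.1, 1), "Gmax")
  expect_error(effective_conductance(0.1, -1), "factor")

  expect_identical(ionic_current(0.01, -77, -77), 0)
  expect_identical(ionic_current(0, -50, -77), 0)
  expect_equal(ionic_current(0.01, -50, -77), 0.27)
  expect_gt(ionic_current(0.01, -40, -77), 0)  # outward above reversal
  expect_error(ionic_current(-1, 0, 0), "conductance")
})

test_that("default channel set carries 18 state equations per compartment", {
  expect_identical(n_state_equations(), 18L)
})

test_that("passive cell relaxes to the leak reversal everywhere", {
  gm <- default_gmax_profiles()
  gm$g0 <- 0
  cell <- build_cell(small_morph(), gmax = gm)
  tr <- hh_integrate(cell, duration = 4000, dt = 0.1, v_init = -60)
  expect_true(all(abs(tr$v_final - cell$e_pas) < 0.05))
})

test_that("single-compartment reduction matches the analytic RC response", {
  soma <- morphology(data.frame(id = 1L, parent = NA_integer_,
                                section = "soma", length = 20, diam = 15))
  gm <- default_gmax_profiles(); gm$g0 <- 0
  cell <- build_cell(soma, gmax = gm)
  A <- pi * 20 * 15 * 1e-8                       # cm2
  gpas <- leak_conductance(0)                    # S/cm2
  tau_ms <- 5e-6 / gpas * 1000                   # Cm/g
  amp_nA <- 0.01
  for (t_end in c(100, 400)) {
    tr <- hh_integrate(cell, list(steps = data.frame(
      compartment = 1, t0 = 0, t1 = 1e6, amp_nA = amp_nA)),
      duration = t_end, dt = 0.025, v_init = -70, record = "soma")
    dv_theory <- amp_nA * 1e-9 / (gpas * A) * (1 - exp(-t_end / tau_ms)) * 1e3
    dv_sim <- tail(tr$v[, "soma"], 1) + 70
    expect_lt(abs(dv_sim - dv_theory) / dv_theory, 0.01)
  }
})

test_that("charge bookkeeping: passive decay conserves injected charge", {
  # brief pulse on an isolated soma: peak deflection = Q/C, then leak decay
  soma <- morphology(data.frame(id = 1L, parent = NA_integer_,
                                section = "soma", length = 20, diam = 15))
  gm <- default_gmax_profiles(); gm$g0 <- 0
  cell <- build_cell(soma, gmax = gm)
  tr <- hh_integrate(cell, list(steps = data.frame(
    compartment = 1, t0 = 10, t1 = 11, amp_nA = 0.5)),
    duration = 60, dt = 0.005, v_init = -70, record = "soma",
    record_dt = 0.005)
  C_nF <- 5 * pi * 20 * 15 * 1e-8 * 1e3
  dv_peak_theory <- 0.5 * 1 / C_nF   # Q = 0.5 nA x 1 ms; tau >> pulse
  expect_lt(abs(max(tr$v[, 1]) + 70 - dv_peak_theory) / dv_peak_theory, 0.01)
})

test_that("the cell spikes at 1.5x rheobase and f-I is monotone", {
  cell <- build_cell(tiny_morph())
  rb <- find_rheobase(cell, max_nA = 1.5, resolution = 0.05)
  expect_false(is.na(rb))
  counts <- vapply(c(1, 1.5, 2.5) * rb, function(amp) {
    tr <- hh_integrate(cell, list(steps = data.frame(
      compartment = 1, t0 = 50, t1 = 550, amp_nA = amp)),
      duration = 650, dt = 0.025, record = "soma")
    length(detect_spikes(tr$v[, "soma"], tr$fs))
  }, numeric(1))
  expect_gte(counts[2], 1)
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[1], 1)   # rheobase is defined by the first spike
})

test_that("integration converges under dt refinement", {
  cell <- small_cell()
  tr1 <- hh_integrate(cell, duration = 300, dt = 0.05, record = "soma")
  tr2 <- hh_integrate(cell, duration = 300, dt = 0.025, record = "soma")
  expect_lt(abs(tail(tr1$v[, 1], 1) - tail(tr2$v[, 1], 1)), 0.1)
})

test_that("integration is deterministic and aborts on divergence", {
  cell <- build_cell(tiny_morph())
  tr1 <- hh_integrate(cell, duration = 200, dt = 0.05)
  tr2 <- hh_integrate(cell, duration = 200, dt = 0.05)
  expect_identical(tr1$v, tr2$v)

  gm <- default_gmax_profiles(); gm$g0 <- 0
  passive <- build_cell(tiny_morph(), gmax = gm)
  expect_error(hh_integrate(passive, list(steps = data.frame(
    compartment = 1, t0 = 10, t1 = 1e6, amp_nA = 50)),
    duration = 4000, dt = 0.05),
    "divergence.*compartment")
})

test_that("spike detection isolates action-potential events", {
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)
  # subthreshold theta-frequency oscillation: no events
  v_sine <- -60 + 10 * sin(2 * pi * 8 * t)
  expect_length(detect_spikes(v_sine, fs), 0)

  # insert action-potential templates at known times
  template <- 100 * exp(-((seq_len(21) - 11) / 3)^2)  # ~1 ms half-width
  v <- rep(-65, length(t))
  at <- c(2001, 5001, 8001)
  for (a in at) v[a + seq_along(template) - 11] <-
      v[a + seq_along(template) - 11] + template
  sp <- detect_spikes(v, fs)
  expect_length(sp, 3)
  expect_true(all(abs(sp - (at - 1) / fs * 1000) <= 1000 / fs))

  # two templates 1 ms apart merge under the 2 ms refractory rule
  v2 <- rep(-65, length(t))
  for (a in c(5001, 5011)) v2[a + seq_along(template) - 11] <-
      pmax(v2[a + seq_along(template) - 11],
           -65 + template)
  expect_length(detect_spikes(v2, fs), 1)

  expect_error(detect_spikes(v[1:100], fs), "warm-up")
  expect_error(detect_spikes(v, 500), "fs must exceed")
})
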