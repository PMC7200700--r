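test_that("sublayer profiles encode the PV/CCK bouton fractions", {
  deep <- sublayer_profile("deep")
  expect_identical(deep[["CCK"]], 0.30)
  expect_identical(deep[["PV"]], 1.00)
  sup <- sublayer_profile("superficial")
  expect_identical(sup[["CCK"]], 1.00)
  expect_identical(sup[["PV"]], 0.30)
  expect_length(sublayer_profile("none"), 0)
  expect_error(sublayer_profile("middle"), "arg")
})

test_that("rate inclusion implements the 3-of-4 realistic-rate rule", {
  expect_true(include_by_rate(c(5, 5, 5, 9)))
  expect_false(include_by_rate(c(0, 0, 0, 0)))
  expect_false(include_by_rate(c(9, 9, 0.005, 5)))
  expect_true(include_by_rate(c(0.01, 8, 3, 100)))   # bounds inclusive
  expect_false(include_by_rate(c(1, 2)))             # too few in range
  expect_error(include_by_rate(c(-1, 2, 3)), "rates")
  expect_error(include_by_rate(numeric(0)), "at least one")
})

test_that("silent pathways yield silent cells and runs are deterministic", {
  m <- generate_morphology(3, 4, depth = 1, seed = 5)
  pw <- default_pathways()
  pw$rate <- 0
  cell <- synthetic_cell(m, pathways = pw)
  r <- run_theta(cell, experiment_config(n_cycles = 5, seed = 2))
  expect_identical(nrow(r$phases), 0L)
  expect_identical(r$rate, 0)

  cell2 <- synthetic_cell(m)
  cfg <- experiment_config(n_cycles = 10, seed = 6)
  r1 <- run_theta(cell2, cfg)
  r2 <- run_theta(cell2, cfg)
  expect_identical(r1$phases, r2$phases)
  expect_identical(r1$trace$v, r2$trace$v)
})

test_that("an identity glutamatergic scan reproduces the baseline", {
  m <- generate_morphology(3, 4, depth = 1, seed = 7)
  cell <- synthetic_cell(m)
  cfg <- experiment_config(n_cycles = 10, seed = 9)
  base <- run_theta(cell, cfg)
  scan <- glutamatergic_scan(cell, "ECIII", levels = c(0, 1), cfg = cfg)
  expect_identical(scan[["1"]]$phases, base$phases)
  # level 0 equals the fully removed condition
  cfg0 <- cfg
  cfg0$manipulation <- c(ECIII = 0)
  cfg0$manipulation_mode <- "rate"
  removed <- run_theta(cell, cfg0)
  expect_identical(scan[["0"]]$phases, removed$phases)
  expect_error(glutamatergic_scan(cell, "ECIII", levels = -1), "levels")
})

test_that("a pure CA3 drive locks firing inside the CA3 input window", {
  m <- generate_morphology(3, 5, seed = 11)
  pw <- default_pathways()
  pw$rate[pw$name != "CA3"] <- 0
  pw$gmax_uS[pw$name == "CA3"] <- pw$gmax_uS[pw$name == "CA3"] * 2
  cell <- synthetic_cell(m, pathways = pw)
  r <- run_theta(cell, experiment_config(n_cycles = 40, seed = 13))
  expect_gte(nrow(r$phases), 4)
  # CA3 window: phases where the event density exceeds its cycle mean
  ev_ph <- (r$schedule$events$time %% 125) / 125 * 360
  h <- phase_histogram(ev_ph, n_bins = 24)
  centers <- (seq_len(24) - 0.5) * 15
  window <- centers[h > mean(h)]
  mu <- mean_vector(r$phases$phase)$mu
  gap <- abs(((mu - window + 180) %% 360) - 180)
  expect_lt(min(gap), 15)
})

test_that("synthetic cells and configs validate their inputs", {
  m <- generate_morphology(3, 4, depth = 1, seed = 3)
  expect_error(synthetic_cell(m, synaptic = c(nope = 0.5)),
               "pathway names")
  cell <- synthetic_cell(m, synaptic = c(CA3 = 0.5))
  expect_equal(cell$pathways["CA3", "gmax_uS"],
               default_pathways()["CA3", "gmax_uS"] * 0.5)
  expect_error(experiment_config(n_cycles = 0), "n_cycles")
})

test_that("spike phases dissociate from dendritic peak phases", {
  m <- generate_morphology(3, 5, seed = 17)
  cell <- synthetic_cell(m)
  cell$pathways["CA3", "rate"] <- cell$pathways["CA3", "rate"] * 2  # high CA3
  r <- run_theta(cell, experiment_config(n_cycles = 60, seed = 19))
  expect_gte(nrow(r$phases), 8)
  dend <- dendritic_peak_phases(r, "proximal")
  expect_length(dend, 60)
  expect_true(all(dend >= 0 & dend < 360))
  # spikes only in cycles where the cell fired
  sp_cycles <- unique(r$phases$cycle)
  cc <- circ_corr(r$phases$phase,
                  dend[pmin(sp_cycles, length(dend))][
                    match(r$phases$cycle, sp_cycles)])
  expect_lt(abs(cc), 1)
  # the two phase distributions are not identical
  mv_sp <- mean_vector(r$phases$phase)
  mv_de <- mean_vector(dend)
  expect_gt(abs(((mv_sp$mu - mv_de$mu + 180) %% 360) - 180) +
              abs(mv_sp$R - mv_de$R), 0.05)
})

test_that("somatic depolarization in the CA3 window grows with CA3 drive", {
  m <- generate_morphology(3, 4, depth = 1, seed = 23)
  cell <- synthetic_cell(m)
  cfg <- experiment_config(n_cycles = 25, seed = 29)
  scan <- glutamatergic_scan(cell, "CA3", levels = c(0.5, 1, 2), cfg = cfg)
  # CA3 window: phases where its event density exceeds the cycle mean
  mu <- default_pathways()["CA3", "phase_mu"]
  window_mean <- vapply(scan, function(r) {
    ph <- (r$trace$t %% 125) / 125 * 360
    in_win <- abs(((ph - mu + 180) %% 360) - 180) < 60
    mean(r$trace$v[in_win, "soma"])
  }, numeric(1))
  expect_true(all(diff(window_mean) > 0))
})
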