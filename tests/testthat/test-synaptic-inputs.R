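test_that("double-exponential conductance is normalized to its peak", {
  tau1 <- 0.5; tau2 <- 3; gmax <- 2e-3
  expect_identical(syn_conductance(0, tau1, tau2, gmax), 0)
  tp <- syn_peak_time(tau1, tau2)
  expect_equal(tp, tau1 * tau2 / (tau1 - tau2) * log(tau1 / tau2))
  expect_equal(syn_conductance(tp, tau1, tau2, gmax), gmax)
  # peak is a maximum and the tail decays to zero
  expect_gt(syn_conductance(tp, tau1, tau2, gmax),
            syn_conductance(tp * 0.5, tau1, tau2, gmax))
  expect_gt(syn_conductance(tp, tau1, tau2, gmax),
            syn_conductance(tp * 2, tau1, tau2, gmax))
  expect_lt(syn_conductance(100, tau1, tau2, gmax), 1e-9)
  expect_error(syn_conductance(1, 2, 2, 1), "degenerate")
  expect_error(syn_conductance(-1, 0.5, 3), "t_since_event")
})

test_that("event phases follow the specified Beta law on the cycle", {
  pw <- default_pathways()["CA3", ]
  pw$rate <- 8; pw$phase_mu <- 120; pw$beta1 <- 2; pw$beta2 <- 2
  times <- sample_event_phases(pw, n_cycles = 10000, theta_freq = 8, seed = 5)
  # Poisson count statistics: ~1 event per cycle
  expect_lt(abs(length(times) - 10000), 3 * sqrt(10000))
  ph <- (times / 125 * 360) %% 360
  mv <- mean_vector(ph)
  expect_lt(abs(((mv$mu - 120 + 180) %% 360) - 180), 3)

  # Kolmogorov-Smirnov against the Beta density on the unwrapped support
  x <- (((ph - 120 + 180) %% 360)) / 360
  ks <- suppressWarnings(stats::ks.test(x, stats::pbeta, 2, 2))
  expect_gt(ks$p.value, 0.01)

  # degenerate dispersion: all phases collapse on phase_mu
  pw2 <- pw; pw2$beta1 <- 5e4; pw2$beta2 <- 5e4
  t2 <- sample_event_phases(pw2, n_cycles = 2000, theta_freq = 8, seed = 5)
  ph2 <- (t2 / 125 * 360) %% 360
  expect_lt(max(abs(((ph2 - 120 + 180) %% 360) - 180)), 5)

  pw3 <- pw; pw3$beta1 <- -1
  expect_error(sample_event_phases(pw3, 10), "beta")
})

test_that("bouton placement respects target bands and determinism", {
  m <- small_morph()
  pv <- default_pathways()["PV", ]
  b <- place_boutons(m, pv, seed = 3)
  expect_length(b, pv$n_boutons)
  cp <- m$compartments
  sz <- ifelse(cp$section == "basal", -cp$z, cp$z)[match(b, cp$id)]
  expect_true(all(sz >= -50 & sz <= 150))

  expect_identical(place_boutons(m, pv, seed = 3), b)

  pv0 <- pv; pv0$n_boutons <- 0L
  expect_length(place_boutons(m, pv0, seed = 3), 0)

  far <- pv; far$z_lo <- 5000; far$z_hi <- 6000
  expect_error(place_boutons(m, far, seed = 1), "PV.*target band")
})

test_that("manipulation operators rescale boutons or rates as specified", {
  p <- default_pathways()
  deep <- apply_manipulation(p, c(CCK = 0.30, PV = 1.00), mode = "boutons")
  expect_equal(deep["CCK", "n_boutons"],
               floor(p["CCK", "n_boutons"] * 0.3 + 0.5))
  expect_equal(deep["PV", "n_boutons"], p["PV", "n_boutons"])
  expect_identical(deep["CA3", ], p["CA3", ])

  ident <- apply_manipulation(p, structure(rep(1, nrow(p)), names = p$name),
                              mode = "boutons")
  expect_identical(ident, p)

  r <- apply_manipulation(p, c(CA3 = 0.5), mode = "rate")
  expect_equal(r["CA3", "rate"], p["CA3", "rate"] * 0.5)

  expect_error(apply_manipulation(p, c(XYZ = 0.5)), "unknown pathway")
  expect_error(apply_manipulation(p, c(PV = 1.5)), "fractions")

  # full removal: the pathway contributes no events to the schedule
  none <- apply_manipulation(p, c(PV = 0), mode = "boutons")
  sched <- build_theta_schedule(small_morph(), none, n_cycles = 20, seed = 2)
  expect_false("PV" %in% sched$events$pathway)
})

test_that("bouton-mode and rate-mode scaling deliver equivalent input", {
  # halving boutons vs halving rate: same expected synaptic charge per cycle
  m <- small_morph()
  p <- default_pathways()["CA3", , drop = FALSE]
  p$n_boutons <- 400L; p$rate <- 5
  pb <- apply_manipulation(p, c(CA3 = 0.5), mode = "boutons")
  pr <- apply_manipulation(p, c(CA3 = 0.5), mode = "rate")
  n_cycles <- 400
  charge <- function(pw, seed) {
    s <- build_theta_schedule(m, pw, n_cycles = n_cycles, seed = seed)
    # event count x conductance-time integral (identical kinetics)
    nrow(s$events) * pw$gmax_uS[1]
  }
  cb <- mean(vapply(1:5, function(s) charge(pb, s), numeric(1)))
  cr <- mean(vapply(1:5, function(s) charge(pr, s), numeric(1)))
  expect_lt(abs(cb - cr) / cr, 0.05)
})

test_that("theta schedules are deterministic and well-formed", {
  m <- small_morph()
  s1 <- build_theta_schedule(m, n_cycles = 30, seed = 9)
  s2 <- build_theta_schedule(m, n_cycles = 30, seed = 9)
  expect_identical(s1$events, s2$events)
  expect_true(all(s1$events$time >= 0 & s1$events$time <= s1$duration))
  expect_true(all(s1$events$compartment %in% m$compartments$id))
  expect_true(all(diff(s1$events$time) >= 0))
  glut <- s1$events$pathway %in% c("CA3", "CA2", "ECIII", "ECII")
  expect_true(all(s1$events$erev[glut] == 0))
  expect_true(all(s1$events$erev[!glut] < -60))
})
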