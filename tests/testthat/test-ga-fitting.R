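# box scorer: error = number of factors outside [0.9, 1.1]
box_scorer <- function(lo = 0.9, hi = 1.1) {
  function(x) sum(x < lo | x > hi)
}

test_that("feature scoring counts out-of-interval features, boundary inside", {
  targets <- data.frame(feature = c("a", "b", "c"),
                        lo = c(0, 10, -5), hi = c(1, 20, 5))
  expect_identical(score_features(c(a = 0.5, b = 15, c = 0), targets), 0L)
  expect_identical(score_features(c(a = 1.5, b = 15, c = 0), targets), 1L)
  expect_identical(score_features(c(a = 1.5, b = 25, c = 9), targets), 3L)
  # boundaries count as inside
  expect_identical(score_features(c(a = 1, b = 10, c = 5), targets), 0L)
  expect_error(score_features(c(a = 1), targets), "missing feature")
  expect_error(score_features(c(a = 1, b = 1, c = 1),
                              data.frame(feature = "a", lo = 2, hi = 1)),
               "empty acceptance interval")
})

test_that("evolution bookkeeping: mutation rate and survival dynamics", {
  bounds <- default_factor_bounds()[1:4, ]
  res <- evolve(box_scorer(), bounds, pop_size = 50, generations = 1000,
                seed = 3)
  # realized per-generation mutated fraction tracks the 40% rule
  expect_lt(abs(mean(res$mutated_fraction, na.rm = TRUE) - 0.40), 0.03)
  expect_identical(res$generations_run, 1000L)

  # all-valid population with mutation disabled and certain survival is a
  # fixed point: the best error stays 0 and no new individuals appear
  res2 <- evolve(function(x) 0L, bounds, pop_size = 20, generations = 10,
                 p_success = 1, mutate_frac = 0, seed = 5)
  expect_true(all(res2$best_error == 0))
  expect_identical(nrow(res2$valid), 20L)

  expect_error(evolve(box_scorer(), bounds, pop_size = 5), "population")
  expect_error(evolve(box_scorer(), bounds, generations = 0), "generations")
})

test_that("elitism makes the best error non-increasing", {
  bounds <- data.frame(lo = rep(0, 6), hi = rep(1, 6),
                       row.names = paste0("f", 1:6))
  # graded integer error with a narrow optimum: progress is slow enough
  # that regressions would be visible without elitism
  scorer <- function(x) sum(x < 0.45 | x > 0.55)
  res <- evolve(scorer, bounds, pop_size = 30, generations = 60,
                elitism = TRUE, seed = 7)
  expect_true(all(diff(res$best_error) <= 0))
})

test_that("per-value survival variant runs and respects bounds", {
  bounds <- default_factor_bounds()[1:3, ]
  res <- evolve(box_scorer(), bounds, pop_size = 20, generations = 30,
                per_value = TRUE, seed = 9)
  if (nrow(res$valid))
    expect_true(all(res$valid >= 0.5 & res$valid <= 2))
  expect_identical(res$generations_run, 30L)
})

test_that("planted targets are recovered on a reduced cell", {
  m <- tiny_morph()
  ref <- structure(rep(1, length(ca1theta:::GA_PARAMS)),
                   names = ca1theta:::GA_PARAMS)
  feats <- measure_cell_features(build_cell(m, factors = ref),
                                 settle_ms = 400, step_ms = 300)
  targets <- fitness_targets(feats)
  expect_identical(score_features(feats, targets), 0L)
  scorer <- make_intrinsic_scorer(m, targets, settle_ms = 400,
                                  step_ms = 300)
  res <- evolve(scorer, default_factor_bounds(), pop_size = 24,
                generations = 100, stop_at_valid = 1, seed = 11)
  expect_gte(nrow(res$valid), 1)
  # the recovered individual indeed scores error 0
  expect_identical(scorer(res$valid[1, ]), 0L)
})

test_that("cross-morphology validation replaces failing individuals", {
  # toy pool: 5 individuals, exactly 2 valid on every morphology
  pool <- rbind(a = c(x = 1.0), b = c(x = 5.0), c = c(x = 1.05),
                d = c(x = 9.0), e = c(x = 7.0))
  scorers <- list(function(f) sum(f < 0.9 | f > 1.1),
                  function(f) sum(f < 0.95 | f > 1.2))
  got <- cross_morphology_validate(pool, scorers, n_pick = 2, seed = 3)
  expect_identical(nrow(got), 2L)
  expect_true(all(got[, "x"] %in% c(1.0, 1.05)))

  expect_error(cross_morphology_validate(pool, scorers, n_pick = 3,
                                         seed = 3),
               "pool exhausted: validated 2 of 3")
  expect_error(cross_morphology_validate(pool[0, , drop = FALSE], scorers),
               "empty pool")
})

test_that("synaptic PSP scorer recovers a planted CA3 parameterization", {
  m <- small_morph()
  ref <- c(CA3 = 1, PV = 1, CCK = 1)
  cell <- build_cell(m)
  feats <- measure_psp(cell, m, synaptic = as.list(ref))
  expect_gt(feats[["psp_amp"]], 0)
  expect_gt(feats[["psp_halfwidth"]], 0)
  targets <- fitness_targets(feats, tol = c(psp_amp = NA,
                                            psp_halfwidth = NA))
  scorer <- make_synaptic_scorer(m, targets)
  expect_identical(scorer(ref), 0L)
  # strongly scaled conductances leave the acceptance window
  expect_gt(scorer(c(CA3 = 3, PV = 1, CCK = 1)), 0)
})
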