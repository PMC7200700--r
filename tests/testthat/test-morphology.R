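test_that("spine correction reproduces the full decision table", {
  # soma and basal rules
  expect_identical(spine_correction("soma", 0, 15), 1.0)
  expect_identical(spine_correction("basal", 80, 0.9), 2.51)
  # apical near (<= 350 um): thick / intermediate / thin
  expect_identical(spine_correction("apical_trunk", 100, 2.0), 1.69)
  expect_identical(spine_correction("apical_branch", 100, 1.0), 1.60)
  expect_identical(spine_correction("apical_branch", 100, 0.3), 1.86)
  # apical far (> 350 um): thick / thin
  expect_identical(spine_correction("apical_branch", 400, 0.5), 2.10)
  expect_identical(spine_correction("apical_branch", 400, 0.2), 1.71)
  # interval boundaries: closed on the lower bound; z = 350 is "near"
  expect_identical(spine_correction("apical_branch", 100, 1.6), 1.69)
  expect_identical(spine_correction("apical_branch", 100, 0.55), 1.60)
  expect_identical(spine_correction("apical_branch", 400, 0.35), 2.10)
  expect_identical(spine_correction("apical_branch", 350, 2.0), 1.69)
  expect_identical(spine_correction("apical_branch", 350.01, 2.0), 2.10)
  # rejections
  expect_error(spine_correction("axon", 10, 1), "unknown section")
  expect_error(spine_correction("basal", -5, 1), "z must be")
  expect_error(spine_correction("basal", 10, 0), "thickness")
})

test_that("leak conductance matches its closed form and asymptotes", {
  # sigmoid midpoint: denominator is 80 + (0.4 - 80)/2
  expect_equal(leak_conductance(225), 0.001 / (80 + (0.4 - 80) / 2),
               tolerance = 1e-9)
  # somatic value: the exp((225-0)/30) term evaluated numerically
  expect_equal(leak_conductance(0),
               0.001 / (80 + (0.4 - 80) / (1 + exp(225 / 30))),
               tolerance = 1e-9)
  expect_equal(leak_conductance(0), 1.2507e-5, tolerance = 1e-4)
  # asymptotes bound the profile
  expect_equal(leak_conductance(1e9), 0.001 / 0.4, tolerance = 1e-9)
  z <- seq(0, 600, by = 5)
  g <- leak_conductance(z)
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0.001 / 80 & g < 0.001 / 0.4))
  # spine factor multiplies the somatic profile
  expect_equal(leak_conductance(100, SS = 2.51),
               2.51 * leak_conductance(100))
  expect_error(leak_conductance(-1), "z must be")
})

test_that("generated morphologies meet branch counts exactly over many seeds", {
  for (seed in 1:100) {
    nb <- 2 + seed %% 5
    na <- 3 + seed %% 6
    m <- generate_morphology(n_basal = nb, n_apical = na, depth = 1,
                             mean_seg_length = 40, seed = seed)
    expect_equal(m$n_basal_branches, nb)
    expect_equal(m$n_apical_branches, na)
    expect_equal(m$n_total_branches, nb + na)
  }
})

test_that("morphology generation is seed-deterministic and size-targeted", {
  m1 <- generate_morphology(5, 8, seed = 7)
  m2 <- generate_morphology(5, 8, seed = 7)
  expect_identical(m1$compartments, m2$compartments)
  m3 <- generate_morphology(5, 8, seed = 8)
  expect_false(identical(m1$compartments$length, m3$compartments$length))

  # branching arithmetic: soma + trunk + (2k-1) branch chains per tree
  nb <- 4; na <- 6; depth <- 2
  m <- generate_morphology(nb, na, depth = depth, mean_seg_length = 30,
                           trunk_length = 150, seed = 3)
  trunk_segs <- max(2, ceiling(150 / 30))
  target <- 1 + trunk_segs + (2 * nb - 1 + 2 * na - 1) * depth
  expect_lt(abs(nrow(m$compartments) - target) / target, 0.2)

  expect_error(generate_morphology(5, 8, depth = 0), "depth")
  expect_error(generate_morphology(0, 8), "counts")
})

test_that("morphology invariants hold and violations are rejected", {
  m <- small_morph()
  cp <- m$compartments
  expect_identical(sum(is.na(cp$parent)), 1L)
  expect_identical(cp$z[is.na(cp$parent)], 0)
  pidx <- match(cp$parent, cp$id)
  nonroot <- !is.na(pidx)
  expect_true(all(cp$z[nonroot] > cp$z[pidx[nonroot]]))
  expect_true(all(cp$length > 0 & cp$diam > 0))

  expect_error(morphology(data.frame(
    id = 1:2, parent = c(NA, 5), section = c("soma", "basal"),
    length = c(20, 30), diam = c(15, 1))), "parent ids missing")
  expect_error(morphology(data.frame(
    id = 1:2, parent = c(NA, NA), section = c("soma", "basal"),
    length = c(20, 30), diam = c(15, 1))), "exactly one root")
  expect_error(morphology(data.frame(
    id = 1:2, parent = c(NA, 1), section = c("soma", "basal"),
    length = c(20, 0), diam = c(15, 1))), "lengths and diameters")
})

test_that("SWC round trip preserves topology, types and geometry", {
  m <- generate_morphology(3, 4, seed = 11)
  f1 <- tempfile(fileext = ".swc")
  f2 <- tempfile(fileext = ".swc")
  write_swc(m, f1)
  m2 <- read_swc(f1)
  write_swc(m2, f2)
  m3 <- read_swc(f2)

  expect_identical(m2$n_basal_branches, m$n_basal_branches)
  expect_identical(m2$n_apical_branches, m$n_apical_branches)
  expect_identical(m3$compartments$parent, m2$compartments$parent)
  expect_identical(m3$compartments$section, m2$compartments$section)
  expect_equal(m3$compartments$length, m2$compartments$length,
               tolerance = 1e-3)
  expect_equal(m3$compartments$diam, m2$compartments$diam, tolerance = 1e-6)
  unlink(c(f1, f2))
})

test_that("minimal and malformed SWC files are handled", {
  # 3-point soma plus one dendrite sample -> soma + 1 basal section
  f <- tempfile(fileext = ".swc")
  writeLines(c("# soma + dendrite",
               "1 1 0 0 0 7 -1",
               "2 1 0 8 0 7 1",
               "3 1 0 -8 0 7 1",
               "4 3 0 40 0 1 2"), f)
  m <- read_swc(f)
  expect_identical(nrow(m$compartments), 2L)
  expect_identical(m$compartments$section, c("soma", "basal"))

  writeLines(c("1 1 0 0 0 7 -1",
               "2 3 0 40 0 1 9"), f)
  expect_error(read_swc(f), "parent missing for id\\(s\\) 2")
  unlink(f)
})
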