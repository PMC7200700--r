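# shared fixtures, built once per test run

the_cache <- new.env(parent = emptyenv())

small_morph <- function() {
  if (is.null(the_cache$small_morph))
    the_cache$small_morph <- generate_morphology(n_basal = 4, n_apical = 6,
                                                 depth = 2, seed = 42)
  the_cache$small_morph
}

small_cell <- function() {
  if (is.null(the_cache$small_cell))
    the_cache$small_cell <- build_cell(small_morph())
  the_cache$small_cell
}

# a reduced cell: soma plus a short apical chain (5 compartments)
tiny_morph <- function() {
  morphology(data.frame(
    id = 1:5, parent = c(NA, 1, 2, 3, 4),
    section = c("soma", rep("apical_trunk", 4)),
    length = c(20, 50, 50, 50, 50), diam = c(15, 2.5, 2, 1.5, 1.2)))
}

# von Mises sampler (degrees) used to plant phase-locked spikes
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 360))
  # Best-Fisher rejection sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- (mu + theta * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

# heavier shared fixtures for the acceptance checks (built once)

acceptance_panel <- function() {
  if (is.null(the_cache$panel)) {
    cells <- build_cell_panel(n_cells = 8, seed = 2)
    the_cache$panel <- list(
      cells = cells,
      experiment = sublayer_experiment(cells, n_cycles = 200, seed = 11))
  }
  the_cache$panel
}

pv_removal_runs <- function() {
  if (is.null(the_cache$pv)) {
    cells <- acceptance_panel()$cells
    run_cond <- function(manip) lapply(seq_along(cells), function(i) {
      cfg <- experiment_config(n_cycles = 200, manipulation = manip,
                               manipulation_mode = "rate",
                               seed = 11 * 1000 + i)
      run_theta(cells[[i]], cfg)
    })
    the_cache$pv <- list(baseline = run_cond(c()),
                         removed = run_cond(c(PV = 0)))
  }
  the_cache$pv
}
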