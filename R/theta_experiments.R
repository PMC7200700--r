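## In-silico theta experiments: sublayer (PV/CCK) profiles, interneuron
## manipulations, glutamatergic scans, and the firing-rate inclusion rule.

#' Assemble a synthetic cell
#'
#' A synthetic cell is a morphology combined with an intrinsic GA factor
#' vector and a pathway parameterization (optionally rescaled by synaptic
#' GA factors on the CA3 feedforward loop).
#'
#' @param morph a `ca1_morphology`.
#' @param intrinsic named GA factor vector (defaults to all 1).
#' @param pathways pathway table (defaults to [default_pathways()]).
#' @param synaptic optional named vector of multipliers on pathway
#'   `gmax_uS` (names = pathway names).
#' @param id optional label.
#' @return object of class `synthetic_cell`.
#' @export
synthetic_cell <- function(morph, intrinsic = NULL,
                           pathways = default_pathways(), synaptic = NULL,
                           id = NULL) {
  stopifnot(inherits(morph, "ca1_morphology"))
  if (!is.null(synaptic)) {
    if (is.null(names(synaptic)) || !all(names(synaptic) %in% pathways$name))
      stop("synaptic factors must be named over pathway names")
    for (nm in names(synaptic))
      pathways$gmax_uS[pathways$name == nm] <-
        pathways$gmax_uS[pathways$name == nm] * synaptic[[nm]]
  }
  structure(list(morphology = morph, intrinsic = intrinsic,
                 pathways = pathways, id = id), class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat("synthetic_cell", if (!is.null(x$id)) paste0("[", x$id, "]"), ":",
      nrow(x$morphology$compartments), "compartments,",
      nrow(x$pathways), "input pathways\n")
  invisible(x)
}

#' Sublayer manipulation profiles
#'
#' Perisomatic-bouton fractions emulating the differential PV/CCK basket
#' innervation of the CA1 sublayers: deep cells retain 30% of CCK and 100%
#' of PV boutons, superficial cells 100% CCK and 30% PV.
#'
#' @param kind `"deep"`, `"superficial"` or `"none"`.
#' @return named fraction vector for [apply_manipulation()].
#' @export
sublayer_profile <- function(kind = c("none", "deep", "superficial")) {
  kind <- match.arg(kind)
  switch(kind,
         none = c(),
         deep = c(CCK = 0.30, PV = 1.00),
         superficial = c(CCK = 1.00, PV = 0.30))
}

#' Experiment configuration
#'
#' @param n_cycles theta cycles to simulate (the reference protocol uses
#'   1000; desk-scale runs use 100-300).
#' @param theta_freq theta frequency, Hz.
#' @param profile sublayer profile kind.
#' @param manipulation extra named fraction vector.
#' @param manipulation_mode `"boutons"` or `"rate"`.
#' @param dt integration step, ms (0.05 for population experiments; halve
#'   it to check convergence).
#' @param seed master seed; per-cell condition streams derive from it.
#' @export
experiment_config <- function(n_cycles = 1000, theta_freq = 8,
                              profile = "none", manipulation = c(),
                              manipulation_mode = "boutons", dt = 0.05,
                              seed = 1) {
  stopifnot(n_cycles >= 1, theta_freq > 0)
  list(n_cycles = n_cycles, theta_freq = theta_freq, profile = profile,
       manipulation = manipulation, manipulation_mode = manipulation_mode,
       dt = dt, seed = seed)
}

#' Run a theta-drive simulation on a synthetic cell
#'
#' Applies the sublayer profile and any extra manipulation to the cell's
#' pathways, generates the theta-modulated event schedule, integrates the
#' cell and returns somatic spike phases against the sinusoidal reference
#' (trough 0, peak 180) together with the somatic and dendritic traces.
#'
#' @param cell a `synthetic_cell`.
#' @param cfg an [experiment_config()].
#' @return object of class `theta_run`: `phases` (spike table), `rate`
#'   (Hz), `cycle_phases` (per-cycle spike phases, for the surrogate test),
#'   `trace`, `schedule`, `cfg`.
#' @export
run_theta <- function(cell, cfg = experiment_config()) {
  stopifnot(inherits(cell, "synthetic_cell"))
  pw <- cell$pathways
  prof <- sublayer_profile(cfg$profile)
  if (length(prof)) pw <- apply_manipulation(pw, prof, mode = "boutons")
  if (length(cfg$manipulation))
    pw <- apply_manipulation(pw, cfg$manipulation,
                             mode = cfg$manipulation_mode)

  sched <- build_theta_schedule(cell$morphology, pw,
                                n_cycles = cfg$n_cycles,
                                theta_freq = cfg$theta_freq,
                                seed = cfg$seed)
  hhcell <- build_cell(cell$morphology, factors = cell$intrinsic)
  tr <- hh_integrate(hhcell, list(events = sched),
                     duration = sched$duration, dt = cfg$dt,
                     record = c("soma", "proximal", "distal"))
  sp <- detect_spikes(tr$v[, "soma"], tr$fs)
  ph <- spike_phases(sp, theta_freq = cfg$theta_freq)
  cyc_ph <- split(ph$phase, factor(ph$cycle, levels = seq_len(cfg$n_cycles)))
  structure(list(phases = ph,
                 rate = length(sp) / (sched$duration / 1000),
                 cycle_phases = cyc_ph,
                 trace = tr, schedule = sched, cfg = cfg),
            class = "theta_run")
}

#' @export
print.theta_run <- function(x, ...) {
  cat(sprintf("theta_run: %d spikes over %d cycles (%.2f Hz)\n",
              nrow(x$phases), x$cfg$n_cycles, x$rate))
  if (nrow(x$phases) >= 4) {
    mv <- mean_vector(x$phases$phase)
    cat(sprintf("  R = %.2f, preferred phase = %.0f deg, TP = %.2f\n",
                mv$R, mv$mu, tp_index(x$phases$phase)))
  }
  invisible(x)
}

#' Firing-rate inclusion rule
#'
#' A synthetic-cell individual is included when its firing rate is
#' realistic (within `[lo, hi]` Hz) in at least `min_morphologies` of the
#' morphologies it was simulated in.
#'
#' @param rates named numeric vector, one rate per morphology.
#' @param lo,hi realistic-rate bounds, Hz (defaults 0.01 and 8).
#' @param min_morphologies minimum morphologies in range (default 3).
#' @export
include_by_rate <- function(rates, lo = 0.01, hi = 8, min_morphologies = 3) {
  if (!length(rates)) stop("at least one rate is required")
  if (any(rates < 0)) stop("rates must be >= 0")
  sum(rates >= lo & rates <= hi) >= min_morphologies
}

#' Scan glutamatergic input levels
#'
#' One simulation per rate multiplier on the chosen pathway, with a shared
#' seed derivation so conditions are paired.
#'
#' @param cell a `synthetic_cell`.
#' @param pathway `"CA3"`, `"ECIII"` or `"CA2"`.
#' @param levels positive rate multipliers (level 1 is the baseline).
#' @param cfg an [experiment_config()].
#' @return named list of `theta_run` objects (names = levels).
#' @export
glutamatergic_scan <- function(cell, pathway = c("CA3", "ECIII", "CA2"),
                               levels = c(0.5, 1, 2), cfg = experiment_config()) {
  pathway <- match.arg(pathway)
  if (any(levels < 0)) stop("levels must be >= 0")
  out <- lapply(levels, function(lv) {
    cfg_lv <- cfg
    if (lv <= 1) {
      cfg_lv$manipulation <- c(cfg$manipulation,
                               structure(lv, names = pathway))
      cfg_lv$manipulation_mode <- "rate"
      run_theta(cell, cfg_lv)
    } else {
      # fractions cap at 1; upscale the pathway rate directly
      cell2 <- cell
      i <- which(cell2$pathways$name == pathway)
      cell2$pathways$rate[i] <- cell2$pathways$rate[i] * lv
      run_theta(cell2, cfg_lv)
    }
  })
  names(out) <- as.character(levels)
  out
}

#' Build a panel of synthetic cells
#'
#' Cells combine generated morphologies with jittered intrinsic GA factors
#' (uniform within `jitter` of 1), emulating the GA-derived individual
#' variability.
#'
#' @param n_cells panel size.
#' @param n_basal,n_apical,depth morphology parameters.
#' @param jitter half-width of the factor jitter.
#' @param seed integer seed.
#' @return list of `synthetic_cell` objects.
#' @export
build_cell_panel <- function(n_cells = 8, n_basal = 4, n_apical = 6,
                             depth = 2, jitter = 0.10, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  lapply(seq_len(n_cells), function(i) {
    m <- generate_morphology(n_basal = n_basal, n_apical = n_apical,
                             depth = depth, seed = seed * 1000 + i)
    set.seed(seed * 2000 + i)
    f <- structure(runif(length(GA_PARAMS), 1 - jitter, 1 + jitter),
                   names = GA_PARAMS)
    synthetic_cell(m, intrinsic = f, id = paste0("cell", i))
  })
}

#' Deep-vs-superficial sublayer experiment on a cell panel
#'
#' Runs each cell under the deep (30% CCK / 100% PV) and superficial
#' (100% CCK / 30% PV) perisomatic profiles, computes per-cell TP indices,
#' and compares the two profiles with a permutation test on the mean
#' difference of paired TP values.
#'
#' @param cells list of `synthetic_cell`s (e.g. [build_cell_panel()]).
#' @param n_cycles theta cycles per run.
#' @param n_perm permutations for the group comparison.
#' @param seed master seed.
#' @param min_spikes minimum spikes for a cell to enter the comparison.
#' @return list: `tp` (per cell x profile), `rates`, `p_perm`,
#'   `mean_deep`, `mean_superficial`, and the run objects.
#' @export
sublayer_experiment <- function(cells, n_cycles = 200, n_perm = 2000,
                                seed = 1, min_spikes = 10) {
  runs <- list()
  tp <- data.frame(cell = character(), deep = numeric(),
                   superficial = numeric())
  rates <- data.frame(cell = character(), deep = numeric(),
                      superficial = numeric())
  for (i in seq_along(cells)) {
    for (prof in c("deep", "superficial")) {
      cfg <- experiment_config(n_cycles = n_cycles, profile = prof,
                               seed = .sub_seed(seed, i))
      runs[[paste0(i, "_", prof)]] <- run_theta(cells[[i]], cfg)
    }
    rd <- runs[[paste0(i, "_deep")]]
    rs <- runs[[paste0(i, "_superficial")]]
    rates <- rbind(rates, data.frame(cell = i, deep = rd$rate,
                                     superficial = rs$rate))
    if (nrow(rd$phases) >= min_spikes && nrow(rs$phases) >= min_spikes)
      tp <- rbind(tp, data.frame(cell = i,
                                 deep = tp_index(rd$phases$phase),
                                 superficial = tp_index(rs$phases$phase)))
  }
  if (!nrow(tp)) stop("no cell produced enough spikes in both profiles")

  # paired permutation: flip profile labels within cells
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d_obs <- mean(tp$superficial - tp$deep)
  flips <- matrix(sample(c(-1, 1), n_perm * nrow(tp), replace = TRUE),
                  n_perm, nrow(tp))
  d_null <- flips %*% (tp$superficial - tp$deep) / nrow(tp)
  p_perm <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_perm + 1)

  list(tp = tp, rates = rates, p_perm = p_perm,
       mean_deep = mean(tp$deep), mean_superficial = mean(tp$superficial),
       runs = runs)
}

#' Per-cycle phase of maximal dendritic depolarization
#'
#' For every theta cycle of a run, the phase (trough-0 convention) at which
#' the recorded dendritic potential reaches its maximum. Spike timing need
#' not follow the dendritic envelope: somatic firing results from the
#' interplay of dendritic drive, perisomatic inhibition and intrinsic
#' currents, so the two phase distributions can dissociate.
#'
#' @param run a `theta_run`.
#' @param site trace to analyze: `"proximal"` or `"distal"`.
#' @return numeric vector, one phase per complete cycle.
#' @export
dendritic_peak_phases <- function(run, site = c("proximal", "distal")) {
  site <- match.arg(site)
  tr <- run$trace
  if (!site %in% colnames(tr$v))
    stop("trace does not contain a ", site, " recording")
  period <- 1000 / run$cfg$theta_freq
  n_cycles <- run$cfg$n_cycles
  cyc <- pmin(floor(tr$t / period), n_cycles - 1)
  v <- tr$v[, site]
  vapply(0:(n_cycles - 1), function(k) {
    idx <- which(cyc == k)
    (tr$t[idx[which.max(v[idx])]] %% period) / period * 360
  }, numeric(1))
}
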