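## Evolutionary fitting of GA factors to target response features, and the
## cross-morphology validation loop.

#' Default GA factor bounds
#'
#' Dimensionless multiplier ranges for the eight active conductances, the
#' leak and the axial resistivity.
#'
#' @param lo,hi common bounds applied to every factor.
#' @return data.frame with rownames over the GA parameters.
#' @export
default_factor_bounds <- function(lo = 0.5, hi = 2) {
  data.frame(lo = rep(lo, length(GA_PARAMS)), hi = rep(hi, length(GA_PARAMS)),
             row.names = GA_PARAMS)
}

#' Measure intrinsic response features of a cell
#'
#' Somatic current-step protocol: settle to rest, a hyperpolarizing step
#' (input resistance and sag), and a depolarizing step (spike count and
#' spike peak).
#'
#' @param cell a `ca1_cell`.
#' @param settle_ms settling time before measurements.
#' @param step_ms step duration.
#' @param step_amp depolarizing step, nA.
#' @param sag_amp hyperpolarizing step, nA (negative).
#' @param dt integration step, ms.
#' @return named vector: `v_rest` (mV), `R_in` (MOhm), `sag_ratio`,
#'   `n_spikes`, `spike_peak` (mV).
#' @export
measure_cell_features <- function(cell, settle_ms = 600, step_ms = 400,
                                  step_amp = 0.4, sag_amp = -0.15,
                                  dt = 0.05) {
  soma_id <- cell$compartments$id[cell$compartments$section == "soma"][1]
  rest <- hh_integrate(cell, duration = settle_ms, dt = dt, record = "soma")
  v_rest <- tail(rest$v[, "soma"], 1)

  hyp <- hh_integrate(cell, list(steps = data.frame(
    compartment = soma_id, t0 = settle_ms, t1 = settle_ms + step_ms,
    amp_nA = sag_amp)),
    duration = settle_ms + step_ms, dt = dt, record = "soma")
  seg <- hyp$v[hyp$t > settle_ms, "soma"]
  v_min <- min(seg)
  v_ss <- mean(tail(seg, round(length(seg) * 0.1)))
  R_in <- (v_ss - v_rest) / sag_amp            # mV/nA = MOhm
  sag_ratio <- if (v_rest - v_min > 1e-9)
    (v_ss - v_min) / (v_rest - v_min) else 0

  dep <- hh_integrate(cell, list(steps = data.frame(
    compartment = soma_id, t0 = settle_ms, t1 = settle_ms + step_ms,
    amp_nA = step_amp)),
    duration = settle_ms + step_ms, dt = dt, record = "soma")
  sp <- detect_spikes(dep$v[, "soma"], dep$fs)
  c(v_rest = v_rest, R_in = R_in, sag_ratio = sag_ratio,
    n_spikes = length(sp),
    spike_peak = if (length(sp)) max(dep$v[, "soma"]) else v_rest)
}

#' Build acceptance intervals around reference features
#'
#' @param features named feature vector (as from
#'   [measure_cell_features()]).
#' @param tol named list/vector of half-widths per feature; defaults give
#'   physiologically meaningful margins.
#' @return a fitness-target data.frame: feature, lo, hi.
#' @export
fitness_targets <- function(features,
                            tol = c(v_rest = 2, R_in = NA, sag_ratio = 0.05,
                                    n_spikes = 1, spike_peak = 6)) {
  lo <- hi <- numeric(length(features))
  for (i in seq_along(features)) {
    f <- names(features)[i]
    t_i <- if (f %in% names(tol) && !is.na(tol[[f]])) tol[[f]]
    else 0.2 * abs(features[[i]])   # relative margin (e.g. R_in)
    lo[i] <- features[[i]] - t_i
    hi[i] <- features[[i]] + t_i
  }
  data.frame(feature = names(features), lo = lo, hi = hi)
}

#' Score an individual against fitness targets
#'
#' The error is the count of measured features falling outside their
#' acceptance interval; a feature exactly on a boundary counts as inside.
#' A diverging simulation yields an infinite error (invalid individual).
#'
#' @param features measured feature vector, or a function to call.
#' @param targets fitness-target data.frame (feature, lo, hi).
#' @return integer error (0 = all targets met), or `Inf` on divergence.
#' @export
score_features <- function(features, targets) {
  if (any(targets$lo > targets$hi)) stop("empty acceptance interval")
  f <- features[targets$feature]
  if (any(is.na(f))) stop("missing feature(s): ",
                          paste(targets$feature[is.na(f)], collapse = ", "))
  sum(f < targets$lo | f > targets$hi)
}

#' Intrinsic scorer for a morphology
#'
#' Returns a closure mapping a GA factor vector to its integer error on
#' `targets`, building the cell and running the measurement protocol.
#' Simulation divergence gives `Inf`.
#'
#' @param morph a `ca1_morphology`.
#' @param targets fitness targets.
#' @param ... protocol options for [measure_cell_features()].
#' @export
make_intrinsic_scorer <- function(morph, targets, ...) {
  force(morph); force(targets)
  dots <- list(...)
  function(factors) {
    feats <- tryCatch(
      do.call(measure_cell_features,
              c(list(build_cell(morph, factors = factors)), dots)),
      error = function(e) NULL)
    if (is.null(feats)) return(Inf)
    score_features(feats, targets)
  }
}

#' Evolve GA factors toward target behavior
#'
#' Generational loop: every individual is scored; successful individuals
#' (error 0) survive with probability `p_success`, unsuccessful ones with
#' `p_fail` (promoting variability); vacancies are refilled by uniform
#' resampling within bounds; then a `mutate_frac` fraction of individuals
#' has exactly one randomly chosen factor redrawn uniformly within its
#' range. All error-0 individuals encountered are collected.
#'
#' @param score_fn function(named factor vector) -> integer error.
#' @param bounds data.frame (lo, hi) with factor names as rownames.
#' @param pop_size population size (>= 10).
#' @param generations generation count (default 100).
#' @param p_success,p_fail survival probabilities.
#' @param mutate_frac fraction of individuals mutated per generation.
#' @param per_value if `TRUE`, survival is decided per factor value
#'   (non-survivors have that value resampled) instead of per individual.
#' @param elitism keep the best individual unchanged each generation.
#' @param stop_at_valid stop once this many distinct error-0 individuals
#'   have been found (`Inf` runs all generations).
#' @param seed integer seed.
#' @return list: `valid` (matrix of error-0 individuals), `best_error`
#'   per generation, `mutated_fraction` realized per generation,
#'   `generations_run`.
#' @export
evolve <- function(score_fn, bounds, pop_size = 64, generations = 100,
                   p_success = 0.4, p_fail = 0.2, mutate_frac = 0.4,
                   per_value = FALSE, elitism = FALSE, stop_at_valid = Inf,
                   seed = 1) {
  if (pop_size < 10) stop("population must hold >= 10 individuals")
  if (generations < 1) stop("generations must be >= 1")
  k <- nrow(bounds)
  fnames <- rownames(bounds)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  draw <- function(n) {
    m <- matrix(runif(n * k, rep(bounds$lo, each = n),
                      rep(bounds$hi, each = n)), n, k)
    colnames(m) <- fnames
    m
  }
  pop <- draw(pop_size)
  errors <- rep(NA_real_, pop_size)
  valid <- list()
  best_error <- numeric(0)
  mut_frac <- numeric(0)

  score_row <- function(x) {
    names(x) <- fnames
    score_fn(x)
  }

  for (gen in seq_len(generations)) {
    need <- is.na(errors)
    errors[need] <- apply(pop[need, , drop = FALSE], 1, score_row)
    best_error <- c(best_error, min(errors))
    for (i in which(errors == 0))
      valid[[paste(signif(pop[i, ], 10), collapse = "|")]] <- pop[i, ]
    if (length(valid) >= stop_at_valid) {
      mut_frac <- c(mut_frac, NA)
      break
    }

    if (per_value) {
      keep_val <- matrix(runif(pop_size * k) <
                           ifelse(errors == 0, p_success, p_fail),
                         pop_size, k)
      if (elitism) keep_val[which.min(errors), ] <- TRUE
      repl <- draw(pop_size)
      newpop <- ifelse(keep_val, pop, repl)
      new_err <- ifelse(rowSums(!keep_val) == 0, errors, NA_real_)
    } else {
      keep <- runif(pop_size) < ifelse(errors == 0, p_success, p_fail)
      if (elitism) keep[which.min(errors)] <- TRUE
      n_new <- sum(!keep)
      newpop <- pop
      new_err <- errors
      if (n_new) {
        newpop[!keep, ] <- draw(n_new)
        new_err[!keep] <- NA_real_
      }
    }

    n_mut <- round(mutate_frac * pop_size)
    mut_idx <- sample.int(pop_size, n_mut)
    if (elitism) mut_idx <- setdiff(mut_idx, which.min(new_err))
    for (i in mut_idx) {
      j <- sample.int(k, 1)
      newpop[i, j] <- runif(1, bounds$lo[j], bounds$hi[j])
      new_err[i] <- NA_real_
    }
    mut_frac <- c(mut_frac, length(mut_idx) / pop_size)
    pop <- newpop
    errors <- new_err
  }

  valid_mat <- if (length(valid)) do.call(rbind, valid) else
    matrix(numeric(0), 0, k, dimnames = list(NULL, fnames))
  rownames(valid_mat) <- NULL
  list(valid = valid_mat, best_error = best_error,
       mutated_fraction = mut_frac, generations_run = length(best_error))
}

#' Cross-morphology validation of GA individuals
#'
#' Randomly picks `n_pick` error-0 individuals from the pool and verifies
#' each against every morphology's scorer; failures are replaced by new
#' random picks from the remaining pool until the set validates or the
#' pool/budget is exhausted.
#'
#' @param pool matrix of error-0 individuals (rows).
#' @param scorers list of scoring functions, one per morphology.
#' @param n_pick validated individuals required (default 20).
#' @param budget maximum replacement draws.
#' @param seed integer seed.
#' @return matrix of `n_pick` validated individuals.
#' @export
cross_morphology_validate <- function(pool, scorers, n_pick = 20,
                                      budget = 10 * n_pick, seed = 1) {
  if (!nrow(pool)) stop("empty pool of error-0 individuals")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  remaining <- sample.int(nrow(pool))
  validated <- list()
  draws <- 0L
  while (length(validated) < n_pick && length(remaining) && draws < budget) {
    i <- remaining[1]
    remaining <- remaining[-1]
    draws <- draws + 1L
    x <- structure(as.numeric(pool[i, ]), names = colnames(pool))
    ok <- all(vapply(scorers, function(s) s(x) == 0, logical(1)))
    if (ok) validated[[length(validated) + 1L]] <- x
  }
  if (length(validated) < n_pick)
    stop("pool exhausted: validated ", length(validated), " of ", n_pick,
         " requested individuals")
  out <- do.call(rbind, validated)
  rownames(out) <- NULL
  out
}

#' Somatic PSP response to a synchronous CA3 volley
#'
#' Places the CA3 pathway's boutons, delivers one simultaneous volley
#' (optionally with the feedforward GABAergic contingent delayed by
#' `ff_delay_ms`) and measures the somatic PSP amplitude and half-width.
#'
#' @param cell a `ca1_cell`.
#' @param morph the cell's morphology.
#' @param pathways pathway table; `synaptic` multipliers on `gmax_uS` may
#'   be applied first (names over pathway names).
#' @param synaptic named multipliers on pathway peak conductances.
#' @param n_boutons volley size (sampled from the pathway placements).
#' @param feedforward include the CA3-driven inhibitory contingent
#'   (Axo, Bis, CCK, PV, SCA).
#' @param ff_delay_ms disynaptic delay of the feedforward volley.
#' @param t_volley volley time, ms.
#' @param duration,dt simulation window and step, ms.
#' @param seed integer seed for bouton sampling.
#' @return named vector: `psp_amp` (mV) and `psp_halfwidth` (ms).
#' @export
measure_psp <- function(cell, morph, pathways = default_pathways(),
                        synaptic = NULL, n_boutons = 60,
                        feedforward = TRUE, ff_delay_ms = 2,
                        t_volley = 400, duration = 600, dt = 0.05,
                        seed = 1) {
  if (!is.null(synaptic))
    for (nm in names(synaptic))
      pathways$gmax_uS[pathways$name == nm] <-
        pathways$gmax_uS[pathways$name == nm] * synaptic[[nm]]
  pws <- if (feedforward) c("CA3", "Axo", "Bis", "CCK", "PV", "SCA")
  else "CA3"
  ev <- do.call(rbind, lapply(pws, function(nm) {
    pw <- pathways[nm, ]
    b <- place_boutons(morph, pw, seed = seed)
    if (!length(b)) return(NULL)
    k <- min(n_boutons, length(b))
    data.frame(compartment = b[seq_len(k)],
               time = t_volley + if (nm == "CA3") 0 else ff_delay_ms,
               tau_rise = pw$tau_rise, tau_decay = pw$tau_decay,
               erev = pw$erev, gmax_uS = pw$gmax_uS)
  }))
  tr <- hh_integrate(cell, list(events = ev), duration = duration, dt = dt,
                     record = "soma", record_dt = dt)
  v <- tr$v[, "soma"]
  base <- v[which.min(abs(tr$t - t_volley))]
  post <- tr$t > t_volley
  amp <- max(v[post]) - base
  half <- base + amp / 2
  above <- post & v > half
  hw <- if (any(above)) diff(range(tr$t[above])) else 0
  c(psp_amp = amp, psp_halfwidth = hw)
}

#' Synaptic scorer for the CA3 feedforward loop
#'
#' Returns a closure mapping synaptic factors (multipliers on the CA3 and
#' feedforward-GABAergic peak conductances) to an integer error on PSP
#' targets, the quantity the synaptic GA fits per morphology.
#'
#' @param morph a `ca1_morphology`.
#' @param targets fitness targets over `psp_amp` / `psp_halfwidth`.
#' @param pathways pathway table.
#' @param ... options for [measure_psp()].
#' @export
make_synaptic_scorer <- function(morph, targets,
                                 pathways = default_pathways(), ...) {
  force(morph); force(targets); force(pathways)
  dots <- list(...)
  cell <- build_cell(morph)
  function(factors) {
    feats <- tryCatch(
      do.call(measure_psp, c(list(cell, morph, pathways = pathways,
                                  synaptic = as.list(factors)), dots)),
      error = function(e) NULL)
    if (is.null(feats)) return(Inf)
    score_features(feats, targets)
  }
}
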