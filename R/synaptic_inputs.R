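## Theta-modulated pathway inputs: bouton placement along the morphology,
## phase-tuned event sampling, double-exponential conductances, and the
## manipulation operators used by the in-silico experiments.

PATHWAY_NAMES <- c("CA3", "CA2", "ECIII", "ECII", "Axo", "Bis", "CCK",
                   "Ivy", "NGF", "OLM", "PV", "SCA")

#' Default synaptic pathway configuration
#'
#' One row per input population: four glutamatergic pathways (CA3, CA2,
#' ECIII, ECII; reversal 0 mV) and eight GABAergic interneuron types
#' (reversal -75 mV). `z_lo`/`z_hi` delimit the somatodendritic target band
#' in signed path distance (basal negative, apical positive; the perisomatic
#' band is -50 to 150 um; Schaffer/CA3 synapses target the apical trunk
#' band of stratum radiatum). `phase_mu` is the preferred theta phase of the
#' presynaptic population under the trough-0/peak-180 convention; `beta1`,
#' `beta2` shape the asymmetric (Beta-function) phase dispersion. Bouton
#' counts are desk-scale, so per-contact conductances are effective values
#' absorbing the larger real synapse numbers (and, for the distal
#' entorhinal pathway, the dendritic amplification that NMDA receptors
#' would otherwise provide). All values are conventions standing in for
#' experimental tables and can be overridden or rescaled.
#'
#' @return data.frame with one row per pathway (rownames = pathway names).
#' @export
default_pathways <- function() {
  p <- data.frame(
    name = PATHWAY_NAMES,
    class = c(rep("glutamatergic", 4), rep("GABAergic", 8)),
    n_boutons = c(1200, 250, 600, 150, 40, 150, 80, 120, 80, 100, 120, 60),
    z_lo = c(50, -200, 350, 350, -30, -350, -50, -350, 350, 350, -50, 50),
    z_hi = c(350, 200, Inf, Inf, 30, 350, 150, 350, Inf, Inf, 150, 350),
    erev = c(rep(0, 4), rep(-75, 8)),
    tau_rise = c(0.5, 0.5, 0.5, 0.5, 0.3, 0.5, 0.5, 1, 2, 0.5, 0.3, 0.5),
    tau_decay = c(3, 3, 3, 3, 2, 4, 5, 10, 30, 5, 2, 5),
    gmax_uS = c(3.1e-3, 3.1e-3, 4.7e-2, 3.1e-3, 9e-4, 2.4e-3, 1.8e-2,
                5e-4, 5e-4, 2.4e-3, 9e-3, 5e-4),
    rate = c(2, 2, 3, 2, 15, 20, 8, 5, 8, 15, 25, 5),
    phase_mu = c(10, 330, 180, 350, 185, 20, 180, 60, 200, 10, 250, 250),
    beta1 = c(2, 2, 5, 2, 4, 4, 4, 2, 2, 4, 4, 2),
    beta2 = c(2, 2, 5, 2, 4, 4, 4, 2, 2, 4, 4, 2),
    row.names = PATHWAY_NAMES)
  .validate_pathways(p)
  p
}

.validate_pathways <- function(p) {
  stopifnot(is.data.frame(p))
  if (any(p$tau_rise == p$tau_decay))
    stop("degenerate synapse kinetics: tau_rise must differ from tau_decay")
  if (any(p$gmax_uS < 0) || any(p$rate < 0) || any(p$n_boutons < 0))
    stop("gmax, rate and bouton counts must be >= 0")
  if (any(p$phase_mu < 0 | p$phase_mu >= 360))
    stop("phase_mu must lie in [0, 360)")
  if (any(p$beta1 <= 0) || any(p$beta2 <= 0))
    stop("beta shape parameters must be > 0")
  glut <- p$class == "glutamatergic"
  if (any(p$erev[glut] != 0)) stop("glutamatergic reversal must be 0 mV")
  if (any(p$erev[!glut] >= -60)) stop("GABAergic reversal must be < -60 mV")
  invisible(TRUE)
}

# signed somatodendritic distance: basal negative, soma 0, apical positive
.signed_z <- function(cp) ifelse(cp$section == "basal", -cp$z, cp$z)

# deterministic per-stream sub-seed derivation (31-bit)
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% 2147483647L) + 1L
}

#' Place pathway boutons on a morphology
#'
#' Samples `n_boutons` compartment assignments within the pathway's target
#' band, with probability proportional to compartment membrane area.
#' Seed-deterministic.
#'
#' @param morph a `ca1_morphology`.
#' @param pathway one row of a pathway table (see [default_pathways()]).
#' @param seed integer seed.
#' @return integer vector of compartment ids (length `n_boutons`).
#' @export
place_boutons <- function(morph, pathway, seed = 1) {
  stopifnot(inherits(morph, "ca1_morphology"), nrow(pathway) == 1L)
  cp <- morph$compartments
  sz <- .signed_z(cp)
  band <- sz >= pathway$z_lo & sz <= pathway$z_hi & cp$section != "soma"
  if (pathway$z_lo <= 0 && pathway$z_hi >= 0)
    band <- band | cp$section == "soma"
  if (!any(band))
    stop("pathway ", pathway$name, ": no compartments in target band [",
         pathway$z_lo, ", ", pathway$z_hi, "] um")
  if (pathway$n_boutons == 0L) return(integer(0))
  area <- pi * cp$diam * cp$length
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, match(pathway$name, PATHWAY_NAMES)))
  sample(cp$id[band], pathway$n_boutons, replace = TRUE,
         prob = area[band] / sum(area[band]))
}

#' Sample theta-phase-tuned event times for one presynaptic source
#'
#' Event counts per theta cycle are Poisson with mean `rate / theta_freq`;
#' each event phase is drawn from a Beta(beta1, beta2) distribution mapped
#' onto the full cycle `[phase_mu - 180, phase_mu + 180)` and wrapped
#' circularly, then converted to time within its cycle.
#'
#' @param pathway one row of a pathway table.
#' @param n_cycles number of theta cycles (>= 1).
#' @param theta_freq theta frequency, Hz.
#' @param seed integer seed.
#' @return numeric vector of event times in ms, sorted.
#' @export
sample_event_phases <- function(pathway, n_cycles, theta_freq = 8, seed = 1) {
  stopifnot(nrow(pathway) == 1L, n_cycles >= 1, theta_freq > 0)
  if (pathway$beta1 <= 0 || pathway$beta2 <= 0)
    stop("beta shape parameters must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 100L + match(pathway$name, PATHWAY_NAMES)))
  period <- 1000 / theta_freq
  counts <- rpois(n_cycles, pathway$rate / theta_freq)
  n <- sum(counts)
  if (!n) return(numeric(0))
  x <- rbeta(n, pathway$beta1, pathway$beta2)
  phase <- (pathway$phase_mu + (x - 0.5) * 360) %% 360
  cyc <- rep(seq_len(n_cycles) - 1L, counts)
  sort((cyc + phase / 360) * period)
}

#' Double-exponential synaptic conductance
#'
#' `g(t) = Gmax * (exp(-t/tau_decay) - exp(-t/tau_rise)) / norm`, normalized
#' so the conductance peaks exactly at `Gmax`; zero at the event time and
#' decaying back to zero.
#'
#' @param t_since_event time since the presynaptic event, ms (>= 0).
#' @param tau_rise,tau_decay kinetic time constants, ms (must differ).
#' @param gmax peak conductance, uS.
#' @export
syn_conductance <- function(t_since_event, tau_rise, tau_decay, gmax = 1) {
  if (any(t_since_event < 0)) stop("t_since_event must be >= 0")
  if (tau_rise == tau_decay) stop("degenerate synapse: tau_rise == tau_decay")
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  gmax * (exp(-t_since_event / tau_decay) - exp(-t_since_event / tau_rise)) / norm
}

#' Peak time of the double-exponential conductance
#' @inheritParams syn_conductance
#' @export
syn_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise == tau_decay) stop("degenerate synapse: tau_rise == tau_decay")
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Build the full theta-input schedule for a cell
#'
#' For every pathway: boutons are placed on the morphology, per-bouton event
#' trains are drawn (pooled Poisson across the pathway's boutons, which is
#' equivalent to independent per-bouton sampling), and events are stamped
#' with the pathway's synaptic kinetics.
#'
#' @param morph a `ca1_morphology`.
#' @param pathways pathway table (rows as in [default_pathways()]).
#' @param n_cycles number of theta cycles.
#' @param theta_freq theta frequency, Hz.
#' @param seed integer seed.
#' @return object of class `synaptic_schedule` with elements `events`
#'   (data.frame: compartment, time, pathway, tau_rise, tau_decay, erev,
#'   gmax_uS), `boutons` (per-pathway placements), `n_cycles`, `theta_freq`.
#' @export
build_theta_schedule <- function(morph, pathways = default_pathways(),
                                 n_cycles = 1000, theta_freq = 8, seed = 1) {
  .validate_pathways(pathways)
  period <- 1000 / theta_freq
  ev_list <- list()
  boutons <- list()
  for (i in seq_len(nrow(pathways))) {
    pw <- pathways[i, ]
    if (pw$n_boutons == 0L || pw$rate == 0) {
      boutons[[pw$name]] <- integer(0)
      next
    }
    b <- place_boutons(morph, pw, seed = seed)
    boutons[[pw$name]] <- b
    # pooled pathway train: rate scales with the number of boutons
    pooled <- pw
    pooled$rate <- pw$rate * pw$n_boutons
    times <- sample_event_phases(pooled, n_cycles, theta_freq, seed = seed)
    if (!length(times)) next
    old <- .Random.seed_save()
    set.seed(.sub_seed(seed, 200L + i))
    comp <- sample(b, length(times), replace = TRUE)
    .Random.seed_restore(old)
    ev_list[[pw$name]] <- data.frame(
      compartment = comp, time = times, pathway = pw$name,
      tau_rise = pw$tau_rise, tau_decay = pw$tau_decay,
      erev = pw$erev, gmax_uS = pw$gmax_uS)
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(compartment = integer(), time = numeric(),
               pathway = character(), tau_rise = numeric(),
               tau_decay = numeric(), erev = numeric(), gmax_uS = numeric())
  rownames(events) <- NULL
  structure(list(events = events[order(events$time), , drop = FALSE],
                 boutons = boutons, n_cycles = n_cycles,
                 theta_freq = theta_freq, duration = n_cycles * period),
            class = "synaptic_schedule")
}

#' @export
print.synaptic_schedule <- function(x, ...) {
  cat(sprintf("synaptic_schedule: %d events over %d cycles at %.1f Hz theta\n",
              nrow(x$events), x$n_cycles, x$theta_freq))
  if (nrow(x$events))
    print(table(x$events$pathway))
  invisible(x)
}

#' Scale pathway connectivity or input rate
#'
#' Applies the in-silico manipulations: `mode = "boutons"` rescales the
#' bouton counts (rounded half-up), `mode = "rate"` rescales presynaptic
#' rates; untouched pathways are unchanged. A fraction of 0 removes the
#' pathway entirely.
#'
#' @param pathways pathway table.
#' @param fractions named numeric vector, values in \[0, 1\] (names are
#'   pathway names).
#' @param mode `"boutons"` or `"rate"`.
#' @return modified pathway table.
#' @export
apply_manipulation <- function(pathways, fractions,
                               mode = c("boutons", "rate")) {
  mode <- match.arg(mode)
  if (!length(fractions)) return(pathways)
  if (is.null(names(fractions)) || !all(names(fractions) %in% pathways$name))
    stop("unknown pathway name(s): ",
         paste(setdiff(names(fractions), pathways$name), collapse = ", "))
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  for (nm in names(fractions)) {
    i <- which(pathways$name == nm)
    if (mode == "boutons")
      pathways$n_boutons[i] <- as.integer(floor(
        pathways$n_boutons[i] * fractions[[nm]] + 0.5))
    else
      pathways$rate[i] <- pathways$rate[i] * fractions[[nm]]
  }
  pathways
}

#' Write / read a synaptic schedule as delimited text
#' @param schedule a `synaptic_schedule`.
#' @param path output file.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "synaptic_schedule"))
  meta <- sprintf("# n_cycles=%d theta_freq=%g", schedule$n_cycles,
                  schedule$theta_freq)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  write.table(schedule$events, con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
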