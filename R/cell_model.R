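## Multicompartment Hodgkin-Huxley cell model: channel configuration,
## GA-factor conductance scaling, cable assembly and numerical integration.

CHANNELS <- c("Na", "KDR", "KA", "KM", "KC", "KAHP", "CaL", "HCN")
GA_PARAMS <- c(CHANNELS, "leak", "Ra")

#' Default gating kinetics
#'
#' Rate-function parameters for the nine-conductance channel set. Twelve
#' voltage-dependent gates are first-order Boltzmann processes
#' (`x_inf = 1/(1+exp(-(V-vhalf)/slope))`, fixed time constant); calcium-
#' dependent gates (KC opening, AHP activation, CaL inactivation) are Hill
#' functions of the intracellular calcium pool. Together with V and [Ca]
#' each compartment carries 18 coupled state equations. Every value can be
#' overridden, so kinetics from published CA1 pyramidal-cell models can be
#' dropped in.
#'
#' @return named list of kinetic parameters.
#' @export
default_kinetics <- function() {
  list(
    gates = data.frame(
      gate  = c("Na.m", "Na.h", "Na.s", "Na.d", "KDR.n", "KDR.k",
                "KA.a", "KA.b", "KM.u", "KC.c", "CaL.e", "HCN.h"),
      vhalf = c(-40, -45, -53, -58, -30, -50, -35, -70, -35, -25, -20, -82),
      slope = c(5, -5, -8, -10, 10, -15, 10, -8, 9, 10, 7, -7),
      tau   = c(0.1, 5, 200, 2000, 5, 1000, 0.6, 15, 50, 2, 1.5, 40)),
    floors = c(Na.s = 0.3, Na.d = 0.5, KDR.k = 0.4),
    calcium = c(kd_kc = 1e-3, kd_ahp = 5e-4, kd_cal = 2e-3,
                tau_o = 2, tau_q = 200, tau_f = 10,
                phi = 0.01, ca_rest = 5e-5, tau_ca = 80),
    reversal = c(Na = 50, K = -90, Ca = 120, HCN = -30, leak = -70))
}

.kinetics_vector <- function(kin = default_kinetics()) {
  g <- kin$gates
  c(as.vector(t(as.matrix(g[, c("vhalf", "slope", "tau")]))),
    unname(kin$floors[c("Na.s", "Na.d", "KDR.k")]),
    unname(kin$calcium[c("kd_kc", "kd_ahp", "kd_cal", "tau_o", "tau_q", "tau_f")]),
    unname(kin$calcium[c("phi", "ca_rest", "tau_ca")]),
    unname(kin$reversal[c("Na", "K", "Ca", "HCN")]))
}

#' Number of coupled state equations per compartment
#'
#' Membrane potential, the intracellular calcium pool, the voltage-dependent
#' gates of the kinetics table (the HCN row contributes fast and slow
#' components) and the three calcium-dependent gates (KC opening, AHP
#' activation, CaL inactivation).
#'
#' @param kinetics kinetics list as from [default_kinetics()].
#' @export
n_state_equations <- function(kinetics = default_kinetics()) {
  n_v_gates <- nrow(kinetics$gates) + 1L  # HCN.h integrates as hf + hs
  n_ca_gates <- 3L
  2L + n_v_gates + n_ca_gates
}

#' Default maximal-conductance distributions
#'
#' Somatodendritic Gmax profiles, linear in path distance z:
#' `g(z) = max(0, g0 * (1 + slope_per_um * z))` in S/cm2. Sodium and delayed
#' rectifier concentrate perisomatically (somatic spike initiation) while
#' A-type potassium, L-type calcium and HCN increase with distance,
#' approximating published CA1 channel gradients; the rising CaL profile
#' lets distal (tuft) input recruit dendritic calcium electrogenesis.
#'
#' @return data.frame with one row per active channel.
#' @export
default_gmax_profiles <- function() {
  data.frame(
    channel = CHANNELS,
    g0 = c(0.08, 0.012, 0.005, 0.0012, 0.003, 0.0005, 0.002, 0.0002),
    slope_per_um = c(-2.5e-3, -2.5e-3, 8e-3, 0, 0, 0, 6e-3, 8e-3),
    row.names = CHANNELS)
}

#' Effective conductance from a GA factor
#'
#' The genetic algorithm scales each maximal conductance by a dimensionless
#' factor: `g = Gmax * factor`.
#'
#' @param Gmax maximal conductance (S/cm2), >= 0.
#' @param factor dimensionless GA factor, >= 0.
#' @export
effective_conductance <- function(Gmax, factor) {
  if (any(Gmax < 0)) stop("Gmax must be >= 0")
  if (any(factor < 0)) stop("GA factor must be >= 0")
  Gmax * factor
}

#' Ionic current in the HH formalism
#'
#' `I = g * (V - Vrev)`: positive (outward) when V exceeds the reversal.
#'
#' @param g conductance (per-area or absolute), >= 0.
#' @param V membrane potential, mV.
#' @param Vrev reversal potential, mV.
#' @export
ionic_current <- function(g, V, Vrev) {
  if (any(g < 0)) stop("conductance must be >= 0")
  if (any(!is.finite(Vrev))) stop("Vrev must be finite")
  g * (V - Vrev)
}

#' Assemble a simulatable cell
#'
#' Combines a morphology with the passive rules (axial resistivity 100
#' Ohm cm scaled by its GA factor; somatic capacitance 5 uF/cm2 and
#' 1.8 x 5 x SS elsewhere; leak from the sigmoidal somatodendritic profile
#' times SS) and the GA-scaled channel conductance distributions.
#'
#' @param morph a `ca1_morphology`.
#' @param factors named numeric vector of GA factors over
#'   `c(CHANNELS, "leak", "Ra")`; missing entries default to 1.
#' @param gmax profile table as from [default_gmax_profiles()].
#' @param kinetics kinetics list as from [default_kinetics()].
#' @param cm_soma somatic specific capacitance, uF/cm2.
#' @param cm_dend_multiplier dendritic capacitance multiplier.
#' @param Ra_base axial resistivity, Ohm cm.
#' @return object of class `ca1_cell`.
#' @export
build_cell <- function(morph, factors = NULL,
                       gmax = default_gmax_profiles(),
                       kinetics = default_kinetics(),
                       cm_soma = 5, cm_dend_multiplier = 1.8,
                       Ra_base = 100) {
  stopifnot(inherits(morph, "ca1_morphology"))
  f <- structure(rep(1, length(GA_PARAMS)), names = GA_PARAMS)
  if (!is.null(factors)) {
    if (is.null(names(factors)) || !all(names(factors) %in% GA_PARAMS))
      stop("factors must be named over: ", paste(GA_PARAMS, collapse = ", "))
    if (any(factors < 0)) stop("GA factors must be >= 0")
    f[names(factors)] <- factors
  }

  cp <- morph$compartments
  ord <- order(cp$z, cp$id)  # parents strictly before children (z increases)
  cp <- cp[ord, , drop = FALSE]
  parent0 <- match(cp$parent, cp$id) - 1L
  parent0[is.na(parent0)] <- -1L

  area <- pi * cp$diam * cp$length * 1e-8           # cm2
  SS <- vapply(seq_len(nrow(cp)), function(i)
    spine_correction(cp$section[i], cp$z[i], cp$diam[i]), numeric(1))
  cm <- ifelse(cp$section == "soma", cm_soma, cm_soma * cm_dend_multiplier * SS)
  gpas <- effective_conductance(leak_conductance(cp$z, SS), f["leak"])

  gbar <- vapply(CHANNELS, function(ch) {
    prof <- gmax[ch, ]
    effective_conductance(
      pmax(0, prof$g0 * (1 + prof$slope_per_um * cp$z)), f[ch])
  }, numeric(nrow(cp)))
  gbar <- matrix(gbar, nrow = nrow(cp), dimnames = list(NULL, CHANNELS))

  Ra <- Ra_base * f["Ra"]                            # Ohm cm
  r_cm <- cp$diam / 2 * 1e-4
  half_res <- Ra * (cp$length * 1e-4 / 2) / (pi * r_cm^2)  # Ohm
  g_ax <- numeric(nrow(cp))
  has_parent <- parent0 >= 0
  g_ax[has_parent] <- 1e6 / (half_res[has_parent] +
                             half_res[parent0[has_parent] + 1L])  # uS

  structure(list(
    morphology = morph, order = ord, compartments = cp,
    parent0 = parent0, area = area, cm = cm, gpas = gpas,
    e_pas = unname(kinetics$reversal["leak"]),
    g_axial = g_ax, gbar = gbar, factors = f,
    kinetics = kinetics, Ra = Ra), class = "ca1_cell")
}

#' @export
print.ca1_cell <- function(x, ...) {
  cat(sprintf("ca1_cell: %d compartments, Ra %.0f Ohm cm\n",
              nrow(x$compartments), x$Ra))
  cat("GA factors: ",
      paste(sprintf("%s=%.2f", names(x$factors), x$factors), collapse = " "),
      "\n")
  invisible(x)
}

# compartment indices (in internal order) for the standard recording sites
.record_sites <- function(cell) {
  cp <- cell$compartments
  soma <- which(cp$section == "soma")[1]
  trunk <- which(cp$section == "apical_trunk")
  apical <- which(startsWith(cp$section, "apical"))
  proximal <- if (length(trunk)) trunk[which.min(cp$z[trunk])] else soma
  distal <- if (length(trunk)) trunk[which.max(cp$z[trunk])] else
    if (length(apical)) apical[which.max(cp$z[apical])] else soma
  c(soma = soma, proximal = proximal, distal = distal)
}

#' Integrate the multicompartment model
#'
#' Fixed-step integration: backward-Euler voltage update solved directly on
#' the dendritic tree (Hines ordering) and exponential-Euler gating states;
#' 18 state equations per compartment. Deterministic given cell and stimuli.
#' Integration aborts with a diagnostic naming compartment and time if any
#' membrane potential exceeds 200 mV in magnitude.
#'
#' @param cell a `ca1_cell`.
#' @param stimuli list with optional elements `steps` (data.frame
#'   `compartment`, `t0`, `t1`, `amp_nA`; compartment ids refer to the
#'   morphology) and `events` (a [synaptic_schedule()] object or data.frame
#'   `compartment`, `time`, `tau_rise`, `tau_decay`, `erev`, `gmax_uS`).
#' @param duration,dt simulation length and step, ms.
#' @param v_init initial potential, mV.
#' @param record which traces to keep: `"soma"`, `"proximal"`, `"distal"`.
#' @param record_dt trace sampling step, ms (multiple of `dt`).
#' @return object of class `ca1_trace`: time base, recorded potentials and
#'   sampling rate.
#' @export
hh_integrate <- function(cell, stimuli = list(), duration = 500, dt = 0.025,
                         v_init = -65,
                         record = c("soma", "proximal", "distal"),
                         record_dt = 0.1) {
  stopifnot(inherits(cell, "ca1_cell"), dt > 0, duration >= dt)
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  sites <- .record_sites(cell)
  record <- match.arg(record, c("soma", "proximal", "distal"),
                      several.ok = TRUE)
  rec_idx <- sites[record]

  steps <- stimuli$steps
  if (is.null(steps))
    steps <- data.frame(compartment = integer(), t0 = numeric(),
                        t1 = numeric(), amp_nA = numeric())
  inj_comp <- match(steps$compartment, cell$compartments$id) - 1L
  if (any(is.na(inj_comp))) stop("current step targets unknown compartment id")

  ev <- stimuli$events
  if (is.null(ev))
    ev <- data.frame(compartment = integer(), time = numeric(),
                     tau_rise = numeric(), tau_decay = numeric(),
                     erev = numeric(), gmax_uS = numeric())
  if (inherits(ev, "synaptic_schedule")) ev <- ev$events
  syn <- .build_syn_groups(ev, cell)

  out <- .hh_integrate_cpp(
    cell$parent0, cell$area, cell$cm, cell$gpas, cell$e_pas, cell$g_axial,
    as.matrix(cell$gbar), .kinetics_vector(cell$kinetics),
    syn$comp, syn$tau_rise, syn$tau_decay, syn$erev,
    syn$ev_group, syn$ev_time, syn$ev_weight,
    inj_comp, steps$t0, steps$t1, steps$amp_nA,
    dt, duration, v_init, rec_idx - 1L, rec_every)

  v <- out$v
  colnames(v) <- names(rec_idx)
  structure(list(t = out$t, v = v, fs = 1000 / (dt * rec_every),
                 dt = dt, duration = duration,
                 v_final = out$v_final), class = "ca1_trace")
}

#' @export
print.ca1_trace <- function(x, ...) {
  cat(sprintf("ca1_trace: %.0f ms at %.1f kHz, traces: %s\n",
              x$duration, x$fs / 1000, paste(colnames(x$v), collapse = ", ")))
  invisible(x)
}

# group synaptic events by (compartment, kinetics, reversal) for the solver
.build_syn_groups <- function(ev, cell) {
  if (!nrow(ev))
    return(list(comp = integer(), tau_rise = numeric(), tau_decay = numeric(),
                erev = numeric(), ev_group = integer(), ev_time = numeric(),
                ev_weight = numeric()))
  if (any(ev$tau_rise == ev$tau_decay))
    stop("degenerate synapse: tau_rise must differ from tau_decay")
  comp0 <- match(ev$compartment, cell$compartments$id) - 1L
  if (any(is.na(comp0))) stop("synaptic event targets unknown compartment id")
  key <- paste(comp0, ev$tau_rise, ev$tau_decay, ev$erev)
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  o <- order(ev$time)
  list(comp = comp0[first],
       tau_rise = ev$tau_rise[first], tau_decay = ev$tau_decay[first],
       erev = ev$erev[first],
       ev_group = grp[o] - 1L, ev_time = ev$time[o],
       ev_weight = ev$gmax_uS[o])
}

#' Detect spikes in a somatic voltage trace
#'
#' The trace is high-pass filtered above 300 Hz (zero-phase FIR);
#' suprathreshold excursions of the raw potential that carry high-frequency
#' energy are reduced to one event at the excursion peak, and events closer
#' than the refractory period are merged.
#'
#' @param v somatic potential, mV.
#' @param fs sampling rate, Hz (> 600, Nyquist for the 300 Hz corner).
#' @param threshold spike threshold on the raw trace, mV.
#' @param refractory minimum inter-event interval, ms.
#' @param hp_floor minimum high-passed amplitude at the peak, mV; rejects
#'   slow suprathreshold drift.
#' @return spike times in ms (sample-resolution).
#' @export
detect_spikes <- function(v, fs, threshold = 0, refractory = 2,
                          hp_floor = 1) {
  if (fs <= 600) stop("fs must exceed 600 Hz (Nyquist for the 300 Hz filter)")
  ntaps <- 65L
  if (length(v) <= 3L * ntaps)
    stop("trace shorter than filter warm-up (need > ", 3L * ntaps, " samples)")
  hp <- signal::filtfilt(signal::fir1(ntaps - 1L, 300 / (fs / 2),
                                      type = "high"), v)
  above <- v > threshold
  if (!any(above)) return(numeric(0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  peaks <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(v[seg])]
  }, integer(1))
  hp_amp <- vapply(seq_along(starts), function(i)
    max(abs(hp[starts[i]:ends[i]])), numeric(1))
  peaks <- peaks[hp_amp > hp_floor]
  if (!length(peaks)) return(numeric(0))
  times <- (peaks - 1L) / fs * 1000
  keep <- c(TRUE, diff(times) >= refractory)
  # iterate: merging can bring later events inside the refractory window
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= refractory)
  }
  times
}

#' Find the rheobase of a cell by a somatic current sweep
#'
#' Smallest step amplitude (to `resolution` nA) eliciting at least one
#' somatic spike during a `duration`-ms step.
#'
#' @param cell a `ca1_cell`.
#' @param max_nA sweep upper bound, nA.
#' @param resolution sweep resolution, nA.
#' @param duration step length, ms.
#' @param dt integration step, ms.
#' @return rheobase in nA (`NA` if no spike up to `max_nA`).
#' @export
find_rheobase <- function(cell, max_nA = 2, resolution = 0.05,
                          duration = 300, dt = 0.025) {
  soma_id <- cell$compartments$id[cell$compartments$section == "soma"][1]
  lo <- 0; hi <- NA
  for (amp in seq(resolution, max_nA, by = resolution)) {
    tr <- hh_integrate(cell, list(steps = data.frame(
      compartment = soma_id, t0 = 50, t1 = 50 + duration, amp_nA = amp)),
      duration = duration + 100, dt = dt, record = "soma")
    if (length(detect_spikes(tr$v[, "soma"], tr$fs))) { hi <- amp; break }
  }
  hi
}
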