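## Synthetic-data generators: LFP with planted theta/tSC structure,
## phase-locked spike trains, and feature tables with planted
## feature-to-phase effects. Every generator is a pure function of its seed.

#' von Mises random angles (degrees)
#'
#' Best-Fisher rejection sampling; `kappa = 0` gives the circular uniform.
#'
#' @param n sample size.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, 0, 360))
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
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f) * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

#' Spectrally shaped 1/f ("pink") noise
#'
#' Gaussian noise with power spectral density proportional to
#' `1/f^exponent`.
#'
#' @param n samples.
#' @param exponent spectral exponent (default 1).
#' @export
pink_noise <- function(n, exponent = 1) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec))[-1] else Conj(rev(spec)))
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

#' Plan for a synthetic LFP recording
#'
#' Defaults emulate a hippocampal theta epoch: an 8 Hz carrier with the
#' four nested spectral burst classes over 1/f background noise. Burst
#' classes follow the tSC signatures (center frequency, theta-phase
#' position); `proportion` is the fraction of cycles carrying each class.
#'
#' @param duration_s recording length, s.
#' @param fs sampling rate, Hz.
#' @param theta_freq,theta_amp carrier frequency (Hz) and amplitude.
#' @param tsc data.frame: class, freq (Hz), phase (deg), amp, proportion.
#' @param noise 1/f noise amplitude (standard deviations).
#' @param seed integer seed.
#' @export
lfp_plan <- function(duration_s = 60, fs = 1000, theta_freq = 8,
                     theta_amp = 1,
                     tsc = data.frame(
                       class = c("tSC1", "tSC2", "tSC3", "tSC4"),
                       freq = c(16, 35, 55, 80),
                       phase = c(180, 250, 180, 180),
                       amp = c(0.45, 0.45, 0.45, 0.45),
                       proportion = c(0.2, 0.2, 0.2, 0.2)),
                     noise = 0.15, seed = 1) {
  stopifnot(duration_s > 0, fs > 0, theta_freq > 0)
  if (sum(tsc$proportion) > 1) stop("tSC proportions must sum to <= 1")
  if (any(tsc$freq <= 4) || any(tsc$freq >= fs / 2))
    stop("tSC bands must lie within (4, fs/2)")
  structure(list(duration_s = duration_s, fs = fs, theta_freq = theta_freq,
                 theta_amp = theta_amp, tsc = tsc, noise = noise,
                 seed = seed), class = "lfp_plan")
}

#' Generate a synthetic LFP with ground-truth cycle classes
#'
#' Theta carrier `-cos` (troughs at cycle starts), plus one
#' Gaussian-windowed burst per labeled cycle at the class's frequency and
#' phase position, over 1/f noise. The ground-truth class of every cycle is
#' returned.
#'
#' @param plan an [lfp_plan()].
#' @return list: `lfp`, `fs`, `t` (s), and `cycles` (cycle, start_s,
#'   trough_s, class).
#' @export
generate_lfp <- function(plan = lfp_plan()) {
  stopifnot(inherits(plan, "lfp_plan"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(plan$seed)

  n <- round(plan$duration_s * plan$fs)
  t <- (seq_len(n) - 1) / plan$fs
  period <- 1 / plan$theta_freq
  lfp <- -plan$theta_amp * cos(2 * pi * plan$theta_freq * t)

  n_cycles <- floor(plan$duration_s * plan$theta_freq)
  probs <- c(plan$tsc$proportion, 1 - sum(plan$tsc$proportion))
  classes <- sample(c(plan$tsc$class, "none"), n_cycles, replace = TRUE,
                    prob = probs)

  for (ci in seq_len(n_cycles)) {
    if (classes[ci] == "none") next
    row <- plan$tsc[plan$tsc$class == classes[ci], ]
    center <- (ci - 1 + row$phase / 360) * period
    sigma <- 1.2 / row$freq
    mask <- abs(t - center) < 4 * sigma
    lfp[mask] <- lfp[mask] + row$amp *
      cos(2 * pi * row$freq * (t[mask] - center)) *
      exp(-(t[mask] - center)^2 / (2 * sigma^2))
  }
  if (plan$noise > 0) lfp <- lfp + plan$noise * pink_noise(n)

  list(lfp = lfp, fs = plan$fs, t = t,
       cycles = data.frame(cycle = seq_len(n_cycles),
                           start_s = (seq_len(n_cycles) - 1) * period,
                           trough_s = (seq_len(n_cycles) - 1) * period,
                           class = classes))
}

#' Generate phase-locked spike trains for a population of units
#'
#' Per cycle and unit the spike count is Poisson at
#' `rate / theta_freq`; spike phases are von Mises around the unit's
#' preferred phase (`kappa = 0` gives uniform phases).
#'
#' @param units data.frame: unit, rate (Hz), phase_mu (deg), kappa, and
#'   optionally sublayer.
#' @param cycles cycle table as from [generate_lfp()] (columns cycle,
#'   start_s) or an integer cycle count.
#' @param theta_freq theta frequency, Hz.
#' @param seed integer seed.
#' @return data.frame: unit, cycle, phase (deg), time (s).
#' @export
generate_spike_trains <- function(units, cycles, theta_freq = 8, seed = 1) {
  stopifnot(all(c("unit", "rate", "phase_mu", "kappa") %in% names(units)))
  if (any(units$rate < 0)) stop("rates must be >= 0")
  if (is.numeric(cycles) && length(cycles) == 1L)
    cycles <- data.frame(cycle = seq_len(cycles),
                         start_s = (seq_len(cycles) - 1) / theta_freq)
  if (!nrow(cycles)) stop("cycle table is empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  period <- 1 / theta_freq
  out <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    counts <- rpois(nrow(cycles), u$rate / theta_freq)
    total <- sum(counts)
    if (!total) next
    ph <- rvonmises(total, u$phase_mu, u$kappa)
    cyc <- rep(cycles$cycle, counts)
    start <- rep(cycles$start_s, counts)
    out[[i]] <- data.frame(unit = u$unit, cycle = cyc, phase = ph,
                           time = start + ph / 360 * period)
  }
  if (!length(out))
    return(data.frame(unit = character(), cycle = integer(),
                      phase = numeric(), time = numeric()))
  res <- do.call(rbind, out)
  res[order(res$time), , drop = FALSE]
}

#' Generate a synthetic feature table with planted phase effects
#'
#' All features are i.i.d. standard normal; the response phase of each cell
#' is a von Mises draw around a base direction shifted by the planted
#' features: `mu_i = base + sum_j shift_j * x_ij`. Unplanted features carry
#' no information by construction.
#'
#' @param n_cells number of rows.
#' @param planted data.frame: feature, shift (degrees per standard
#'   deviation), or `NULL` for a pure-noise table.
#' @param base_phase base preferred direction, degrees.
#' @param kappa response concentration around the planted direction.
#' @param seed integer seed.
#' @return list: `features` (n x length(ca1_feature_names()) data.frame),
#'   `phase` (degrees), `planted`.
#' @export
generate_feature_table <- function(n_cells = 731, planted = NULL,
                                   base_phase = 90, kappa = 8, seed = 1) {
  nm <- ca1_feature_names()
  if (!is.null(planted)) {
    bad <- setdiff(planted$feature, nm)
    if (length(bad))
      stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- matrix(rnorm(n_cells * length(nm)), n_cells, length(nm),
              dimnames = list(NULL, nm))
  mu <- rep(base_phase, n_cells)
  if (!is.null(planted))
    for (j in seq_len(nrow(planted)))
      mu <- mu + planted$shift[j] * X[, planted$feature[j]]
  phase <- vapply(mu, function(m) rvonmises(1, m, kappa), numeric(1))
  list(features = as.data.frame(X, check.names = FALSE), phase = phase,
       planted = planted)
}

#' Write / read an LFP as flat binary with a JSON header
#'
#' The signal is stored as little-endian float32 in `<path>.dat` with a
#' JSON sidecar `<path>.json` holding the sampling rate and channel map.
#'
#' @param lfp numeric vector (one channel).
#' @param fs sampling rate, Hz.
#' @param path base path (without extension).
#' @param channel_name role of the channel in the header.
#' @export
write_lfp <- function(lfp, fs, path, channel_name = "SLM") {
  writeBin(as.numeric(lfp), paste0(path, ".dat"), size = 4,
           endian = "little")
  writeLines(jsonlite::toJSON(list(fs = fs, n_channels = 1L,
                                   dtype = "float32",
                                   channels = channel_name),
                              auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  sz <- file.info(paste0(path, ".dat"))$size
  x <- readBin(paste0(path, ".dat"), "numeric", n = sz / 4, size = 4,
               endian = "little")
  list(lfp = x, fs = as.numeric(hdr$fs), header = hdr)
}
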