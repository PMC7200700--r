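## Theta-cycle detection from LFP and unsupervised classification of cycle
## waveforms into theta-nested spectral component (tSC) classes.

#' Detect theta cycles in an LFP trace
#'
#' The signal is band-filtered at 4-12 Hz with a forward-backward
#' (zero-phase) FIR filter. Troughs are detected as local minima and
#' validated when flanked on both sides by peaks of at least
#' `peak_fraction` of the trough magnitude at a lag consistent with the
#' oscillation's own spectral period. Cycles run trough-to-trough, so the
#' cycle phase convention (trough 0, peak 180) holds within each cycle.
#'
#' @param lfp numeric vector.
#' @param fs sampling rate, Hz (>= 250).
#' @param band theta band, Hz.
#' @param peak_fraction flanking-peak validation threshold.
#' @param lag_fraction maximum flanking-peak lag, as a fraction of the
#'   spectral period.
#' @param min_trough minimum trough magnitude as a fraction of the raw
#'   signal's standard deviation; screens out narrowband filter ringing
#'   when no genuine theta oscillation is present. Scale-invariant.
#' @return object of class `theta_cycles`: data.frame `cycles` (start,
#'   trough, end sample indices; duration s; class, initialized "unlabeled"),
#'   the filtered signal and parameters.
#' @export
detect_theta_cycles <- function(lfp, fs, band = c(4, 12),
                                peak_fraction = 0.5, lag_fraction = 0.6,
                                min_trough = 0.5) {
  if (fs < 250) stop("fs must be >= 250 Hz")
  if (length(lfp) < 2 * fs) stop("need at least 2 s of LFP")
  if (sd(lfp) == 0)
    return(structure(list(cycles = data.frame(
      start = integer(), trough = integer(), end = integer(),
      duration = numeric(), class = character()),
      filtered = lfp * 0, fs = fs, band = band), class = "theta_cycles"))

  ntaps <- 2L * floor(fs * 0.125) + 1L   # ~250 ms zero-phase FIR
  flt <- signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, lfp)

  # dominant period from the band-filtered periodogram
  nfft <- 2^ceiling(log2(min(length(x), 8 * fs)))
  px <- Mod(fft(c(x[seq_len(min(length(x), nfft))],
                  rep(0, max(0, nfft - length(x))))))^2
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  in_band <- freqs >= band[1] & freqs <= band[2]
  f_dom <- freqs[in_band][which.max(px[in_band])]
  period <- fs / f_dom                   # samples

  d <- diff(x)
  nx <- length(x)
  minima <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  maxima <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (x[1] < x[2] && x[1] < 0) minima <- c(1L, minima)
  if (x[nx] < x[nx - 1L] && x[nx] < 0) minima <- c(minima, nx)
  floor_amp <- min_trough * sd(lfp)
  minima <- minima[x[minima] < -floor_amp]
  maxima <- maxima[x[maxima] > 0]

  # flanking peaks of sufficient magnitude within the spectral period; at
  # the signal edges a missing side is tolerated if the other validates
  lag <- lag_fraction * period
  valid <- vapply(minima, function(tr) {
    before <- maxima[maxima < tr & maxima >= tr - lag]
    after <- maxima[maxima > tr & maxima <= tr + lag]
    ok_before <- length(before) > 0 &&
      max(x[before]) >= peak_fraction * abs(x[tr])
    ok_after <- length(after) > 0 &&
      max(x[after]) >= peak_fraction * abs(x[tr])
    edge_before <- tr - lag < 1
    edge_after <- tr + lag > nx
    (ok_before || (edge_before && ok_after)) &&
      (ok_after || (edge_after && ok_before))
  }, logical(1))
  troughs <- minima[valid]

  if (length(troughs) < 2)
    return(structure(list(cycles = data.frame(
      start = integer(), trough = integer(), end = integer(),
      duration = numeric(), class = character()),
      filtered = x, fs = fs, band = band), class = "theta_cycles"))

  start <- troughs[-length(troughs)]
  end <- troughs[-1]
  dur <- (end - start) / fs
  keep <- dur >= 1 / band[2] & dur <= 1 / band[1]
  cycles <- data.frame(start = start[keep], trough = start[keep],
                       end = end[keep], duration = dur[keep],
                       class = "unlabeled", stringsAsFactors = FALSE)
  structure(list(cycles = cycles, filtered = x, fs = fs, band = band),
            class = "theta_cycles")
}

#' @export
print.theta_cycles <- function(x, ...) {
  cat(sprintf("theta_cycles: %d validated cycles at %.0f Hz sampling\n",
              nrow(x$cycles), x$fs))
  if (nrow(x$cycles)) print(table(x$cycles$class))
  invisible(x)
}

#' Extract fixed-length cycle waveforms
#'
#' Each detected cycle is linearly resampled to `n_samples` points spanning
#' its trough-to-trough extent (phase 0-360).
#'
#' @param cycles a `theta_cycles` object.
#' @param lfp the raw LFP the cycles were detected in.
#' @param n_samples samples per cycle (default 64).
#' @return matrix, one row per cycle.
#' @export
cycle_waveforms <- function(cycles, lfp, n_samples = 64) {
  stopifnot(inherits(cycles, "theta_cycles"))
  cc <- cycles$cycles
  out <- matrix(0, nrow(cc), n_samples)
  for (i in seq_len(nrow(cc))) {
    idx <- seq(cc$start[i], cc$end[i])
    out[i, ] <- approx(seq_along(idx), lfp[idx],
                       xout = seq(1, length(idx), length.out = n_samples))$y
  }
  out
}

#' Time-frequency signatures of cycle waveforms
#'
#' Analytic Morlet wavelet power of each cycle (10-100 Hz log-spaced,
#' coarse time bins, log-compressed). Nested spectral bursts are coupled to
#' theta phase with cycle-to-cycle jitter, so spectral signatures group
#' cycles sharing a nested component far more robustly than the raw
#' samples do.
#'
#' @param waveforms cycles x samples matrix from [cycle_waveforms()].
#' @param durations per-cycle durations in seconds.
#' @param freqs wavelet center frequencies, Hz.
#' @param n_time coarse time bins per cycle.
#' @return cycles x (freqs x n_time) feature matrix.
#' @export
cycle_signatures <- function(waveforms, durations,
                             freqs = exp(seq(log(10), log(100),
                                             length.out = 24)),
                             n_time = 16) {
  n_samp <- ncol(waveforms)
  grp <- rep(seq_len(n_time), each = ceiling(n_samp / n_time),
             length.out = n_samp)
  out <- matrix(0, nrow(waveforms), length(freqs) * n_time)
  for (i in seq_len(nrow(waveforms))) {
    x <- waveforms[i, ] - mean(waveforms[i, ])
    pw <- .morlet_power(x, n_samp / durations[i], freqs)
    tb <- vapply(seq_len(n_time), function(b)
      rowMeans(pw[, grp == b, drop = FALSE]), numeric(length(freqs)))
    out[i, ] <- log1p(as.vector(tb) * 100)
  }
  out
}

#' PCA embedding of cycle waveforms
#'
#' Retains the smallest number of principal components explaining more than
#' `var_explained` of the total variance.
#'
#' @param waveforms cycles x samples matrix (>= 20 cycles).
#' @param var_explained variance threshold (default 0.9).
#' @return list: `scores` (cycles x k), `k`, `explained`, `pca`.
#' @export
embed_cycles <- function(waveforms, var_explained = 0.9) {
  if (nrow(waveforms) < 20) stop("embedding requires >= 20 cycles")
  total_var <- sum(apply(waveforms, 2, stats::var))
  if (total_var < .Machine$double.eps) {
    warning("all cycles identical: no components retained")
    return(list(scores = matrix(0, nrow(waveforms), 0), k = 0L,
                explained = 1, pca = NULL))
  }
  pca <- prcomp(waveforms, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cumvar > var_explained)[1]
  list(scores = pca$x[, seq_len(k), drop = FALSE], k = k,
       explained = cumvar[k], pca = pca)
}

## ---- self-organizing map ----------------------------------------------------

# online-trained rectangular SOM; returns codebook and BMU assignment
.som_train <- function(scores, grid = c(8, 8), epochs = 10, seed = 1,
                       alpha = c(0.5, 0.02)) {
  n <- nrow(scores); d <- ncol(scores)
  nu <- prod(grid)
  gx <- rep(seq_len(grid[1]), grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code <- scores[sample.int(n, nu, replace = nu > n), , drop = FALSE]
  n_iter <- epochs * n
  radius0 <- max(grid) / 2
  it <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      it <- it + 1L
      frac <- it / n_iter
      a <- alpha[1] * (alpha[2] / alpha[1])^frac
      r <- max(radius0 * (0.5 / radius0)^frac, 0.5)
      x <- scores[i, ]
      dists <- rowSums(sweep(code, 2, x)^2)
      bmu <- which.min(dists)
      nb <- exp(-((gx - gx[bmu])^2 + (gy - gy[bmu])^2) / (2 * r^2))
      upd <- which(nb > 1e-3)
      # move neighborhood units toward the sample
      delta <- sweep(code[upd, , drop = FALSE], 2, x)   # code - x
      code[upd, ] <- code[upd, , drop = FALSE] - a * nb[upd] * delta
    }
  }
  bmu <- apply(scores, 1, function(x)
    which.min(rowSums(sweep(code, 2, x)^2)))
  list(codebook = code, bmu = bmu, grid = grid)
}

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the worst-case ratio of within-cluster scatter to
#' between-centroid separation; lower is better.
#'
#' @param x data matrix.
#' @param labels integer cluster labels (>= 2 clusters).
#' @export
davies_bouldin <- function(x, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("Davies-Bouldin requires >= 2 clusters")
  cent <- t(vapply(ks, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
  S <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(cent))
  db <- vapply(seq_along(ks), function(i) {
    ratios <- (S[i] + S[-i]) / M[i, -i]
    max(ratios)
  }, numeric(1))
  mean(db)
}

#' SOM classification of embedded theta cycles
#'
#' Trains a self-organizing map on the PCA scores, groups the SOM units by
#' hierarchical clustering of the codebook (the similarity structure of the
#' map), and selects the cluster count by the Davies-Bouldin index over
#' `k_range`. If no multi-cluster partition reaches `db_max`, the degenerate
#' single-cluster solution is returned.
#'
#' @param scores cycles x components matrix.
#' @param grid SOM grid dimensions.
#' @param k_range candidate cluster counts (>= 2 candidates).
#' @param db_max Davies-Bouldin acceptance ceiling for multi-cluster
#'   solutions.
#' @param seed integer seed.
#' @return list: `labels` (per cycle), `k`, `db` (index per candidate),
#'   `som`.
#' @export
som_classify <- function(scores, grid = c(8, 8), k_range = 2:6,
                         db_max = 1.2, seed = 1) {
  if (length(k_range) < 2) stop("need >= 2 candidate cluster counts")
  if (prod(grid) > nrow(scores))
    stop("SOM grid (", prod(grid), " units) larger than sample count (",
         nrow(scores), ")")
  som <- .som_train(scores, grid = grid, seed = seed)
  hc <- hclust(dist(som$codebook), method = "ward.D2")
  db <- vapply(k_range, function(k) {
    unit_lab <- cutree(hc, k)
    lab <- unit_lab[som$bmu]
    if (length(unique(lab)) < 2) return(Inf)
    davies_bouldin(scores, lab)
  }, numeric(1))
  names(db) <- k_range
  best <- which.min(db)
  if (db[best] > db_max) {
    labels <- rep(1L, nrow(scores))
    k <- 1L
  } else {
    unit_lab <- cutree(hc, k_range[best])
    labels <- unname(unit_lab[som$bmu])
    k <- length(unique(labels))
    labels <- match(labels, sort(unique(labels)))
  }
  list(labels = labels, k = k, db = db, som = som)
}

## ---- wavelet labeling -------------------------------------------------------

# analytic Morlet CWT power of a short signal at the given frequencies
.morlet_power <- function(x, fs, freqs, n_cycles = 3) {
  n <- length(x)
  out <- matrix(0, length(freqs), n)
  tgrid <- (seq_len(n) - 1) / fs
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- n_cycles / (2 * pi * f)
    half <- min(n - 1L, ceiling(4 * sigma * fs))
    tk <- (-half:half) / fs
    w <- exp(2i * pi * f * tk) * exp(-tk^2 / (2 * sigma^2))
    w <- w / sum(Mod(w))
    conv <- stats::convolve(x, Conj(rev(w)), type = "open")
    out[fi, ] <- Mod(conv[(half + 1):(half + n)])^2
  }
  dimnames(out) <- list(sprintf("%.1f", freqs), NULL)
  out
}

#' Label a cluster-mean cycle with its theta-nested spectral component
#'
#' The fundamental (theta) component is removed by regressing out one
#' sinusoidal cycle; the residual's dominant time-frequency atom (analytic
#' Morlet wavelet transform, 10-100 Hz log-spaced) is matched against the
#' four tSC signatures: tSC1 < 20 Hz at the theta peak, tSC2 30-40 Hz on
#' the falling phase, tSC3 50-60 Hz at the peak, tSC4 70-90 Hz at the peak.
#' No match returns "unlabeled".
#'
#' @param waveform one full cycle (trough-to-trough), any length >= 16.
#' @param duration cycle duration in seconds.
#' @param min_power minimum residual burst power relative to waveform
#'   variance for a label to be assigned.
#' @return one of "tSC1", "tSC2", "tSC3", "tSC4", "unlabeled".
#' @export
label_tsc <- function(waveform, duration, min_power = 0.01) {
  n <- length(waveform)
  if (n < 16) stop("waveform must hold one full cycle (>= 16 samples)")
  fs_eff <- n / duration
  phase <- (seq_len(n) - 1) / n * 360
  # remove the theta fundamental (and mean) by harmonic regression
  X <- cbind(1, cos(phase * pi / 180), sin(phase * pi / 180))
  resid <- waveform - X %*% qr.solve(X, waveform)
  if (stats::var(resid) < min_power * max(stats::var(waveform),
                                          .Machine$double.eps))
    return("unlabeled")

  freqs <- exp(seq(log(10), log(min(100, fs_eff / 2 * 0.9)), length.out = 40))
  pw <- .morlet_power(as.numeric(resid), fs_eff, freqs)
  # taper edges so boundary artifacts do not dominate
  edge <- pmin(seq_len(n), rev(seq_len(n)))
  taper <- pmin(1, edge / (n / 8))
  pw <- sweep(pw, 2, taper, `*`)
  peak <- which(pw == max(pw), arr.ind = TRUE)[1, ]
  f_star <- freqs[peak[1]]
  ph_star <- phase[peak[2]]

  at_peak <- ph_star > 90 & ph_star < 270
  falling <- ph_star > 180 & ph_star <= 330
  if (f_star < 20 && at_peak) "tSC1"
  else if (f_star >= 25 && f_star <= 45 && falling) "tSC2"
  else if (f_star >= 45 && f_star < 65 && at_peak) "tSC3"
  else if (f_star >= 65 && f_star <= 95 && at_peak) "tSC4"
  else "unlabeled"
}

#' End-to-end classification of theta cycles into tSC classes
#'
#' Detects cycles, embeds their waveforms (PCA > 90% variance), clusters
#' with the SOM / Davies-Bouldin pipeline and labels every cluster by the
#' wavelet signature of its mean waveform.
#'
#' @inheritParams detect_theta_cycles
#' @inheritParams som_classify
#' @param n_samples waveform resampling length.
#' @param features `"spectral"` embeds each cycle's wavelet time-frequency
#'   signature (robust to cycle-to-cycle burst-phase jitter, the default);
#'   `"waveform"` embeds the raw resampled samples.
#' @return a `theta_cycles` object with per-cycle `class` labels, plus
#'   attributes `cluster` (raw SOM cluster per cycle) and `cluster_label`.
#' @export
classify_theta_cycles <- function(lfp, fs, band = c(4, 12), grid = c(8, 8),
                                  k_range = 2:6, n_samples = 64,
                                  features = c("spectral", "waveform"),
                                  seed = 1) {
  features <- match.arg(features)
  cyc <- detect_theta_cycles(lfp, fs, band = band)
  if (nrow(cyc$cycles) < 20) {
    warning("fewer than 20 cycles detected: no classification performed")
    return(cyc)
  }
  wf <- cycle_waveforms(cyc, lfp, n_samples = n_samples)
  emb <- embed_cycles(if (features == "spectral")
    cycle_signatures(wf, cyc$cycles$duration) else wf)
  if (emb$k == 0L) return(cyc)
  cl <- som_classify(emb$scores, grid = grid, k_range = k_range, seed = seed)
  lab <- vapply(seq_len(cl$k), function(k) {
    label_tsc(colMeans(wf[cl$labels == k, , drop = FALSE]),
              duration = median(cyc$cycles$duration[cl$labels == k]))
  }, character(1))
  cyc$cycles$class <- lab[cl$labels]
  attr(cyc, "cluster") <- cl$labels
  attr(cyc, "cluster_label") <- lab
  cyc
}
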