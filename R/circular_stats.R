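## Circular phase-locking statistics. Phases are in degrees under the
## trough-0/peak-180 convention: the theta trough is 0 (== 360) degrees and
## the peak 180 degrees.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Phase histogram over the theta cycle
#'
#' Counts spike phases in `n_bins` equal bins; bin 1 starts at 0 degrees.
#'
#' @param phi phases in degrees (wrapped internally to \[0, 360)).
#' @param n_bins number of bins (default 25, the per-cycle resolution used
#'   throughout the analyses).
#' @return integer vector of counts (sums to `length(phi)`), with bin lower
#'   edges as names.
#' @export
phase_histogram <- function(phi, n_bins = 25) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  phi <- phi %% 360
  idx <- pmin(floor(phi / (360 / n_bins)) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- sprintf("%.1f", (seq_len(n_bins) - 1L) * 360 / n_bins)
  counts
}

#' Mean resultant vector of circular data
#'
#' @param phi phases in degrees, n >= 1.
#' @return list with `R` (mean vector length in \[0, 1\]), `mu` (preferred
#'   phase in \[0, 360)) and `n`.
#' @export
mean_vector <- function(phi) {
  if (!length(phi)) stop("mean_vector requires at least one phase")
  a <- .deg2rad(phi)
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  mu <- .rad2deg(atan2(S, C)) %% 360
  list(R = min(R, 1), mu = mu, n = length(phi))
}

#' Rayleigh test of circular uniformity
#'
#' Standard Rayleigh approximation: `Z = n R^2` with the finite-sample
#' series correction.
#'
#' @param phi phases in degrees, n >= 4.
#' @return list with `p`, `Z`, `R`, `n`.
#' @export
rayleigh_test <- function(phi) {
  n <- length(phi)
  if (n < 4) stop("rayleigh_test requires n >= 4")
  R <- mean_vector(phi)$R
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(p = min(max(p, 0), 1), Z = Z, R = R, n = n)
}

#' Trough-peak preference index
#'
#' `TP = (n_trough - n_peak) / (n_trough + n_peak)` with the trough window
#' \[270, 360) U \[0, 90) and peak window \[90, 270): +1 for pure trough
#' (superficial-like) firing, -1 for pure peak (deep-like) firing.
#'
#' @param phi phases in degrees, n >= 1.
#' @export
tp_index <- function(phi) {
  if (!length(phi)) stop("tp_index requires at least one phase")
  phi <- phi %% 360
  trough <- phi < 90 | phi >= 270
  (sum(trough) - sum(!trough)) / length(phi)
}

# maximum-likelihood-style kappa estimate from a mean resultant length
.circ_kappa <- function(Rbar, n = Inf) {
  kappa <- if (Rbar < 0.53) 2 * Rbar + Rbar^3 + 5 * Rbar^5 / 6
  else if (Rbar < 0.85) -0.4 + 1.39 * Rbar + 0.43 / (1 - Rbar)
  else 1 / (Rbar^3 - 4 * Rbar^2 + 3 * Rbar)
  if (is.finite(n) && n < 15 && n > 1) {
    kappa <- if (kappa < 2) max(kappa - 2 / (n * kappa), 0)
    else kappa * (n - 1)^3 / (n^3 + n)
  }
  kappa
}

#' Watson-Williams multi-sample test (circular one-way ANOVA)
#'
#' Tests equality of mean directions across k groups under a shared-
#' concentration von Mises assumption. A warning is issued when the pooled
#' mean resultant length is below 0.45 (the F approximation degrades).
#'
#' @param groups list of >= 2 numeric vectors of phases in degrees, each of
#'   length >= 5.
#' @return list with `F`, `df1`, `df2`, `p`, `kappa`.
#' @export
watson_williams <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("watson_williams requires a list of >= 2 groups")
  ni <- lengths(groups)
  if (any(ni < 5)) stop("each group requires n >= 5")
  k <- length(groups)
  N <- sum(ni)
  Ri <- vapply(groups, function(g) mean_vector(g)$R * length(g), numeric(1))
  all_phi <- unlist(groups)
  R <- mean_vector(all_phi)$R * N
  rw <- sum(Ri) / N
  if (rw < 0.45)
    warning("mean resultant length ", round(rw, 2),
            " < 0.45: Watson-Williams F approximation is unreliable")
  kappa <- .circ_kappa(rw)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  df1 <- k - 1; df2 <- N - k
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = df1, df2 = df2, p = p, kappa = kappa)
}

#' Harrison-Kanji test (circular two-way ANOVA)
#'
#' Two-factor analysis of circular data with interaction. For concentrated
#' data (kappa > 2) an F-table with the Stephens correction is used; for
#' dispersed data the chi-squared approximation.
#'
#' @param phi phases in degrees.
#' @param factorA,factorB factor labels (>= 2 levels each); every cell of
#'   the A x B design must be non-empty.
#' @return data.frame with one row per effect (A, B, interaction):
#'   statistic, df, p, plus attribute `kappa`.
#' @export
harrison_kanji <- function(phi, factorA, factorB) {
  fa <- as.factor(factorA); fb <- as.factor(factorB)
  stopifnot(length(phi) == length(fa), length(phi) == length(fb))
  p_lev <- nlevels(fa); q_lev <- nlevels(fb)
  if (p_lev < 2 || q_lev < 2) stop("each factor requires >= 2 levels")
  cn <- table(fa, fb)
  if (any(cn == 0)) {
    empty <- which(cn == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", levels(fa)[empty[1]], " x ",
         levels(fb)[empty[2]])
  }
  n <- length(phi)
  resultant <- function(x) mean_vector(x)$R * length(x)
  tr <- resultant(phi)
  kk <- .circ_kappa(tr / n, n)

  cr_a <- vapply(levels(fa), function(l) resultant(phi[fa == l]), numeric(1))
  cr_b <- vapply(levels(fb), function(l) resultant(phi[fb == l]), numeric(1))
  cg <- matrix(0, p_lev, q_lev)
  for (i in seq_len(p_lev)) for (j in seq_len(q_lev))
    cg[i, j] <- resultant(phi[fa == levels(fa)[i] & fb == levels(fb)[j]])

  na <- rowSums(cn); nb <- colSums(cn)
  eff_a <- sum(cr_a^2 / na) - tr^2 / n
  eff_b <- sum(cr_b^2 / nb) - tr^2 / n
  eff_t <- sum(cg^2 / cn) - tr^2 / n
  eff_i <- eff_t - eff_a - eff_b
  eff_r <- n - sum(cg^2 / cn)
  df_a <- p_lev - 1; df_b <- q_lev - 1
  df_i <- df_a * df_b; df_r <- n - p_lev * q_lev

  if (kk > 2) {
    beta <- 1 / (1 - 1 / (5 * kk) - 1 / (10 * kk^2))
    ms_r <- eff_r / df_r
    Fs <- beta * c(eff_a / df_a, eff_b / df_b, eff_i / df_i) / ms_r
    pv <- pf(Fs, c(df_a, df_b, df_i), df_r, lower.tail = FALSE)
    out <- data.frame(effect = c("A", "B", "interaction"), statistic = Fs,
                      df1 = c(df_a, df_b, df_i), df2 = df_r, p = pv)
  } else {
    rr <- besselI(kk, 1) / besselI(kk, 0)
    f <- 2 / (1 - rr^2)
    chis <- f * c(eff_a, eff_b, eff_i)
    pv <- pchisq(chis, c(df_a, df_b, df_i), lower.tail = FALSE)
    out <- data.frame(effect = c("A", "B", "interaction"), statistic = chis,
                      df1 = c(df_a, df_b, df_i), df2 = NA_real_, p = pv)
  }
  attr(out, "kappa") <- kk
  out
}

#' Surrogate test of theta modulation
#'
#' Compares a cell's phase-locking statistics (mean vector length R and TP
#' index) against surrogates that randomize the cell's firing rate across
#' cycles: per-cycle spike counts are permuted over cycle identities and the
#' corresponding spike phases are redrawn (`method = "redraw"`: uniformly
#' over the cycle; `method = "permute_counts"`: resampled from the cell's
#' own pooled phases).
#'
#' @param cycle_phases list of numeric vectors: spike phases (degrees) per
#'   theta cycle. Needs >= 10 cycles containing spikes and >= 2 spikes total.
#' @param n_surrogates number of surrogates (default 1000).
#' @param alpha significance level.
#' @param method surrogate construction (see above).
#' @param seed integer seed.
#' @return list: `significant` (R exceeds the 1-alpha surrogate quantile),
#'   `p_R`, `p_TP` (two-sided), observed `R` and `TP`, and the surrogate
#'   distributions.
#' @export
surrogate_modulation_test <- function(cycle_phases, n_surrogates = 1000,
                                      alpha = 0.05,
                                      method = c("redraw", "permute_counts"),
                                      seed = 1) {
  method <- match.arg(method)
  if (!is.list(cycle_phases)) stop("cycle_phases must be a list (one entry per cycle)")
  counts <- lengths(cycle_phases)
  if (sum(counts > 0) < 10)
    stop("surrogate test requires >= 10 cycles with spikes (got ",
         sum(counts > 0), ")")
  pooled <- unlist(cycle_phases)
  n <- length(pooled)
  if (n < 2) stop("surrogate test requires >= 2 spikes in total")
  obs_R <- mean_vector(pooled)$R
  obs_TP <- tp_index(pooled)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # count permutation leaves the total n unchanged; phases are redrawn, so
  # surrogate statistics can be computed on n draws per surrogate
  sur_R <- numeric(n_surrogates)
  sur_TP <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    ph <- if (method == "redraw") runif(n, 0, 360)
    else sample(pooled, n, replace = TRUE)
    a <- ph * pi / 180
    sur_R[s] <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
    sur_TP[s] <- tp_index(ph)
  }
  p_R <- (sum(sur_R >= obs_R) + 1) / (n_surrogates + 1)
  p_TP <- (sum(abs(sur_TP) >= abs(obs_TP)) + 1) / (n_surrogates + 1)
  list(significant = obs_R > quantile(sur_R, 1 - alpha),
       p_R = p_R, p_TP = p_TP, R = obs_R, TP = obs_TP,
       surrogate_R = sur_R, surrogate_TP = sur_TP, alpha = alpha)
}

#' Circular-circular correlation
#'
#' Jammalamadaka-SenGupta correlation coefficient between two samples of
#' angles.
#'
#' @param a,b paired angles in degrees.
#' @export
circ_corr <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ar <- .deg2rad(a); br <- .deg2rad(b)
  am <- atan2(mean(sin(ar)), mean(cos(ar)))
  bm <- atan2(mean(sin(br)), mean(cos(br)))
  num <- sum(sin(ar - am) * sin(br - bm))
  den <- sqrt(sum(sin(ar - am)^2) * sum(sin(br - bm)^2))
  if (den == 0) return(0)
  num / den
}

#' Assign spike times to theta phases against a sinusoidal reference
#'
#' For simulations the reference is `-cos(2 pi f t)`: troughs at cycle
#' starts, so phase = (360 f t) mod 360 with trough 0 and peak 180.
#'
#' @param times spike times, ms.
#' @param theta_freq theta frequency, Hz.
#' @return phases in degrees and cycle indices (1-based).
#' @export
spike_phases <- function(times, theta_freq = 8) {
  period <- 1000 / theta_freq
  data.frame(time = times,
             phase = (times / period * 360) %% 360,
             cycle = as.integer(floor(times / period)) + 1L)
}
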