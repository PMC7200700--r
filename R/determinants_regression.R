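## Multinomial logistic-regression analysis of the determinants of theta
## phase preference: morphological, intrinsic and synaptic features of
## synthetic cells against their 30-degree-binned preferred phase.

#' Canonical feature names of the determinant analysis
#'
#' Per input pathway: GA factor (`_F`), original conductance (`_G`), final
#' conductance (`_F*G`), bouton count (`_B`), input frequency (`_Freq`) and
#' input phase (`_Ph`); per intrinsic channel class (and the axial
#' resistance): GA factor and mean original conductance; plus the three
#' branch counts (nBrApic, nBrBasal, nBrTotal).
#'
#' @return character vector of feature names.
#' @export
ca1_feature_names <- function() {
  pathways <- c("CA3", "CA2", "EC3", "EC2", "Axo", "Bis", "CCK", "Ivy",
                "NGF", "OL-M", "PV", "SCA")
  suffixes <- c("_F", "_G", "_F*G", "_B", "_Freq", "_Ph")
  chans <- c("iNa", "iA", "iAHPs", "iC", "iKDR", "iM", "iCa", "HCN", "L", "Ra")
  c(as.vector(t(outer(pathways, suffixes, paste0))),
    as.vector(t(outer(chans, c("_F", "_Gmean"), paste0))),
    "nBrApic", "nBrBasal", "nBrTotal")
}

#' Bin a preferred phase into one of twelve 30-degree bins
#'
#' `bin = floor(mod(phase, 360) / 30) + 1`.
#'
#' @param phi phase in degrees (vectorized).
#' @export
bin_phase <- function(phi) {
  if (any(!is.finite(phi))) stop("phase must be finite")
  as.integer(floor((phi %% 360) / 30)) + 1L
}

# bin-center phases, degrees
.bin_centers <- function() (seq_len(12) - 1) * 30 + 15

#' Fit the multinomial phase-determinant model
#'
#' Features are standardized internally and fitted against the 30-degree
#' phase bin with a quasi-Newton multinomial logistic regression
#' ([nnet::multinom]). Coefficients are re-expressed as a full 12 x p map
#' under the sum-to-zero (softmax) normalization, so a positive coefficient
#' means that increasing the feature favors that phase bin.
#'
#' @param features data.frame or matrix of numeric features (rows = cells).
#' @param phase preferred phase per cell, degrees.
#' @param maxit optimizer iteration cap.
#' @param tol convergence tolerance passed to the optimizer (`reltol`).
#' @param decay L2 (ridge) penalty on the standardized coefficients; keeps
#'   the near-saturated 12-bin model identified while preserving the
#'   predicted contrasts the importance analysis relies on.
#' @return object of class `phase_determinants`: `coef` (12 x p matrix),
#'   the fitted probabilities, per-bin counts, feature scaling, and the
#'   underlying fit.
#' @export
fit_multinomial <- function(features, phase, maxit = 300, tol = 1e-10,
                            decay = 0.1) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  if (nrow(X) != length(phase)) stop("features and phase lengths differ")
  if (any(!is.finite(X))) stop("features must be finite")
  bins <- factor(bin_phase(phase), levels = 1:12)
  small <- table(bins)
  if (any(small > 0 & small < 5))
    warning("phase bins with fewer than 5 cells: ",
            paste(names(small)[small > 0 & small < 5], collapse = ", "))

  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  df <- data.frame(.bin = bins, Xs, check.names = FALSE)

  fit <- nnet::multinom(.bin ~ ., data = df, maxit = maxit,
                        MaxNWts = 1e5, reltol = tol, decay = decay,
                        trace = FALSE)
  co <- coef(fit)   # (K-1) x (p+1), relative to the reference bin
  present <- levels(droplevels(bins))
  full <- matrix(0, 12, ncol(co),
                 dimnames = list(NULL, colnames(co)))
  full[as.integer(present[-1]), ] <- co
  # sum-to-zero normalization over the occupied bins
  occ <- as.integer(present)
  full[occ, ] <- sweep(full[occ, , drop = FALSE], 2,
                       colMeans(full[occ, , drop = FALSE]))
  cmap <- full[, -1, drop = FALSE]   # drop intercept
  colnames(cmap) <- colnames(Xs)

  probs <- .softmax_probs(Xs, full, occ)
  structure(list(coef = cmap, intercept = full[, 1], occupied = occ,
                 probs = probs, bins = as.integer(as.character(bins)),
                 phase = phase %% 360,
                 n = nrow(X), center = mu, scale = sdv,
                 deviance = fit$deviance, fit = fit,
                 Xs = Xs), class = "phase_determinants")
}

.softmax_probs <- function(Xs, full, occ) {
  eta <- cbind(1, Xs) %*% t(full[occ, , drop = FALSE])
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  colnames(p) <- occ
  p
}

#' @export
print.phase_determinants <- function(x, ...) {
  cat(sprintf("phase_determinants: %d cells, %d features, %d occupied bins\n",
              x$n, ncol(x$coef), length(x$occupied)))
  cat(sprintf("  residual deviance: %.1f\n", x$deviance))
  invisible(x)
}

#' @export
coef.phase_determinants <- function(object, ...) object$coef

#' Per-feature circular significance
#'
#' Tests whether a feature carries phase information with the Mardia
#' circular-linear correlation between the feature values and the cells'
#' preferred phases (`n R^2` compared against a chi-squared distribution
#' with 2 degrees of freedom). The positive parts of the feature's 12 bin
#' coefficients, read as weights on the bin-center phases, summarize the
#' direction of the effect (`resultant`, `mu`); phase bins are few and
#' mutually dependent, so the phase attribution is descriptive while the
#' significance comes from the per-cell correlation.
#'
#' @param fit a `phase_determinants` object.
#' @param n_perm unused, kept for call compatibility.
#' @param seed unused, kept for call compatibility.
#' @return data.frame: feature, circular-linear `r2`, `resultant`,
#'   preferred phase `mu`, p.
#' @export
feature_phase_significance <- function(fit, n_perm = NULL, seed = NULL) {
  stopifnot(inherits(fit, "phase_determinants"))
  a <- fit$phase * pi / 180
  ca <- cos(a); sa <- sin(a)
  rcs <- cor(ca, sa)
  centers <- .bin_centers() * pi / 180
  cosb <- cos(centers); sinb <- sin(centers)

  p <- ncol(fit$coef)
  out <- data.frame(feature = colnames(fit$coef), r2 = NA_real_,
                    resultant = NA_real_, mu = NA_real_, p = NA_real_)
  for (j in seq_len(p)) {
    x <- fit$Xs[, j]
    rxc <- cor(x, ca); rxs <- cor(x, sa)
    r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
    out$r2[j] <- r2
    out$p[j] <- pchisq(fit$n * r2, 2, lower.tail = FALSE)
    w <- pmax(fit$coef[, j], 0)
    if (sum(w) > 0) {
      out$resultant[j] <- sqrt(sum(w * cosb)^2 + sum(w * sinb)^2) / sum(w)
      out$mu[j] <- (atan2(sum(w * sinb), sum(w * cosb)) * 180 / pi) %% 360
    } else out$resultant[j] <- 0
  }
  out
}

#' Per-bin variance explained by each feature
#'
#' Permutation importance on the multinomial deviance, resolved by phase
#' bin: for every feature the column is permuted (`n_perm` times, averaged)
#' and the increase of the per-bin deviance is expressed as a fraction of
#' that bin's deviance under the permuted model.
#'
#' @param fit a `phase_determinants` object.
#' @param n_perm permutations averaged per feature (averaging stabilizes
#'   the per-bin fractions near the selection threshold).
#' @param seed integer seed.
#' @return features x 12 matrix of variance-explained fractions in \[0, 1\].
#' @export
bin_variance_explained <- function(fit, n_perm = 8, seed = 1) {
  stopifnot(inherits(fit, "phase_determinants"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  full <- cbind(fit$intercept, fit$coef)
  occ <- fit$occupied
  bins <- fit$bins
  n <- fit$n

  bin_dev <- function(probs) {
    # -2 log-likelihood contribution of the observations in each bin
    pick <- probs[cbind(seq_len(n), match(bins, as.integer(colnames(probs))))]
    pick <- pmax(pick, 1e-12)
    d <- -2 * log(pick)
    vapply(1:12, function(b) sum(d[bins == b]), numeric(1))
  }
  d_fit <- bin_dev(fit$probs)

  p <- ncol(fit$coef)
  ve <- matrix(0, p, 12, dimnames = list(colnames(fit$coef), NULL))
  for (j in seq_len(p)) {
    d_perm <- matrix(0, n_perm, 12)
    for (k in seq_len(n_perm)) {
      Xp <- fit$Xs
      Xp[, j] <- Xp[sample.int(n), j]
      d_perm[k, ] <- bin_dev(.softmax_probs(Xp, full, occ))
    }
    dp <- colMeans(d_perm)
    ve[j, ] <- pmin(pmax((dp - d_fit) / pmax(dp, 1e-12), 0), 1)
  }
  ve
}

#' Select contributing features
#'
#' A feature-direction (up = positive coefficients, down = negative) is a
#' significant contributor when its per-bin variance explained reaches
#' `var_threshold` in at least `run_length` consecutive 30-degree bins
#' (circular adjacency) on bins where the direction's coefficient is
#' active.
#'
#' @param fit a `phase_determinants` object.
#' @param ve variance-explained matrix from [bin_variance_explained()]
#'   (computed if missing).
#' @param var_threshold per-bin variance threshold (default 0.20).
#' @param run_length required consecutive bins (default 3).
#' @param ... passed to [bin_variance_explained()].
#' @return data.frame: feature, direction, max run length, selected flag.
#' @export
select_contributors <- function(fit, ve = NULL, var_threshold = 0.20,
                                run_length = 3, ...) {
  stopifnot(inherits(fit, "phase_determinants"))
  if (is.null(ve)) ve <- bin_variance_explained(fit, ...)
  circ_run <- function(ok) {
    if (all(ok)) return(length(ok))
    if (!any(ok)) return(0L)
    r <- rle(c(ok, ok))$lengths[c(rle(c(ok, ok))$values)]
    min(max(r), length(ok))
  }
  rows <- list()
  for (j in seq_len(ncol(fit$coef))) {
    for (dir in c("up", "down")) {
      act <- if (dir == "up") fit$coef[, j] > 0 else fit$coef[, j] < 0
      ok <- ve[j, ] >= var_threshold & act
      run <- circ_run(ok)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(fit$coef)[j], direction = dir,
        run = run, selected = run >= run_length)
    }
  }
  do.call(rbind, rows)
}

#' Full determinant analysis
#'
#' Fits the multinomial model, filters features by circular significance
#' (`p < p_threshold`) and applies the variance/run selection among the
#' significant ones.
#'
#' @inheritParams fit_multinomial
#' @param p_threshold Rayleigh-style significance cutoff (default 0.001).
#' @param var_threshold,run_length selection rule parameters.
#' @param n_perm_sig,n_perm_ve permutation counts.
#' @param seed integer seed.
#' @return list: `fit`, `significance`, `variance_explained`, `selection`,
#'   and `selected` (character vector of selected feature names).
#' @export
phase_determinants <- function(features, phase, p_threshold = 0.001,
                               var_threshold = 0.20, run_length = 3,
                               n_perm_sig = 1000, n_perm_ve = 8, seed = 1) {
  fit <- fit_multinomial(features, phase)
  sig <- feature_phase_significance(fit)
  ve <- bin_variance_explained(fit, n_perm = n_perm_ve, seed = seed)
  sel <- select_contributors(fit, ve = ve, var_threshold = var_threshold,
                             run_length = run_length)
  sig_features <- sig$feature[sig$p < p_threshold]
  selected <- unique(sel$feature[sel$selected & sel$feature %in% sig_features])
  list(fit = fit, significance = sig, variance_explained = ve,
       selection = sel, selected = selected)
}
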