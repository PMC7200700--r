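## Rank-order test: identifies theta cycles whose multi-unit firing order
## repeats across cycles more often than expected by chance.

#' Normalized first-spike ranks for one cycle
#'
#' Only the first spike of each unit in the cycle is considered; with k
#' participating units the chronological positions are mapped to the grid
#' 0, 1/(k-1), ..., 1. Exact ties are broken deterministically by unit id
#' (flagged via the `ties` attribute).
#'
#' @param cycle_spikes named list: unit -> spike times within the cycle.
#' @param min_units minimum participating units (default 4); below it the
#'   cycle is excluded and `NULL` is returned.
#' @return named numeric vector of ranks in \[0, 1\], or `NULL`.
#' @export
rank_vector <- function(cycle_spikes, min_units = 4) {
  cycle_spikes <- cycle_spikes[lengths(cycle_spikes) > 0]
  k <- length(cycle_spikes)
  if (k < min_units) return(NULL)
  first <- vapply(cycle_spikes, min, numeric(1))
  ord <- order(first, names(first))   # unit id breaks exact ties
  ranks <- numeric(k)
  ranks[ord] <- (seq_len(k) - 1) / (k - 1)
  names(ranks) <- names(first)
  attr(ranks, "ties") <- anyDuplicated(first) > 0
  ranks
}

#' Build the cycles x units rank matrix
#'
#' @param spike_table data.frame with columns `unit`, `cycle`, `time`.
#' @param min_units minimum participating units per included cycle.
#' @return matrix (rows = included cycles, columns = units) of normalized
#'   ranks, `NA` where a unit is silent.
#' @export
rank_matrix <- function(spike_table, min_units = 4) {
  stopifnot(all(c("unit", "cycle", "time") %in% names(spike_table)))
  units <- sort(unique(as.character(spike_table$unit)))
  cycles <- sort(unique(spike_table$cycle))
  rows <- list()
  for (cy in cycles) {
    sub <- spike_table[spike_table$cycle == cy, ]
    rv <- rank_vector(split(sub$time, as.character(sub$unit)), min_units)
    if (is.null(rv)) next
    row <- rep(NA_real_, length(units))
    names(row) <- units
    row[names(rv)] <- rv
    rows[[as.character(cy)]] <- row
  }
  if (!length(rows))
    return(matrix(numeric(0), 0, length(units),
                  dimnames = list(NULL, units)))
  do.call(rbind, rows)
}

#' Rank-order test across theta cycles
#'
#' For every included cycle, Pearson correlations between its rank vector
#' and every other cycle's (over >= `min_shared` shared units) are counted
#' above `corr_threshold`; the count is compared with its null distribution
#' under within-cycle rank shuffles (order randomization, `n_shuffles`
#' draws), with a mid-p correction for the discreteness of the count
#' statistic. Cycles whose shuffle p-value falls below `alpha` are
#' significant. `statistic = "mean_corr"` uses the mean
#' pairwise correlation instead of the high-correlation count.
#'
#' @param rmat rank matrix from [rank_matrix()] (>= 10 rows).
#' @param n_shuffles shuffles per cycle (default 500).
#' @param alpha significance level.
#' @param corr_threshold pairwise correlation threshold (default 0.8).
#' @param min_shared minimum shared units per cycle pair.
#' @param statistic per-cycle statistic.
#' @param seed integer seed.
#' @return data.frame per included cycle: observed statistic, shuffle
#'   p-value, significance flag.
#' @export
rank_order_test <- function(rmat, n_shuffles = 500, alpha = 0.05,
                            corr_threshold = 0.8, min_shared = 4,
                            statistic = c("count", "mean_corr"), seed = 1) {
  statistic <- match.arg(statistic)
  n_cyc <- nrow(rmat)
  if (n_cyc < 2) {
    warning("fewer than 2 included cycles: no pairs to test")
    return(data.frame(cycle = character(), statistic = numeric(),
                      p = numeric(), significant = logical()))
  }
  if (n_cyc < 10)
    warning("fewer than 10 included cycles: the shuffle test is weak")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  present <- !is.na(rmat)
  stat_obs <- numeric(n_cyc)
  pvals <- numeric(n_cyc)
  any_pairs <- FALSE

  for (i in seq_len(n_cyc)) {
    ui <- which(present[i, ])
    x <- rmat[i, ui]
    partners <- list()
    for (j in seq_len(n_cyc)[-i]) {
      shared <- ui[present[j, ui]]
      if (length(shared) >= min_shared)
        partners[[length(partners) + 1L]] <-
          list(idx = match(shared, ui), y = rmat[j, shared])
    }
    if (!length(partners)) {
      stat_obs[i] <- NA; pvals[i] <- NA
      next
    }
    any_pairs <- TRUE
    obs_r <- vapply(partners, function(p)
      .safe_cor(x[p$idx], p$y), numeric(1))
    stat_obs[i] <- if (statistic == "count")
      sum(obs_r > corr_threshold, na.rm = TRUE)
    else mean(obs_r, na.rm = TRUE)

    # null: shuffle the cycle's own rank order
    perm <- replicate(n_shuffles, x[sample.int(length(x))])
    null_stat <- numeric(n_shuffles)
    for (p in partners) {
      rs <- .cor_cols(perm[p$idx, , drop = FALSE], p$y)
      null_stat <- null_stat + if (statistic == "count")
        as.numeric(rs > corr_threshold) else rs
    }
    if (statistic == "mean_corr") null_stat <- null_stat / length(partners)
    # mid-p: the count statistic is heavily tied under the null, and a
    # plain >= rule would make the test far undersized
    pvals[i] <- (sum(null_stat > stat_obs[i]) +
                   0.5 * (sum(null_stat == stat_obs[i]) + 1)) /
      (n_shuffles + 1)
  }

  if (!any_pairs)
    warning("no cycle pair shares >= ", min_shared, " units")
  out <- data.frame(cycle = rownames(rmat) %||% as.character(seq_len(n_cyc)),
                    statistic = stat_obs, p = pvals,
                    significant = !is.na(pvals) & pvals <= alpha)
  out[!is.na(out$statistic), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Pearson correlation of each column of X with y
.cor_cols <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  denom <- sqrt(colSums(Xc^2) * sum(yc^2))
  out <- as.numeric(crossprod(Xc, yc)) / denom
  out[!is.finite(out)] <- 0
  out
}
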