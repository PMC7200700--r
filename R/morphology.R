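#' @useDynLib ca1theta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rpois rbeta rexp sd prcomp quantile median
#'   pchisq pf pnorm cor predict fft cutree hclust dist
#' @importFrom utils head read.table write.table
NULL

SECTION_TYPES <- c("soma", "basal", "apical_trunk", "apical_branch")

#' Construct a compartmental morphology
#'
#' A morphology is a rooted tree of cylindrical compartments. The root is the
#' soma (path distance `z = 0`); `z` is measured along the tree from the soma
#' centroid to each compartment's midpoint and strictly increases from parent
#' to child.
#'
#' @param compartments data.frame with columns `id`, `parent` (`NA` for the
#'   soma), `section` (one of soma, basal, apical_trunk, apical_branch),
#'   `length` and `diam` in micrometers. A `z` column is computed if absent.
#' @return An object of class `ca1_morphology`: the compartment table plus
#'   terminal-branch counts (`n_basal_branches`, `n_apical_branches`,
#'   `n_total_branches`).
#' @export
morphology <- function(compartments) {
  req <- c("id", "parent", "section", "length", "diam")
  missing_cols <- setdiff(req, names(compartments))
  if (length(missing_cols))
    stop("compartment table lacks columns: ", paste(missing_cols, collapse = ", "))
  cp <- as.data.frame(compartments)[, union(req, names(compartments))]
  if (!all(cp$section %in% SECTION_TYPES))
    stop("unknown section type(s): ",
         paste(unique(setdiff(cp$section, SECTION_TYPES)), collapse = ", "))
  root <- which(is.na(cp$parent))
  if (length(root) != 1L)
    stop("morphology must have exactly one root (soma); found ", length(root))
  if (cp$section[root] != "soma") stop("root compartment must be the soma")
  if (any(!cp$parent[-root] %in% cp$id))
    stop("parent ids missing for compartments: ",
         paste(cp$id[-root][!cp$parent[-root] %in% cp$id], collapse = ", "))
  if (any(cp$length <= 0) || any(cp$diam <= 0))
    stop("all compartment lengths and diameters must be > 0")

  idx <- match(cp$parent, cp$id)
  # path distance soma centroid -> compartment midpoint, walked in tree order
  z <- rep(NA_real_, nrow(cp))
  z[root] <- 0
  remaining <- setdiff(seq_len(nrow(cp)), root)
  guard <- 0L
  while (length(remaining)) {
    ready <- remaining[!is.na(z[idx[remaining]])]
    if (!length(ready)) stop("morphology tree is cyclic or disconnected")
    z[ready] <- z[idx[ready]] +
      ifelse(cp$section[idx[ready]] == "soma", cp$length[idx[ready]] / 2,
             cp$length[idx[ready]] / 2) + cp$length[ready] / 2
    remaining <- setdiff(remaining, ready)
    guard <- guard + 1L
    if (guard > nrow(cp)) stop("morphology tree is cyclic")
  }
  cp$z <- z

  is_terminal <- !(cp$id %in% cp$parent)
  m <- structure(
    list(compartments = cp,
         n_basal_branches = sum(is_terminal & cp$section == "basal"),
         n_apical_branches = sum(is_terminal & startsWith(cp$section, "apical")),
         n_total_branches = sum(is_terminal & cp$section != "soma")),
    class = "ca1_morphology")
  m
}

#' @export
print.ca1_morphology <- function(x, ...) {
  cp <- x$compartments
  cat("CA1 pyramidal-cell morphology\n")
  cat(sprintf("  compartments: %d (total length %.0f um)\n",
              nrow(cp), sum(cp$length)))
  cat(sprintf("  terminal branches: %d basal, %d apical (%d total)\n",
              x$n_basal_branches, x$n_apical_branches, x$n_total_branches))
  cat(sprintf("  max path distance: %.0f um\n", max(cp$z)))
  invisible(x)
}

#' @export
summary.ca1_morphology <- function(object, ...) {
  cp <- object$compartments
  list(n_compartments = nrow(cp),
       n_basal_branches = object$n_basal_branches,
       n_apical_branches = object$n_apical_branches,
       n_total_branches = object$n_total_branches,
       total_length_um = sum(cp$length),
       max_path_distance_um = max(cp$z))
}

#' Dendritic-spine surface correction factor
#'
#' Spine factor (SS) multiplying membrane conductance and capacitance to
#' account for the extra membrane area of dendritic spines. The soma carries
#' no correction; basal dendrites use a single factor; apical dendrites use a
#' decision table on path distance (near/far of 350 um, 350 um assigned to
#' the near rule) and dendritic thickness (intervals closed on the lower
#' bound).
#'
#' @param section_type compartment section type.
#' @param z path distance to the soma, um.
#' @param thickness dendritic diameter, um.
#' @return dimensionless factor >= 1.
#' @export
spine_correction <- function(section_type, z, thickness) {
  stopifnot(length(section_type) == 1L, length(z) == 1L, length(thickness) == 1L)
  if (!section_type %in% SECTION_TYPES)
    stop("unknown section type: ", section_type)
  if (!is.finite(z) || z < 0) stop("z must be >= 0")
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (section_type == "soma") return(1.0)
  if (section_type == "basal") return(2.51)
  if (z <= 350) {
    if (thickness >= 1.6) 1.69 else if (thickness >= 0.55) 1.60 else 1.86
  } else {
    if (thickness >= 0.35) 2.10 else 1.71
  }
}

#' Leak conductance along the somatodendritic axis
#'
#' Specific membrane (leak) conductance in S/cm2 as a sigmoid of path
#' distance `z`: the somatic membrane resistivity of 80 kOhm cm2 falls to
#' 0.4 kOhm cm2 distally with midpoint 225 um and slope 30 um. Non-somatic
#' compartments are additionally scaled by their spine factor `SS`.
#'
#' @param z path distance to the soma, um (vectorized).
#' @param SS spine factor, 1 for the soma.
#' @return conductance in S/cm2.
#' @export
leak_conductance <- function(z, SS = 1) {
  if (any(!is.finite(z)) || any(z < 0)) stop("z must be finite and >= 0")
  if (any(SS < 1)) stop("SS must be >= 1")
  SS * 0.001 / (80 + (0.4 - 80) / (1 + exp((225 - z) / 30)))
}

## ---- synthetic morphologies -------------------------------------------------

# split k terminal tips between the two children of a branch point;
# near-balanced so branch order (and hence taper) is even across the tree
.split_tips <- function(k) {
  if (k <= 1L) stop("cannot split a single tip")
  left <- max(1L, min(k - 1L, k %/% 2L + sample(c(0L, 1L), 1L) *
                        (k %% 2L)))
  c(left, k - left)
}

#' Generate a synthetic pyramidal-cell morphology
#'
#' Builds a branching binary tree standing in for a reconstructed CA1
#' pyramidal cell: a soma, `n_basal` basal terminal branches, an apical
#' trunk spanning the proximal dendritic layers, and `n_apical` apical
#' (tuft) terminal branches above it, so the tuft sits beyond the 350 um
#' boundary where the distal entorhinal inputs terminate. Each branch is a
#' chain of `depth` compartments of mean length `mean_seg_length` (10%
#' jitter); diameters taper by `taper` per branch order. Terminal-branch
#' counts are met exactly; identical seeds give identical trees.
#'
#' @param n_basal,n_apical number of basal / apical terminal branches (>= 1).
#' @param depth compartments per branch segment (>= 1).
#' @param mean_seg_length mean compartment length, um.
#' @param taper diameter multiplier per branch order, in (0, 1].
#' @param trunk_length apical trunk length, um.
#' @param seed integer seed.
#' @return a `ca1_morphology`.
#' @export
generate_morphology <- function(n_basal = 5, n_apical = 8, depth = 2,
                                mean_seg_length = 30, taper = 0.8,
                                trunk_length = 350, seed = 1) {
  if (n_basal < 1 || n_apical < 1) stop("branch counts must be >= 1")
  if (depth < 1) stop("depth must be >= 1 (branches need compartments)")
  if (mean_seg_length <= 0 || trunk_length <= 0) stop("lengths must be > 0")
  if (taper <= 0 || taper > 1) stop("taper must be in (0, 1]")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rows <- list(list(id = 1L, parent = NA_integer_, section = "soma",
                    length = 20, diam = 15))
  next_id <- 2L

  add_chain <- function(parent, section, n, base_len, diam) {
    for (i in seq_len(n)) {
      len <- base_len * runif(1, 0.9, 1.1)
      rows[[length(rows) + 1L]] <<- list(id = next_id, parent = parent,
                                         section = section, length = len,
                                         diam = diam)
      parent <- next_id
      next_id <<- next_id + 1L
    }
    parent
  }

  # recursive binary subtree with exactly k terminal tips
  grow <- function(parent, section, k, diam) {
    tip <- add_chain(parent, section, depth, mean_seg_length, diam)
    if (k == 1L) return(invisible(NULL))
    for (side in .split_tips(k)) grow(tip, section, side, diam * taper)
    invisible(NULL)
  }

  for (kb in .balanced_partition(n_basal, min(n_basal, 3L)))
    grow(1L, "basal", kb, 1.2)

  trunk_segs <- max(2L, ceiling(trunk_length / mean_seg_length))
  trunk_tip <- add_chain(1L, "apical_trunk", trunk_segs,
                         trunk_length / trunk_segs, 3.0)
  grow(trunk_tip, "apical_branch", n_apical, 1.0)

  cp <- do.call(rbind, lapply(rows, as.data.frame))
  morphology(cp)
}

# partition k tips over m primary stems as evenly as possible
.balanced_partition <- function(k, m) {
  base <- k %/% m
  out <- rep(base, m)
  extra <- k - base * m
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out[out > 0]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- SWC I/O ----------------------------------------------------------------

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`). Contiguous soma
#' samples (type 1) are merged into a single somatic compartment; type 3
#' maps to basal and type 4 to apical sections, with the apical chain up to
#' the first apical branch point classified as trunk. Compartment length is
#' the Euclidean distance to the parent sample.
#'
#' @param path SWC file path.
#' @return a `ca1_morphology`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- lines[keep]
  lineno <- which(keep)
  if (!length(recs)) stop("SWC file has no records: ", path)
  fields <- strsplit(trimws(recs), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC record(s) at line(s): ",
         paste(lineno[bad], collapse = ", "))
  tab <- do.call(rbind, lapply(fields, as.numeric))
  colnames(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  tab <- as.data.frame(tab)

  roots <- which(tab$parent == -1)
  if (length(roots) != 1L)
    stop("SWC must have exactly one root; found roots at line(s): ",
         paste(lineno[roots], collapse = ", "))
  orphan <- which(tab$parent != -1 & !tab$parent %in% tab$id)
  if (length(orphan))
    stop("SWC parent missing for id(s) ",
         paste(tab$id[orphan], collapse = ", "),
         " at line(s): ", paste(lineno[orphan], collapse = ", "))

  pidx <- match(tab$parent, tab$id)
  seg_len <- sqrt((tab$x - tab$x[pidx])^2 + (tab$y - tab$y[pidx])^2 +
                  (tab$z - tab$z[pidx])^2)

  soma_ids <- tab$id[tab$type == 1]
  if (!length(soma_ids)) stop("SWC has no soma (type 1) samples")
  soma_len <- max(20, sum(seg_len[tab$type == 1], na.rm = TRUE))
  soma_diam <- 2 * mean(tab$radius[tab$type == 1])

  dend <- tab[tab$type != 1, , drop = FALSE]
  dlen <- seg_len[tab$type != 1]
  dlen[dlen <= 0 | is.na(dlen)] <- 1e-3

  # apical trunk: apical samples from the soma up to the first apical branch
  n_children <- table(factor(dend$parent, levels = tab$id))
  section <- ifelse(dend$type == 3, "basal", "apical_branch")
  if (any(dend$type == 4)) {
    node <- dend$id[dend$type == 4 & tab$type[match(dend$parent, tab$id)] == 1]
    for (start in node) {
      cur <- start
      repeat {
        section[dend$id == cur] <- "apical_trunk"
        kids <- dend$id[dend$parent == cur & dend$type == 4]
        if (length(kids) != 1L) break
        cur <- kids
      }
    }
  }

  parent_mapped <- ifelse(dend$parent %in% soma_ids, 1L,
                          match(dend$parent, dend$id) + 1L)
  cp <- data.frame(
    id = seq_len(nrow(dend)) + 1L,
    parent = as.integer(parent_mapped),
    section = section,
    length = dlen,
    diam = pmax(2 * dend$radius, 1e-3))
  cp <- rbind(data.frame(id = 1L, parent = NA_integer_, section = "soma",
                         length = soma_len, diam = soma_diam), cp)
  morphology(cp)
}

#' Write a morphology to an SWC file
#'
#' Synthesizes 3D sample points consistent with compartment lengths (basal
#' sections grow toward negative y, apical toward positive y, with a
#' deterministic lateral fan so siblings do not overlap).
#'
#' @param morph a `ca1_morphology`.
#' @param path output file path.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "ca1_morphology"))
  cp <- morph$compartments
  n <- nrow(cp)
  xyz <- matrix(0, n, 3)
  pidx <- match(cp$parent, cp$id)
  order_idx <- order(cp$z)  # parents (smaller z) first
  for (i in order_idx) {
    if (is.na(pidx[i])) next
    dir_y <- if (cp$section[i] == "basal") -1 else 1
    # deterministic lateral offset from the compartment id
    ang <- (cp$id[i] * 2.399963) %% (2 * pi)  # golden-angle fan
    lateral <- c(cos(ang), sin(ang)) * 0.35
    v <- c(lateral[1], dir_y, lateral[2])
    v <- v / sqrt(sum(v^2))
    xyz[i, ] <- xyz[pidx[i], ] + v * cp$length[i]
  }
  type <- c(soma = 1L, basal = 3L, apical_trunk = 4L, apical_branch = 4L)
  out <- data.frame(id = cp$id,
                    type = type[cp$section],
                    x = round(xyz[, 1], 4), y = round(xyz[, 2], 4),
                    z = round(xyz[, 3], 4),
                    radius = cp$diam / 2,
                    parent = ifelse(is.na(cp$parent), -1L, cp$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export (id type x y z radius parent)", con)
  write.table(out, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Morphology summary as JSON
#'
#' @param morph a `ca1_morphology`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
morphology_json <- function(morph, path = NULL) {
  s <- summary(morph)
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
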