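#' Build a weighted plant x DT incidence matrix
#'
#' Cell (i, j) holds the summed incident counts of DT j on plant taxon i over
#' the view's leaves (normally one quarry). Taxa and DTs with no interactions
#' are dropped; rows and columns are in lexicographic order.
#'
#' @param census A `leaf_census` view with at least one damaged leaf.
#' @return Numeric matrix, plants as rows, DTs as columns.
#' @export
build_incidence <- function(census) {
  stopifnot(inherits(census, "leaf_census"))
  dm <- census$damage
  if (nrow(dm) == 0L) stop("no damaged leaves in view; no network to build")
  taxon <- census$leaves$plant_taxon[match(dm$leaf_id, census$leaves$leaf_id)]
  plants <- sort(unique(taxon))
  dts <- sort(unique(dm$dt_code))
  m <- matrix(0, length(plants), length(dts), dimnames = list(plants, dts))
  agg <- rowsum(dm$count, paste(taxon, dm$dt_code, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  m[cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))] <- agg[, 1L]
  m
}

#' Connectance of a bipartite network
#'
#' Fraction of possible plant-DT links realized: `L / (I * J)` for an
#' `I x J` matrix with `L` positive cells.
#'
#' @param m Incidence matrix from [build_incidence()].
#' @return Proportion in (0, 1\].
#' @export
connectance <- function(m) {
  stopifnot(is.matrix(m))
  sum(m > 0) / length(m)
}

#' NODF nestedness
#'
#' Binary NODF (nestedness metric based on overlap and decreasing fill): for
#' every pair of rows, and every pair of columns, the pair contributes the
#' percentage of the less-filled line's presences that also appear in the
#' strictly more-filled line (0 when fills are equal); NODF is the mean
#' contribution over all row pairs and column pairs, on a 0-100 scale.
#' Invariant to row/column permutation.
#'
#' @param m Incidence matrix (weights are reduced to presence/absence unless
#'   `weighted = TRUE`).
#' @param weighted Use the weighted variant (delegates to
#'   [vegan::nestednodf()])?
#' @return Value in \[0, 100\]; `NA` with a reason attribute for degenerate
#'   (single-row or single-column) matrices.
#' @export
nestedness_nodf <- function(m, weighted = FALSE) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L || ncol(m) < 2L) {
    return(structure(NA_real_, reason = "degenerate matrix (< 2 rows or columns)"))
  }
  if (weighted) {
    st <- vegan::nestednodf(m, weighted = TRUE)$statistic
    return(unname(st["NODF"]))
  }
  B <- m > 0
  paired_sum <- function(X) {
    fills <- rowSums(X)
    n <- nrow(X)
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      hi <- if (fills[i] > fills[j]) i else j
      lo <- if (fills[i] > fills[j]) j else i
      if (fills[hi] == fills[lo] || fills[lo] == 0) next
      tot <- tot + 100 * sum(X[hi, ] & X[lo, ]) / fills[lo]
    }
    tot
  }
  npairs <- choose(nrow(B), 2) + choose(ncol(B), 2)
  (paired_sum(B) + paired_sum(t(B))) / npairs
}

#' Mean partner diversity of plants
#'
#' Shannon entropy (natural log) of each plant row's interaction-weight
#' distribution across DTs, averaged (unweighted) over plant rows. A plant
#' interacting with a single DT contributes 0.
#'
#' @param m Incidence matrix.
#' @return Mean entropy in nats (>= 0).
#' @export
partner_diversity_plants <- function(m) {
  stopifnot(is.matrix(m))
  mean(apply(m, 1L, function(r) {
    p <- r[r > 0]
    if (length(p) <= 1L) return(0)
    p <- p / sum(p)
    -sum(p * log(p))
  }))
}

# All permutations of 1..n (used for exact robustness, n <= 6).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

robustness_area <- function(pos_by_col, P) {
  # pos_by_col: for one removal order, the removal step at which each DT
  # loses its last host. y_k = fraction of DTs still alive after k removals.
  y <- c(1, vapply(seq_len(P), function(k) mean(pos_by_col > k), 0))
  sum((y[-1L] + y[-length(y)]) / 2) / P
}

#' Robustness of DTs to plant removal
#'
#' Secondary-extinction robustness: plants are removed in random order; a DT
#' survives while at least one of its host plants remains. Robustness is the
#' area under the curve of surviving DT fraction against fraction of plants
#' removed (from 1 at no removal to 0 when all plants are gone), averaged
#' over removal orders. All `P!` orders are enumerated exactly when `P <= 6`;
#' otherwise `n_orders` random orders are sampled.
#'
#' @param m Incidence matrix.
#' @param n_orders Random removal orders when sampling (default 100).
#' @param seed Optional seed for the sampled orders.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default enumerates when `P <= 6`.
#' @return Robustness in \[0, 1\].
#' @export
robustness_dts <- function(m, n_orders = 100L, seed = NULL, exact = NULL) {
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  B <- m > 0
  P <- nrow(B)
  if (is.null(exact)) exact <- P <= 6L
  host_list <- apply(B, 2L, which, simplify = FALSE)
  one_order <- function(ord) {
    pos <- integer(P)
    pos[ord] <- seq_len(P)   # removal step of each plant
    death <- vapply(host_list, function(h) max(pos[h]), 0L)
    robustness_area(death, P)
  }
  if (exact) {
    orders <- all_perms(P)
    mean(apply(orders, 1L, one_order))
  } else {
    if (!is.null(seed)) set.seed(seed)
    mean(vapply(seq_len(n_orders), function(i) one_order(sample.int(P)), 0))
  }
}

# --- H2' machinery -------------------------------------------------------

shannon_cells <- function(w) {
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

# Minimum-entropy (maximally specialized) integer fill with the observed
# marginals: repeatedly allocate min(remaining row, remaining column) to the
# cell pairing the currently largest remaining row and column totals.
h2_fill_min_entropy <- function(r, c) {
  out <- matrix(0, length(r), length(c))
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(c)
    a <- min(r[i], c[j])
    out[i, j] <- out[i, j] + a
    r[i] <- r[i] - a; c[j] <- c[j] - a
  }
  out
}

# Maximum-entropy integer fill: the independence expectation r_i c_j / m,
# floored, with the unit deficits redistributed greedily to the feasible
# cells with the largest remaining fractional part.
h2_fill_max_entropy <- function(r, c) {
  m <- sum(r)
  e <- outer(r, c) / m
  fl <- floor(e)
  frac <- e - fl
  rd <- r - rowSums(fl)
  cd <- c - colSums(fl)
  while (sum(rd) > 0) {
    score <- frac
    score[rd[row(score)] <= 0 | cd[col(score)] <= 0] <- -Inf
    idx <- arrayInd(which.max(score), dim(score))
    i <- idx[1L]; j <- idx[2L]
    fl[i, j] <- fl[i, j] + 1
    frac[i, j] <- frac[i, j] - 1   # deprioritize repeat additions
    rd[i] <- rd[i] - 1; cd[j] <- cd[j] - 1
  }
  fl
}

#' H2' network-wide specialization index
#'
#' Standardized two-dimensional Shannon entropy of the interaction matrix:
#' `H2 = -sum p_ij log p_ij` with `p_ij = a_ij / m`, scaled between the
#' maximum attainable entropy `H2max` (an integer rounding of the
#' independence expectation `r_i c_j / m`, i.e. no specialization) and the
#' minimum attainable entropy `H2min` (a greedy maximally specialized fill),
#' both constrained to the observed marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, clipped to \[0, 1\]. 0 means
#' interactions are as unselective as the marginals allow; 1 means complete
#' specialization (or, during an outbreak, concentrated feeding preference).
#'
#' @param m Integer incidence matrix with total weight >= 2 and at least two
#'   rows and columns.
#' @return H2' in \[0, 1\] with attributes `H2`, `H2max`, `H2min`; `NA` with
#'   a reason attribute when the bounds coincide or the matrix is degenerate.
#' @export
h2prime <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L || ncol(m) < 2L || sum(m) < 2) {
    return(structure(NA_real_, reason = "degenerate matrix"))
  }
  r <- rowSums(m); c <- colSums(m)
  H2 <- shannon_cells(m)
  H2max <- shannon_cells(h2_fill_max_entropy(r, c))
  H2min <- shannon_cells(h2_fill_min_entropy(r, c))
  if (H2max - H2min < 1e-12) {
    return(structure(NA_real_, reason = "H2max = H2min; index undefined",
                     H2 = H2, H2max = H2max, H2min = H2min))
  }
  structure(min(1, max(0, (H2max - H2) / (H2max - H2min))),
            H2 = H2, H2max = H2max, H2min = H2min)
}

NETWORK_METRICS <- c("connectance", "nestedness_nodf",
                     "partner_diversity_plants", "robustness_dts", "h2prime")

#' All network-level metrics of one incidence matrix
#'
#' @param m Incidence matrix.
#' @param metrics Subset of `connectance`, `nestedness_nodf`,
#'   `partner_diversity_plants`, `robustness_dts`, `h2prime`.
#' @param n_orders,seed Passed to [robustness_dts()].
#' @return Named numeric vector.
#' @export
network_metrics <- function(m, metrics = NETWORK_METRICS, n_orders = 100L,
                            seed = NULL) {
  metrics <- match.arg(metrics, NETWORK_METRICS, several.ok = TRUE)
  vapply(metrics, function(mt) {
    v <- switch(mt,
      connectance = connectance(m),
      nestedness_nodf = nestedness_nodf(m),
      partner_diversity_plants = partner_diversity_plants(m),
      robustness_dts = robustness_dts(m, n_orders = n_orders, seed = seed),
      h2prime = h2prime(m)
    )
    as.numeric(v)
  }, 0)
}

#' Bootstrap network metrics for one quarry
#'
#' Standardizes sampling effort by repeatedly drawing `sample_size` leaves
#' without replacement from the quarry, rebuilding the weighted plant-DT
#' network, and recomputing the network metrics. Replicates whose resampled
#' matrix is degenerate (fewer than two plant taxa or two DTs) are skipped
#' and counted, not zero-filled.
#'
#' @param census A single-quarry `leaf_census` view with at least
#'   `sample_size` leaves.
#' @param sample_size Leaves per replicate (default 300).
#' @param n_boot Replicates (default 500).
#' @param seed Seed governing both the leaf draws and the robustness removal
#'   orders.
#' @param metrics Metric subset, as in [network_metrics()].
#' @param n_orders Removal orders per replicate for robustness.
#' @return List of class `bootstrap_networks`: `per_rep` (data.frame of
#'   per-replicate metrics), `summary` (mean, sd, quartiles per metric),
#'   `n_degenerate`, `sample_size`, `n_boot`, `seed`, `quarry_key`.
#' @export
bootstrap_networks <- function(census, sample_size = 300L, n_boot = 500L,
                               seed = 1L, metrics = NETWORK_METRICS,
                               n_orders = 100L) {
  stopifnot(inherits(census, "leaf_census"), n_boot >= 1L)
  metrics <- match.arg(metrics, NETWORK_METRICS, several.ok = TRUE)
  N <- nrow(census$leaves)
  if (N < sample_size) {
    stop("quarry has ", N, " leaves, fewer than sample_size = ", sample_size,
         "; apply filter_quarries() first")
  }
  qk <- paste(unique(census$leaves[c("forest", "env", "quarry")])[1L, ],
              collapse = "/")
  set.seed(seed)
  # integer-index damage representation for fast resampling
  lv_ids <- census$leaves$leaf_id
  dm <- census$damage
  d_leaf <- match(dm$leaf_id, lv_ids)
  taxa <- sort(unique(census$leaves$plant_taxon))
  dts <- sort(unique(dm$dt_code))
  ti <- match(census$leaves$plant_taxon[d_leaf], taxa)
  di <- match(dm$dt_code, dts)
  np <- length(taxa); ndt <- length(dts)

  reps <- vector("list", n_boot)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    inb <- logical(N)
    inb[sample.int(N, sample_size)] <- TRUE
    keep <- inb[d_leaf]
    m <- matrix(0, np, ndt)
    if (any(keep)) {
      key <- (ti[keep] - 1L) * ndt + di[keep]
      agg <- rowsum(dm$count[keep], key)
      k <- as.integer(rownames(agg))
      m[cbind((k - 1L) %/% ndt + 1L, (k - 1L) %% ndt + 1L)] <- agg[, 1L]
    }
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 2L || ncol(m) < 2L) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    reps[[b]] <- network_metrics(m, metrics, n_orders = n_orders)
  }
  ok <- !vapply(reps, is.null, TRUE)
  per_rep <- if (any(ok)) {
    cbind(data.frame(rep = which(ok)),
          as.data.frame(do.call(rbind, reps[ok])))
  } else {
    data.frame(rep = integer())
  }
  summ <- if (any(ok)) {
    do.call(rbind, lapply(metrics, function(mt) {
      x <- per_rep[[mt]]
      data.frame(metric = mt, mean = mean(x, na.rm = TRUE),
                 sd = sd(x, na.rm = TRUE),
                 q25 = unname(quantile(x, 0.25, na.rm = TRUE)),
                 median = unname(quantile(x, 0.5, na.rm = TRUE)),
                 q75 = unname(quantile(x, 0.75, na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  structure(list(per_rep = per_rep, summary = summ,
                 n_degenerate = n_degenerate, sample_size = sample_size,
                 n_boot = n_boot, seed = seed, quarry_key = qk),
            class = "bootstrap_networks")
}

#' @export
print.bootstrap_networks <- function(x, ...) {
  cat("<bootstrap_networks> quarry", x$quarry_key, "-", x$n_boot, "reps of",
      x$sample_size, "leaves (", x$n_degenerate, "degenerate )\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' DT degree profile across quarries
#'
#' Degree of a DT in a quarry is the number of plant taxa it interacts with
#' there (0 when absent) -- an occurrence-level measure of how generalized
#' each DT is across the landscape.
#'
#' @param census A `leaf_census`.
#' @param drop_singletons Recompute after dropping DTs occurring on exactly
#'   one leaf (per quarry)?
#' @return List: `degree` (integer matrix DT x quarry), `ffg` (FFG per DT,
#'   catalog order aligned to rows), `histograms` (per-quarry degree
#'   tabulations over present DTs).
#' @export
degree_profile <- function(census, drop_singletons = FALSE) {
  stopifnot(inherits(census, "leaf_census"))
  views <- aggregate_census(census, "quarry")
  dts <- sort(unique(census$damage$dt_code))
  deg <- matrix(0L, length(dts), length(views),
                dimnames = list(dts, names(views)))
  for (k in names(views)) {
    v <- views[[k]]
    dm <- v$damage
    if (drop_singletons && nrow(dm)) {
      occ <- unique(dm[c("leaf_id", "dt_code")])
      singles <- names(which(table(occ$dt_code) == 1L))
      dm <- dm[!dm$dt_code %in% singles, , drop = FALSE]
    }
    if (!nrow(dm)) next
    taxon <- v$leaves$plant_taxon[match(dm$leaf_id, v$leaves$leaf_id)]
    d <- tapply(taxon, dm$dt_code, function(x) length(unique(x)))
    deg[names(d), k] <- as.integer(d)
  }
  ffg <- census$catalog$ffg[match(dts, census$catalog$dt_code)]
  hists <- apply(deg, 2L, function(col) table(col[col > 0]), simplify = FALSE)
  list(degree = deg, ffg = setNames(ffg, dts), histograms = hists)
}
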