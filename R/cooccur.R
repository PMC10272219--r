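# Exact hypergeometric co-occurrence machinery. The sampling unit is the
# leaf: with N leaves, DT a on N1 of them and DT b on N2, the number of
# leaves bearing both under random placement is hypergeometric, and both
# tail probabilities include the observed value.

cooccur_fields <- function(dt_a, dt_b, N, N1, N2, j_obs, alpha) {
  expected <- N1 * N2 / N
  p_gt <- phyper(j_obs - 1L, N1, N - N1, N2, lower.tail = FALSE)
  p_lt <- phyper(j_obs, N1, N - N1, N2)
  saturated <- N1 == N | N2 == N   # a DT on every leaf admits no variation
  cls <- ifelse(saturated, "random",
                ifelse(p_gt < alpha, "positive",
                       ifelse(p_lt < alpha, "negative", "random")))
  note <- ifelse(saturated, "degenerate: DT present on every leaf", "")
  data.frame(dt_a = dt_a, dt_b = dt_b, N = N, N1 = N1, N2 = N2,
             j_obs = j_obs, expected = expected,
             p_lt = p_lt, p_gt = p_gt, effect = (j_obs - expected) / N,
             classification = cls, note = note, stringsAsFactors = FALSE)
}

#' Probabilistic co-occurrence of one DT pair
#'
#' Leaf-level test of whether two DTs share leaves more or less often than
#' expected under random, independent placement with fixed occurrence counts.
#' The number of jointly occupied leaves follows the hypergeometric
#' distribution `P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)`; the pair is
#' classified `positive` when `P(J >= j_obs) < alpha`, `negative` when
#' `P(J <= j_obs) < alpha`, and `random` otherwise. Both tails include the
#' observed value. The effect size is `(j_obs - expected) / N` with
#' `expected = N1 N2 / N`.
#'
#' @param census A `leaf_census` view (typically one forest).
#' @param dt_a,dt_b DT codes present in the view.
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame with fields `dt_a, dt_b, N, N1, N2, j_obs,
#'   expected, p_lt, p_gt, effect, classification, note`.
#' @export
pair_cooccurrence <- function(census, dt_a, dt_b, alpha = 0.05) {
  stopifnot(inherits(census, "leaf_census"))
  N <- nrow(census$leaves)
  if (N < 2L) stop("need at least two leaves")
  occ <- unique(census$damage[c("leaf_id", "dt_code")])
  la <- occ$leaf_id[occ$dt_code == dt_a]
  lb <- occ$leaf_id[occ$dt_code == dt_b]
  if (!length(la)) stop("DT not present in view: ", dt_a)
  if (!length(lb)) stop("DT not present in view: ", dt_b)
  cooccur_fields(dt_a, dt_b, N, length(la), length(lb),
                 length(intersect(la, lb)), alpha)
}

#' All pairwise DT co-occurrences within a forest
#'
#' Computes [pair_cooccurrence()] for every unordered DT pair in the chosen
#' scope, with the conventional filters of the probabilistic model: pairs
#' whose expected co-occurrence falls below `min_expected` are excluded (but
#' recorded), and singleton DTs (present on exactly one leaf) can be dropped
#' entirely.
#'
#' @param census A `leaf_census`.
#' @param forest Forest id to analyse, or `NULL` to use the census as-is.
#' @param alpha Significance level.
#' @param min_expected Minimum expected co-occurrence for a pair to be tested
#'   (default 1).
#' @param drop_singletons Drop DTs occurring on exactly one leaf?
#' @return List with `pairs` (data.frame of tested pairs), `excluded_pairs`
#'   (pairs under `min_expected`), `dropped_dts` (singletons removed),
#'   `effect_matrix` (symmetric DT x DT effect sizes, `NA` where untested)
#'   and `classification_matrix`.
#' @export
cooccurrence_matrix <- function(census, forest = NULL, alpha = 0.05,
                                min_expected = 1, drop_singletons = FALSE) {
  stopifnot(inherits(census, "leaf_census"))
  if (!is.null(forest)) {
    keep <- census$leaves$leaf_id[census$leaves$forest == forest]
    if (!length(keep)) stop("forest not present in census: ", forest)
    census <- subset_census(census, keep)
  }
  N <- nrow(census$leaves)
  occ <- unique(census$damage[c("leaf_id", "dt_code")])
  n_occ <- table(occ$dt_code)
  dropped <- character()
  if (drop_singletons) {
    dropped <- names(n_occ)[n_occ == 1L]
    occ <- occ[!occ$dt_code %in% dropped, , drop = FALSE]
    n_occ <- n_occ[!names(n_occ) %in% dropped]
  }
  dts <- sort(names(n_occ))
  empty <- list(pairs = NULL, excluded_pairs = NULL, dropped_dts = dropped,
                effect_matrix = NULL, classification_matrix = NULL)
  if (length(dts) < 2L) {
    message("fewer than two eligible DTs; no pairs to test")
    return(empty)
  }
  # leaves x DTs presence matrix; crossprod gives joint occupancy counts
  P <- matrix(0L, N, length(dts),
              dimnames = list(census$leaves$leaf_id, dts))
  P[cbind(occ$leaf_id, occ$dt_code)] <- 1L
  J <- crossprod(P)
  comb <- which(upper.tri(J), arr.ind = TRUE)
  rows <- cooccur_fields(
    dt_a = dts[comb[, 1L]], dt_b = dts[comb[, 2L]], N = N,
    N1 = as.integer(n_occ[dts[comb[, 1L]]]),
    N2 = as.integer(n_occ[dts[comb[, 2L]]]),
    j_obs = as.integer(J[comb]), alpha = alpha
  )
  keep <- rows$expected >= min_expected
  pairs <- rows[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  excluded <- rows[!keep, c("dt_a", "dt_b", "expected"), drop = FALSE]
  rownames(excluded) <- NULL

  eff <- matrix(NA_real_, length(dts), length(dts), dimnames = list(dts, dts))
  cls <- matrix(NA_character_, length(dts), length(dts),
                dimnames = list(dts, dts))
  if (nrow(pairs)) {
    idx <- cbind(match(pairs$dt_a, dts), match(pairs$dt_b, dts))
    eff[idx] <- pairs$effect; eff[idx[, 2:1, drop = FALSE]] <- pairs$effect
    cls[idx] <- pairs$classification
    cls[idx[, 2:1, drop = FALSE]] <- pairs$classification
  }
  list(pairs = pairs, excluded_pairs = excluded, dropped_dts = dropped,
       effect_matrix = eff, classification_matrix = cls)
}

#' Per-DT summary of significant pairings
#'
#' For each DT, among its significantly classified pairs, the percentage that
#' are positive vs. negative (summing to 100 when any exist). DTs with no
#' significant pairs report `n_significant = 0` and `NA` percentages.
#'
#' @param pairs data.frame of classified pairs from [cooccurrence_matrix()].
#' @return data.frame with columns `dt_code, n_pairs, n_significant,
#'   pct_positive, pct_negative`.
#' @export
pairing_summary <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  dts <- sort(unique(c(pairs$dt_a, pairs$dt_b)))
  rows <- lapply(dts, function(d) {
    mine <- pairs[pairs$dt_a == d | pairs$dt_b == d, , drop = FALSE]
    sig <- mine[mine$classification != "random", , drop = FALSE]
    ns <- nrow(sig)
    data.frame(
      dt_code = d, n_pairs = nrow(mine), n_significant = ns,
      pct_positive = if (ns) 100 * mean(sig$classification == "positive")
                     else NA_real_,
      pct_negative = if (ns) 100 * mean(sig$classification == "negative")
                     else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
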