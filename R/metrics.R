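# Resolve a damage selector ("total", a spec_class, or an FFG) to the set of
# DT codes it covers under the census catalog.
selector_dts <- function(census, selector) {
  cat <- census$catalog
  if (identical(selector, "total")) return(cat$dt_code)
  if (selector %in% SPEC_CLASS_LEVELS) {
    return(cat$dt_code[cat$spec_class == selector])
  }
  if (selector %in% FFG_LEVELS) return(cat$dt_code[cat$ffg == selector])
  stop("unknown selector: '", selector, "' (use 'total', a spec_class, ",
       "or an FFG name)")
}

#' Damage frequency
#'
#' Fraction of censused leaves bearing at least one DT matching the selector.
#' A leaf counts once regardless of how many matching DTs or incidents it
#' carries; the denominator is every censused leaf, damaged or not.
#'
#' @param census A `leaf_census` view (any aggregation level).
#' @param selector `"total"`, a spec class (`"generalized"`,
#'   `"specialized"`), or an FFG name.
#' @return Proportion in \[0, 1\].
#' @export
damage_frequency <- function(census, selector = "total") {
  stopifnot(inherits(census, "leaf_census"))
  n <- nrow(census$leaves)
  if (n == 0L) stop("empty census view")
  dts <- selector_dts(census, selector)
  dm <- census$damage
  hit <- unique(dm$leaf_id[dm$dt_code %in% dts])
  length(hit) / n
}

#' Rarefied damage-type diversity
#'
#' Expected number of distinct DTs (matching the selector) in a random subset
#' of `n_std` leaves drawn without replacement, computed analytically:
#' `E[S] = sum_d (1 - choose(N - m_d, n_std) / choose(N, n_std))` where `m_d`
#' is the number of leaves bearing DT `d`. This equals the mean richness over
#' all size-`n_std` leaf subsets; a Monte Carlo mode is provided as a
#' cross-check.
#'
#' @param census A `leaf_census` view with `N >= n_std` leaves.
#' @param selector As in [damage_frequency()].
#' @param n_std Standardized leaf count (default 300).
#' @param method `"exact"` (analytic, default) or `"montecarlo"`.
#' @param n_draws Subsamples for the Monte Carlo mode.
#' @return Expected DT richness (>= 0).
#' @export
rarefied_dt_diversity <- function(census, selector = "total", n_std = 300L,
                                  method = c("exact", "montecarlo"),
                                  n_draws = 1000L) {
  stopifnot(inherits(census, "leaf_census"))
  method <- match.arg(method)
  N <- nrow(census$leaves)
  if (N < n_std) {
    stop("view has ", N, " leaves but n_std = ", n_std,
         "; apply filter_quarries() first")
  }
  dts <- selector_dts(census, selector)
  dm <- census$damage[census$damage$dt_code %in% dts, , drop = FALSE]
  if (nrow(dm) == 0L) return(0)
  m <- table(unique(dm[c("leaf_id", "dt_code")])$dt_code)
  if (method == "exact") {
    # log-space binomial coefficients keep N ~ thousands safe
    sum(1 - exp(lchoose(N - as.numeric(m), n_std) - lchoose(N, n_std)))
  } else {
    ids <- census$leaves$leaf_id
    occ <- unique(dm[c("leaf_id", "dt_code")])
    mean(vapply(seq_len(n_draws), function(i) {
      take <- sample(ids, n_std)
      length(unique(occ$dt_code[occ$leaf_id %in% take]))
    }, 0))
  }
}

#' Plant diversity and evenness
#'
#' Shannon diversity `H = -sum p_i log(p_i)` (natural log) of the leaf shares
#' per plant taxon, and Pielou's evenness `J = H / log(S)`. With a single
#' taxon `J` is undefined and returned as `NA`.
#'
#' @param census A `leaf_census` view.
#' @return Named list: `shannon` (nats), `pielou` (\[0, 1\] or `NA`),
#'   `n_taxa`.
#' @export
plant_diversity <- function(census) {
  stopifnot(inherits(census, "leaf_census"))
  if (nrow(census$leaves) == 0L) stop("empty census view")
  p <- table(census$leaves$plant_taxon)
  p <- as.numeric(p) / sum(p)
  H <- -sum(p * log(p))
  S <- length(p)
  list(shannon = H, pielou = if (S > 1L) H / log(S) else NA_real_, n_taxa = S)
}

#' Empirical logit transform of a damage frequency
#'
#' `log(p / (1 - p))` with natural log. Boundary frequencies (p = 0 or 1) are
#' replaced by the empirical-logit adjustment
#' `p' = (p * (n - 1) + 0.5) / n`, where `n` is the number of leaves behind
#' the frequency; the adjustment is flagged in the `"adjusted"` attribute.
#'
#' @param p Proportion in \[0, 1\].
#' @param n Leaf count behind `p`; required when `p` is 0 or 1.
#' @return The logit, with attribute `adjusted` (logical).
#' @export
logit_adjusted <- function(p, n = NULL) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  adjusted <- FALSE
  if (p == 0 || p == 1) {
    if (is.null(n)) stop("p on the boundary needs the leaf count n")
    p <- (p * (n - 1) + 0.5) / n
    adjusted <- TRUE
  }
  structure(log(p / (1 - p)), adjusted = adjusted)
}

#' Per-quarry herbivory and plant metrics table
#'
#' One row per quarry with the standard herbivory metric set: damage
#' frequencies for total, specialized, and each of the seven FFGs; rarefied
#' DT diversities (at `n_std` leaves) for total, specialized, gall and mine
#' damage; and plant Shannon diversity and Pielou evenness. All quarries must
#' have at least `n_std` leaves (run [filter_quarries()] first).
#'
#' @param census A filtered `leaf_census`.
#' @param n_std Rarefaction size (default 300).
#' @return data.frame with one row per quarry.
#' @export
metrics_table <- function(census, n_std = 300L) {
  stopifnot(inherits(census, "leaf_census"))
  views <- aggregate_census(census, "quarry")
  qt <- quarry_table(census)
  if (any(qt$n_leaves < n_std)) {
    stop("quarry(ies) below n_std = ", n_std, ": ",
         paste(qt$quarry_key[qt$n_leaves < n_std], collapse = ", "),
         "; apply filter_quarries() first")
  }
  freq_sel <- c(total = "total", specialized = "specialized",
                setNames(FFG_LEVELS, FFG_LEVELS))
  div_sel <- c(total = "total", specialized = "specialized",
               gall = "gall", mine = "mine")
  rows <- lapply(names(views), function(k) {
    v <- views[[k]]
    fr <- vapply(freq_sel, function(s) damage_frequency(v, s), 0)
    dv <- vapply(div_sel, function(s) rarefied_dt_diversity(v, s, n_std), 0)
    pd <- plant_diversity(v)
    meta <- v$leaves[1L, c("forest", "env", "quarry")]
    cbind(
      data.frame(quarry_key = k, forest = meta$forest, env = meta$env,
                 quarry = meta$quarry, n_leaves = nrow(v$leaves),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(setNames(fr, paste0("freq_", names(freq_sel))))),
      as.data.frame(as.list(setNames(dv, paste0("div_", names(div_sel))))),
      data.frame(n_std = as.integer(n_std), plant_shannon = pd$shannon,
                 plant_pielou = pd$pielou)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
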