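# Fixtures are built in code; no data files are shipped.

simple_catalog <- function() {
  data.frame(
    dt_code = c("DT1", "DT2", "DT3", "DT4", "DT5", "DT6", "DT7"),
    ffg = c("hole", "margin", "gall", "mine", "surface", "skeletonization",
            "piercing_sucking"),
    spec_class = c("generalized", "generalized", "specialized", "specialized",
                   "generalized", "generalized", "generalized"),
    stringsAsFactors = FALSE
  )
}

# census with explicit per-leaf DT sets; dt_sets is a named list
# leaf_id -> character vector of DT codes (may be empty)
census_from_sets <- function(dt_sets, quarry = "Q1", env = "E1",
                             forest = "F1", taxon = "plantA",
                             catalog = simple_catalog()) {
  ids <- names(dt_sets)
  n <- length(ids)
  taxon <- rep_len(taxon, n)
  leaves <- data.frame(leaf_id = ids, forest = rep_len(forest, n),
                       env = rep_len(env, n), quarry = rep_len(quarry, n),
                       plant_taxon = taxon, stringsAsFactors = FALSE)
  dmg <- do.call(rbind, lapply(ids, function(id) {
    dts <- dt_sets[[id]]
    if (!length(dts)) return(NULL)
    data.frame(leaf_id = id, dt_code = dts, count = 1L,
               stringsAsFactors = FALSE)
  }))
  leaf_census(leaves, dmg, catalog)
}

# small two-forest study sharing taxa, for pipeline and aggregation tests
tiny_study_config <- function(seed = 1L, leaves_per_quarry = 80L) {
  envs <- data.frame(env_id = c("swamp", "river"), n_quarries = 2L,
                     leaves_per_quarry = as.integer(leaves_per_quarry),
                     env_shift = 10, stringsAsFactors = FALSE)
  pool_a <- stats::setNames(c(5, 3, 2, 1), paste0("sp", 1:4))
  pool_b <- stats::setNames(c(4, 3, 2, 2, 1), paste0("sp", 2:6))
  sim_config(seed = seed,
             forests = list(forest_spec("FA", pool_a, envs),
                            forest_spec("FB", pool_b, envs)),
             dt_pool = herbnet:::default_dt_pool())
}

random_incidence <- function(nr, nc, fill = 0.5, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill) * (1 + rpois(nr * nc, lambda)),
                nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# ---- independent oracles ------------------------------------------------

# mean DT richness over all size-n leaf subsets, by exhaustive enumeration
oracle_rarefaction <- function(dt_sets, n) {
  ids <- names(dt_sets)
  subsets <- combn(ids, n, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    length(unique(unlist(dt_sets[s])))
  }, 0))
}

# distribution of joint occupancy by enumerating all C(N, N2) placements of
# the second DT against a fixed placement of the first
oracle_cooccur_tails <- function(N, N1, N2, j_obs) {
  a <- seq_len(N1)
  placements <- combn(N, N2, simplify = FALSE)
  j <- vapply(placements, function(b) length(intersect(a, b)), 0L)
  c(p_lt = mean(j <= j_obs), p_gt = mean(j >= j_obs))
}

# naive elementwise NODF with explicit loops, no shared code with the
# implementation
oracle_nodf <- function(m) {
  B <- (m > 0) * 1L
  score_pairs <- function(M) {
    n <- nrow(M); tot <- 0; cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      cnt <- cnt + 1
      fi <- 0; fj <- 0
      for (k in seq_len(ncol(M))) { fi <- fi + M[i, k]; fj <- fj + M[j, k] }
      if (fi == fj) next
      up <- if (fi > fj) i else j
      lo <- if (fi > fj) j else i
      flo <- min(fi, fj)
      if (flo == 0) next
      ov <- 0
      for (k in seq_len(ncol(M))) if (M[up, k] == 1 && M[lo, k] == 1) ov <- ov + 1
      tot <- tot + 100 * ov / flo
    }
    c(tot, cnt)
  }
  r <- score_pairs(B); cc <- score_pairs(t(B))
  (r[1] + cc[1]) / (r[2] + cc[2])
}

perms_rec <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_rec(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p + (p >= k), k, after = k - 1L)[
      seq_len(n)]
  }
  out
}

# robustness by simulating every removal order step by step
oracle_robustness <- function(m) {
  B <- m > 0
  P <- nrow(B)
  orders <- combinat_perms(P)
  areas <- vapply(orders, function(ord) {
    alive <- rep(TRUE, P)
    y <- numeric(P + 1)
    y[1] <- 1
    for (k in seq_len(P)) {
      alive[ord[k]] <- FALSE
      surv <- 0
      for (j in seq_len(ncol(B))) if (any(B[alive, j])) surv <- surv + 1
      y[k + 1] <- surv / ncol(B)
    }
    sum((y[-1] + y[-(P + 1)]) / 2) / P
  }, 0)
  mean(areas)
}

combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (k in seq_len(n)) for (p in sub) {
    rest <- seq_len(n)[-k]
    out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

# exhaustive entropy bounds over all nonnegative integer matrices with the
# given marginals (small cases only)
oracle_h2_bounds <- function(r, c) {
  nr <- length(r); nc <- length(c)
  ent <- function(w) { p <- w[w > 0] / sum(w); -sum(p * log(p)) }
  best <- c(max = -Inf, min = Inf)
  fill_row <- function(mat, i) {
    if (i > nr) {
      if (all(colSums(mat) == c)) {
        e <- ent(mat)
        best["max"] <<- max(best["max"], e)
        best["min"] <<- min(best["min"], e)
      }
      return(invisible())
    }
    rem_c <- c - colSums(mat)
    cells <- expand_row(r[i], pmin(r[i], rem_c))
    for (row in cells) {
      mat[i, ] <- row
      fill_row(mat, i + 1L)
    }
  }
  expand_row <- function(total, caps) {
    if (length(caps) == 1L) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1])) {
      for (rest in expand_row(total - v, caps[-1])) {
        out[[length(out) + 1L]] <- c(v, rest)
      }
    }
    out
  }
  fill_row(matrix(0L, nr, nc), 1L)
  best
}
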