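#' Quarry-level composition table
#'
#' FFG mode: per quarry, the fraction of leaves bearing at least one DT of
#' each of the seven FFGs (columns need not sum to 1 -- a leaf can carry
#' several FFGs). Plant mode: per quarry, the leaf share of each taxon
#' (columns sum to 1 per row).
#'
#' @param census A `leaf_census` (typically filtered).
#' @param mode `"ffg"` or `"plant"`.
#' @return Object of class `composition_table`: list with `props` (matrix,
#'   quarries x categories), `meta` (data.frame: quarry_key, forest, env)
#'   and `mode`.
#' @export
composition_table <- function(census, mode = c("ffg", "plant")) {
  stopifnot(inherits(census, "leaf_census"))
  mode <- match.arg(mode)
  views <- aggregate_census(census, "quarry")
  cols <- if (mode == "ffg") FFG_LEVELS else
    sort(unique(census$leaves$plant_taxon))
  props <- matrix(0, length(views), length(cols),
                  dimnames = list(names(views), cols))
  meta <- data.frame(quarry_key = names(views), forest = "", env = "",
                     stringsAsFactors = FALSE)
  for (i in seq_along(views)) {
    v <- views[[i]]
    meta$forest[i] <- v$leaves$forest[1L]
    meta$env[i] <- v$leaves$env[1L]
    n <- nrow(v$leaves)
    if (mode == "ffg") {
      props[i, ] <- vapply(FFG_LEVELS,
                           function(g) damage_frequency(v, g), 0)
    } else {
      tab <- table(v$leaves$plant_taxon) / n
      props[i, names(tab)] <- as.numeric(tab)
    }
  }
  structure(list(props = props, meta = meta, mode = mode),
            class = "composition_table")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum min(x_c, y_c) / sum (x_c + y_c)`, computed with
#' [vegan::vegdist()]. Rows of all zeros have undefined dissimilarities and
#' are returned as `NA` with a warning.
#'
#' @param x A [composition_table()] or numeric matrix (rows = sites).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "composition_table")) x$props else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least two rows")
  zero <- rowSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(zero)) {
    warning("row(s) of all zeros: dissimilarities set to NA for ",
            paste(rownames(m)[zero], collapse = ", "))
    d[zero, ] <- NA_real_
    d[, zero] <- NA_real_
  }
  diag(d) <- 0
  d
}

#' NMDS ordination
#'
#' Nonmetric multidimensional scaling of a dissimilarity matrix, minimizing
#' Kruskal stress-1 with monotone regression on dissimilarity ranks via
#' [vegan::metaMDS()] (random-start restarts, best solution kept,
#' coordinates centred). Stress is on the 0-1 scale.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Target dimensionality (default 2); needs `n >= k + 1` points.
#' @param n_restarts Random restarts (default 20).
#' @param seed Optional RNG seed for the restarts.
#' @return List of class `nmds_ordination`: `coordinates` (n x k), `stress`,
#'   `converged`, `n_restarts`, `k`, `seed`.
#' @export
nmds_ordination <- function(d, k = 2L, n_restarts = 20L, seed = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (nrow(dm) < k + 1L) stop("need at least k + 1 points")
  if (!is.null(seed)) set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(as.dist(dm), k = k, try = n_restarts,
                   trymax = n_restarts, autotransform = FALSE,
                   wascores = FALSE, trace = 0)
  ))
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  if (!fit$converged) {
    warning("NMDS did not converge in ", n_restarts,
            " restarts; best attempt returned")
  }
  structure(list(coordinates = coords, stress = fit$stress,
                 converged = isTRUE(fit$converged),
                 n_restarts = n_restarts, k = k, seed = seed),
            class = "nmds_ordination")
}

# Enumerate all distinct assignments of group labels to n items with the
# given group sizes (used for the exact ANOSIM null).
label_arrangements <- function(sizes) {
  n <- sum(sizes)
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) {
      return(list(avail))
    }
    first <- combn(avail, sizes[1L], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- recurse(setdiff(avail, f), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(f, r)))
    }
    out
  }
  # each arrangement lists member indices of group 1, then group 2, ...
  recurse(seq_len(n), sizes)
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of whether dissimilarities between groups
#' exceed those within groups. All pairwise dissimilarities are ranked
#' (average ranks on ties) and
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`,
#' bounded in \[-1, 1\] with R = 1 when every between-group dissimilarity
#' exceeds every within-group one. The p-value is the fraction of label
#' permutations with `R >= R_obs`; the null is enumerated exactly when the
#' number of distinct label arrangements is at most `exact_limit`, otherwise
#' `n_perm` random permutations are used with the +1 correction.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group labels, one per row of `d`; at least two groups of
#'   at least two members each.
#' @param n_perm Random permutations (default 999).
#' @param seed Optional RNG seed.
#' @param exact_limit Enumerate the null exactly when the number of label
#'   arrangements is at most this (default 10000).
#' @return List of class `anosim_result`: `R`, `p`, `n_perm`, `exact`,
#'   `grouping` (the labels).
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = NULL,
                        exact_limit = 10000L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per row of d is required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L)) {
    stop("every group needs at least two members; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  ut <- which(upper.tri(dm))
  rk <- rank(dm[ut])          # average ranks on ties
  if (length(unique(rk)) == 1L) {
    return(structure(list(R = NA_real_, p = NA_real_, n_perm = 0L,
                          exact = FALSE, grouping = groups,
                          reason = "all dissimilarities tied"),
                     class = "anosim_result"))
  }
  pi_ <- row(dm)[ut]; pj <- col(dm)[ut]
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    between <- g[pi_] != g[pj]
    (mean(rk[between]) - mean(rk[!between])) / denom
  }
  R_obs <- r_stat(groups)

  n_arr <- exp(lfactorial(n) - sum(lfactorial(sizes)))
  if (n_arr <= exact_limit) {
    glabs <- rep(names(sizes), sizes)
    arr <- label_arrangements(as.integer(sizes))
    Rs <- vapply(arr, function(idx) {
      g <- character(n); g[idx] <- glabs
      r_stat(g)
    }, 0)
    p <- mean(Rs >= R_obs - 1e-12)
    exact <- TRUE
    n_used <- length(Rs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (r_stat(sample(groups)) >= R_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(R = R_obs, p = p, n_perm = n_used, exact = exact,
                 grouping = groups),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", format(x$R, digits = 4), " p =",
      format(x$p, digits = 4),
      if (x$exact) "(exact null)" else sprintf("(%d permutations)", x$n_perm),
      "\n")
  invisible(x)
}

#' Rosner (generalized ESD) outlier test
#'
#' Generalized extreme Studentized deviate test for up to `k_max` outliers:
#' iteratively remove the most extreme value, compute
#' `R_i = max |x - mean| / sd`, and compare against the critical value
#' `lambda_i = (n - i) t / sqrt((n - i - 1 + t^2)(n - i + 1))` with
#' `t = t_{p, n-i-1}`, `p = 1 - alpha / (2(n - i + 1))`. The number of
#' outliers is the largest `i` with `R_i > lambda_i`.
#'
#' @param x Numeric sample with `n >= k_max + 3`.
#' @param k_max Maximum number of outliers tested (default 3).
#' @param alpha Significance level (default 0.05).
#' @return List of class `rosner_result`: `outliers` (values), `indices`
#'   (positions in `x`), `n_outliers`, `trace` (data.frame of R_i vs
#'   lambda_i).
#' @export
rosner_outliers <- function(x, k_max = 3L, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < k_max + 3L) stop("need n >= k_max + 3 (n = ", n, ")")
  if (sd(x) == 0) {
    return(structure(list(outliers = numeric(), indices = integer(),
                          n_outliers = 0L, trace = NULL,
                          reason = "zero variance"),
                     class = "rosner_result"))
  }
  keep <- seq_len(n)
  trace <- data.frame(i = integer(), value = numeric(), R = numeric(),
                      lambda = numeric(), exceeds = logical())
  cand <- integer()
  for (i in seq_len(k_max)) {
    xi <- x[keep]
    ni <- length(xi)
    s <- sd(xi)
    if (s == 0) break
    dev <- abs(xi - mean(xi))
    w <- which.max(dev)
    Ri <- dev[w] / s
    pp <- 1 - alpha / (2 * (n - i + 1))
    tt <- qt(pp, n - i - 1)
    lam <- (n - i) * tt / sqrt((n - i - 1 + tt^2) * (n - i + 1))
    trace <- rbind(trace, data.frame(i = i, value = xi[w], R = Ri,
                                     lambda = lam, exceeds = Ri > lam))
    cand <- c(cand, keep[w])
    keep <- keep[-w]
  }
  n_out <- if (any(trace$exceeds)) max(trace$i[trace$exceeds]) else 0L
  idx <- cand[seq_len(n_out)]
  structure(list(outliers = x[idx], indices = idx, n_outliers = n_out,
                 trace = trace),
            class = "rosner_result")
}

#' Tukey-Kramer honest significant difference comparisons
#'
#' Pairwise comparisons of group means using the studentized range with the
#' pooled within-group variance and the Tukey-Kramer unbalanced-size
#' correction, via `stats::TukeyHSD` on a one-way `aov` fit. The studentized
#' range statistic `q = |diff| / sqrt(MSE/2 (1/n_i + 1/n_j))` is reported
#' alongside the adjusted p-value.
#'
#' @param values Numeric response.
#' @param groups Group labels (at least two groups of at least two values).
#' @param alpha Family-wise level used for the confidence intervals.
#' @return data.frame with columns `comparison, diff, lwr, upr, q, p_adj`.
#' @export
tukey_hsd_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two values")
  fit <- aov(values ~ groups)
  mse <- sum(fit$residuals^2) / fit$df.residual
  if (mse <= 1e-12 * (mean(values^2) + 1)) {
    stop("zero within-group variance; comparisons undefined")
  }
  th <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  cmp <- rownames(th)
  ab <- strsplit(cmp, "-", fixed = TRUE)
  ns <- table(groups)
  qstat <- vapply(seq_along(cmp), function(i) {
    na <- ns[[ab[[i]][1L]]]; nb <- ns[[ab[[i]][2L]]]
    abs(th[i, "diff"]) / sqrt(mse / 2 * (1 / na + 1 / nb))
  }, 0)
  data.frame(comparison = cmp, diff = th[, "diff"], lwr = th[, "lwr"],
             upr = th[, "upr"], q = qstat, p_adj = th[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}
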