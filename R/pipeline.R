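# Counter-based stage seed expansion: one top-level seed deterministically
# yields an independent sub-seed per stage/unit, so toggling one stage never
# shifts another stage's random stream.
stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + 99991 * counter) %% 2147483587 + 1)
}

# ANOSIM wrapper for the pipeline: drops groups with a single member (e.g.
# the lone upland quarry) and skips gracefully when fewer than two usable
# groups remain.
anosim_row <- function(d, groups, label, grouping, n_perm, seed) {
  ok <- groups %in% names(which(table(groups) >= 2L))
  if (sum(ok) < 4L || length(unique(groups[ok])) < 2L) {
    return(data.frame(scope = label, grouping = grouping, R = NA_real_,
                      p = NA_real_, n_perm = 0L, n_sites = sum(ok),
                      note = "insufficient groups", stringsAsFactors = FALSE))
  }
  a <- anosim_test(d[ok, ok, drop = FALSE], groups[ok], n_perm = n_perm,
                   seed = seed)
  data.frame(scope = label, grouping = grouping, R = a$R, p = a$p,
             n_perm = a$n_perm, n_sites = sum(ok), note = "",
             stringsAsFactors = FALSE)
}

# Partition forests into components connected by shared plant taxa; forests
# with disjoint pools are never co-ordinated.
plant_pool_components <- function(census) {
  lv <- census$leaves
  forests <- sort(unique(lv$forest))
  taxa <- lapply(forests, function(f) unique(lv$plant_taxon[lv$forest == f]))
  comp <- seq_along(forests)
  for (i in seq_along(forests)) for (j in seq_along(forests)) {
    if (i < j && length(intersect(taxa[[i]], taxa[[j]]))) {
      comp[comp == comp[j]] <- comp[i]
    }
  }
  split(forests, comp)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, quarry filtering, herbivory metrics,
#' co-occurrence, bootstrap networks, and ordination/ANOSIM, writing one CSV
#' per stage plus a JSON run manifest (seeds, parameters, record counts,
#' exclusions) into `out_dir`. Identical inputs and seed produce
#' byte-identical artifacts. Plant-composition ordinations are run separately
#' within each set of forests that share plant species.
#'
#' @param out_dir Output directory (created if absent).
#' @param census A `leaf_census`, or `NULL` to simulate from `config`.
#' @param config A [sim_config()] used when `census` is `NULL`.
#' @param seed Top-level seed, expanded per stage.
#' @param min_leaves Quarry retention threshold (default 300).
#' @param n_std Rarefaction size (default 300).
#' @param sample_size,n_boot,n_orders Bootstrap-network parameters
#'   (defaults 300, 500, 100).
#' @param alpha Significance level for co-occurrence classification.
#' @param min_expected,drop_singletons Co-occurrence filters.
#' @param n_perm ANOSIM permutations.
#' @param stages Character subset of
#'   `c("metrics", "cooccurrence", "networks", "ordination")`.
#' @param verbose Print stage progress?
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, census = NULL, config = NULL, seed = 1L,
                         min_leaves = 300L, n_std = 300L,
                         sample_size = 300L, n_boot = 500L, n_orders = 100L,
                         alpha = 0.05, min_expected = 1,
                         drop_singletons = FALSE, n_perm = 999L,
                         stages = c("metrics", "cooccurrence", "networks",
                                    "ordination"),
                         verbose = FALSE) {
  stages <- match.arg(stages, c("metrics", "cooccurrence", "networks",
                                "ordination"), several.ok = TRUE)
  if (is.null(census) && is.null(config)) {
    stop("provide either a census or a sim_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(
    package = "herbnet",
    version = as.character(utils::packageVersion("herbnet")),
    seed = seed,
    parameters = list(min_leaves = min_leaves, n_std = n_std,
                      sample_size = sample_size, n_boot = n_boot,
                      n_orders = n_orders, alpha = alpha,
                      min_expected = min_expected,
                      drop_singletons = drop_singletons, n_perm = n_perm),
    stages = stages
  )

  if (is.null(census)) {
    say("simulate: generating census from config (seed ", config$seed, ")")
    census <- generate_census(config)
    write_census(census, file.path(out_dir, "census.csv"),
                 file.path(out_dir, "catalog.csv"))
    manifest$sim_seed <- config$seed
  }
  manifest$n_leaves_in <- leaf_count(census)

  flt <- filter_quarries(census, min_leaves)
  census <- flt$census
  write.csv(flt$excluded, file.path(out_dir, "excluded_quarries.csv"),
            row.names = FALSE)
  manifest$excluded_quarries <- flt$excluded$quarry_key
  manifest$n_leaves_retained <- leaf_count(census)
  say("filter: ", nrow(flt$excluded), " quarries excluded, ",
      leaf_count(census), " leaves retained")

  if ("metrics" %in% stages) {
    mt <- metrics_table(census, n_std = n_std)
    write.csv(mt, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    manifest$n_quarries <- nrow(mt)
    say("metrics: ", nrow(mt), " quarries")
  }

  if ("cooccurrence" %in% stages) {
    forests <- sort(unique(census$leaves$forest))
    all_pairs <- list(); all_summ <- list()
    for (f in forests) {
      cm <- cooccurrence_matrix(census, forest = f, alpha = alpha,
                                min_expected = min_expected,
                                drop_singletons = drop_singletons)
      if (!is.null(cm$pairs) && nrow(cm$pairs)) {
        all_pairs[[f]] <- cbind(forest = f, cm$pairs)
        all_summ[[f]] <- cbind(forest = f, pairing_summary(cm$pairs))
      }
    }
    pairs <- do.call(rbind, all_pairs)
    write.csv(pairs, file.path(out_dir, "cooccurrence_pairs.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, all_summ),
              file.path(out_dir, "cooccurrence_summary.csv"),
              row.names = FALSE)
    manifest$n_cooccurrence_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
    say("cooccurrence: ", manifest$n_cooccurrence_pairs, " pairs")
  }

  if ("networks" %in% stages) {
    views <- aggregate_census(census, "quarry")
    rows <- list()
    for (i in seq_along(views)) {
      bs <- bootstrap_networks(views[[i]], sample_size = sample_size,
                               n_boot = n_boot, seed = stage_seed(seed, i),
                               n_orders = n_orders)
      s <- bs$summary
      s <- cbind(quarry_key = names(views)[i], s,
                 n_degenerate = bs$n_degenerate, seed = bs$seed)
      rows[[i]] <- s
    }
    netsum <- do.call(rbind, rows)
    write.csv(netsum, file.path(out_dir, "network_bootstrap.csv"),
              row.names = FALSE)
    dp <- degree_profile(census, drop_singletons = drop_singletons)
    deg <- data.frame(dt_code = rownames(dp$degree), ffg = unname(dp$ffg),
                      dp$degree, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.csv(deg, file.path(out_dir, "degree_profile.csv"),
              row.names = FALSE)
    say("networks: ", length(views), " quarries bootstrapped")
  }

  if ("ordination" %in% stages) {
    ffg_tab <- composition_table(census, "ffg")
    d_ffg <- bray_curtis(ffg_tab)
    ord <- nmds_ordination(d_ffg, k = 2, seed = stage_seed(seed, 101L))
    coords <- data.frame(quarry_key = rownames(ord$coordinates),
                         ffg_tab$meta[c("forest", "env")],
                         ord$coordinates, stringsAsFactors = FALSE)
    names(coords)[4:5] <- c("nmds1", "nmds2")
    coords$stress <- ord$stress
    write.csv(coords, file.path(out_dir, "ordination_ffg.csv"),
              row.names = FALSE)

    an <- list(
      anosim_row(d_ffg, ffg_tab$meta$forest, "ffg:all", "forest",
                 n_perm, stage_seed(seed, 102L)),
      anosim_row(d_ffg, ffg_tab$meta$env, "ffg:all", "env",
                 n_perm, stage_seed(seed, 103L))
    )
    for (f in sort(unique(ffg_tab$meta$forest))) {
      sel <- ffg_tab$meta$forest == f
      an[[length(an) + 1L]] <- anosim_row(
        d_ffg[sel, sel, drop = FALSE], ffg_tab$meta$env[sel],
        paste0("ffg:", f), "env", n_perm, stage_seed(seed, 104L))
    }
    # plant composition: only co-ordinate forests sharing species
    comps <- plant_pool_components(census)
    ci <- 0L
    for (grp in comps) {
      ci <- ci + 1L
      sub <- subset_census(census,
                           census$leaves$leaf_id[census$leaves$forest %in% grp])
      ptab <- composition_table(sub, "plant")
      if (nrow(ptab$props) < 4L) next
      d_p <- bray_curtis(ptab)
      label <- paste0("plant:", paste(grp, collapse = "+"))
      if (length(grp) > 1L) {
        an[[length(an) + 1L]] <- anosim_row(d_p, ptab$meta$forest, label,
                                            "forest", n_perm,
                                            stage_seed(seed, 200L + ci))
      }
      an[[length(an) + 1L]] <- anosim_row(d_p, ptab$meta$env, label, "env",
                                          n_perm, stage_seed(seed, 300L + ci))
      for (f in grp) {
        sel <- ptab$meta$forest == f
        an[[length(an) + 1L]] <- anosim_row(
          d_p[sel, sel, drop = FALSE], ptab$meta$env[sel],
          paste0("plant:", f), "env", n_perm, stage_seed(seed, 400L + ci))
      }
    }
    anosim_tab <- do.call(rbind, an)
    write.csv(anosim_tab, file.path(out_dir, "anosim.csv"),
              row.names = FALSE)
    manifest$ffg_stress <- ord$stress
    say("ordination: stress ", round(ord$stress, 4))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Paired outbreak/control simulation experiment
#'
#' Tests whether an insect outbreak concentrated on a few host taxa is
#' detectable through bootstrap bipartite network metrics. For each of
#' `n_seeds` seeds, a census is generated under the outbreak configuration
#' and under its control (the identical configuration with the outbreak
#' removed); for each forest, quarry-level bootstrap network metrics are
#' averaged into forest-level means, alongside the forest's total damage
#' frequency. The detection rate is the fraction of seeds in which the target
#' forest's mean bootstrap H2' under outbreak exceeds its own control.
#'
#' @param base_config A [sim_config()] carrying an [outbreak_spec()]
#'   (default: `default_study_config(outbreak = TRUE)`).
#' @param n_seeds Paired simulation seeds (default 20).
#' @param seed Top-level seed from which per-run seeds are derived.
#' @param sample_size,n_boot,n_orders Bootstrap parameters (defaults 300,
#'   100, 50).
#' @param metrics Network metric subset to bootstrap.
#' @param forests Forest ids to evaluate (default all; restricting to the
#'   outbreak target makes the experiment much cheaper).
#' @return List of class `outbreak_experiment`: `results` (one row per
#'   seed x forest x scenario), `target_forest`, `detection_rate` (when H2'
#'   is among the metrics), `freq_diff` (mean outbreak-minus-control total
#'   damage frequency in the target forest, in proportion units).
#' @export
outbreak_experiment <- function(base_config = default_study_config(TRUE),
                                n_seeds = 20L, seed = 1L,
                                sample_size = 300L, n_boot = 100L,
                                n_orders = 50L,
                                metrics = NETWORK_METRICS,
                                forests = NULL) {
  stopifnot(inherits(base_config, "sim_config"))
  if (is.null(base_config$outbreak)) {
    stop("base_config must carry an outbreak_spec")
  }
  metrics <- match.arg(metrics, NETWORK_METRICS, several.ok = TRUE)
  target <- base_config$outbreak$target_forest_id
  control_config <- base_config
  control_config$outbreak <- NULL

  rows <- list()
  for (s in seq_len(n_seeds)) {
    sim_seed <- stage_seed(seed, s)
    for (scenario in c("outbreak", "control")) {
      cfg <- if (scenario == "outbreak") base_config else control_config
      cfg$seed <- sim_seed
      cen <- generate_census(cfg)
      cen <- filter_quarries(cen, sample_size)$census
      fids <- sort(unique(cen$leaves$forest))
      if (!is.null(forests)) fids <- intersect(fids, forests)
      for (f in fids) {
        fview <- subset_census(cen,
                               cen$leaves$leaf_id[cen$leaves$forest == f])
        qviews <- aggregate_census(fview, "quarry")
        qmeans <- vapply(seq_along(qviews), function(i) {
          bs <- bootstrap_networks(qviews[[i]], sample_size = sample_size,
                                   n_boot = n_boot,
                                   seed = stage_seed(sim_seed, i),
                                   metrics = metrics, n_orders = n_orders)
          setNames(bs$summary$mean, bs$summary$metric)[metrics]
        }, setNames(numeric(length(metrics)), metrics))
        qmeans <- matrix(qmeans, nrow = length(metrics),
                         dimnames = list(metrics, NULL))
        row <- data.frame(seed_index = s, sim_seed = sim_seed, forest = f,
                          scenario = scenario,
                          freq_total = damage_frequency(fview, "total"),
                          stringsAsFactors = FALSE)
        for (mt in metrics) row[[paste0("mean_", mt)]] <- mean(qmeans[mt, ])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  detection_rate <- NA_real_
  freq_diff <- NA_real_
  tgt <- results[results$forest == target, , drop = FALSE]
  if (nrow(tgt)) {
    ob <- tgt[tgt$scenario == "outbreak", ]
    ct <- tgt[tgt$scenario == "control", ]
    ob <- ob[order(ob$seed_index), ]; ct <- ct[order(ct$seed_index), ]
    if ("h2prime" %in% metrics) {
      detection_rate <- mean(ob$mean_h2prime > ct$mean_h2prime)
    }
    freq_diff <- mean(ob$freq_total - ct$freq_total)
  }
  structure(list(results = results, target_forest = target,
                 detection_rate = detection_rate, freq_diff = freq_diff,
                 n_seeds = n_seeds, sample_size = sample_size,
                 n_boot = n_boot, seed = seed),
            class = "outbreak_experiment")
}

#' @export
print.outbreak_experiment <- function(x, ...) {
  cat("<outbreak_experiment> target", x$target_forest, "-", x$n_seeds,
      "paired seeds\n")
  if (!is.na(x$detection_rate)) {
    cat("  H2' detection rate:", format(x$detection_rate, digits = 3), "\n")
  }
  cat("  mean total-frequency shift:",
      format(x$freq_diff, digits = 3), "\n")
  invisible(x)
}
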