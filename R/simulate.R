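#' Damage-type specification for simulation
#'
#' Describes one DT in the synthetic pool. Occurrence and abundance are
#' modelled separately, mirroring the occurrence (presence/absence) vs.
#' abundance (incident count) distinction of the census protocol: on a
#' permitted host leaf the DT occurs with probability `base_occurrence_prob`,
#' and given occurrence the incident count is a zero-truncated Poisson with
#' mean `abundance_mean`.
#'
#' @param dt_code DT code string, e.g. `"DT03"`.
#' @param ffg One of [ffg_levels()].
#' @param spec_class `"generalized"` or `"specialized"`.
#' @param host_breadth Fraction (0, 1] of each forest's plant pool the DT can
#'   occur on; 1 = fully generalist. The host set is a fixed pseudo-random
#'   subset of size `ceiling(host_breadth * pool size)` per (forest, DT).
#' @param base_occurrence_prob Per-leaf Bernoulli occurrence probability on a
#'   permitted host.
#' @param abundance_mean Mean (>= 1) of the zero-truncated Poisson incident
#'   count given occurrence.
#' @return A `dt_spec` list.
#' @export
dt_spec <- function(dt_code, ffg, spec_class, host_breadth = 1,
                    base_occurrence_prob = 0.1, abundance_mean = 2) {
  stopifnot(is.character(dt_code), length(dt_code) == 1L, nzchar(dt_code))
  if (!ffg %in% FFG_LEVELS) stop("unknown ffg: ", ffg)
  if (!spec_class %in% SPEC_CLASS_LEVELS) stop("unknown spec_class: ", spec_class)
  if (!(host_breadth > 0 && host_breadth <= 1)) {
    stop("host_breadth must be in (0, 1]")
  }
  if (base_occurrence_prob < 0 || base_occurrence_prob > 1) {
    stop("base_occurrence_prob must be in [0, 1]")
  }
  if (abundance_mean < 1) {
    stop("abundance_mean must be >= 1 (zero-truncated Poisson mean)")
  }
  structure(list(dt_code = dt_code, ffg = ffg, spec_class = spec_class,
                 host_breadth = host_breadth,
                 base_occurrence_prob = base_occurrence_prob,
                 abundance_mean = abundance_mean),
            class = "dt_spec")
}

#' Forest specification for simulation
#'
#' @param forest_id Forest identifier.
#' @param plant_pool Named numeric vector: taxa and positive forest-level
#'   relative-abundance weights.
#' @param envs data.frame with columns `env_id`, `n_quarries`,
#'   `leaves_per_quarry`, `env_shift` (Dirichlet concentration: the env-level
#'   plant composition is drawn from Dirichlet(`env_shift` * forest weights);
#'   smaller values push environments further from the forest pool).
#' @return A `forest_spec` list.
#' @export
forest_spec <- function(forest_id, plant_pool, envs) {
  stopifnot(is.character(forest_id), nzchar(forest_id))
  if (is.null(names(plant_pool)) || any(!nzchar(names(plant_pool)))) {
    stop("plant_pool must be a named weight vector")
  }
  if (any(plant_pool <= 0)) stop("plant pool weights must be positive")
  if (anyDuplicated(names(plant_pool))) stop("duplicate taxa in plant_pool")
  envs <- as.data.frame(envs, stringsAsFactors = FALSE)
  need <- c("env_id", "n_quarries", "leaves_per_quarry", "env_shift")
  if (!all(need %in% names(envs))) {
    stop("envs must have columns: ", paste(need, collapse = ", "))
  }
  if (any(envs$n_quarries < 1) || any(envs$leaves_per_quarry < 1) ||
      any(envs$env_shift <= 0)) {
    stop("envs: n_quarries, leaves_per_quarry >= 1 and env_shift > 0 required")
  }
  structure(list(forest_id = forest_id,
                 plant_pool = plant_pool / sum(plant_pool),
                 envs = envs[need]),
            class = "forest_spec")
}

#' Outbreak scenario specification
#'
#' Emulates a defoliator outbreak concentrated on one or two preferred host
#' taxa: the occurrence probability of the outbreak DT set (surface and hole
#' feeding types, matching the feeding modes of early- and late-instar
#' caterpillars) is multiplied by `occurrence_multiplier` on the preferred
#' hosts and by the smaller `background_multiplier` on other permitted hosts;
#' resulting probabilities are clipped at 1.
#'
#' @param target_forest_id Forest receiving the outbreak.
#' @param outbreak_dts DT codes elevated by the outbreak.
#' @param preferred_hosts One or two taxa from the target forest's pool.
#' @param occurrence_multiplier Factor (> `background_multiplier`) on
#'   preferred hosts.
#' @param background_multiplier Factor (>= 1) on other permitted hosts.
#' @return An `outbreak_spec` list.
#' @export
outbreak_spec <- function(target_forest_id, outbreak_dts, preferred_hosts,
                          occurrence_multiplier = 25,
                          background_multiplier = 1.05) {
  stopifnot(length(outbreak_dts) >= 1L,
            length(preferred_hosts) >= 1L, length(preferred_hosts) <= 2L)
  if (!(occurrence_multiplier > background_multiplier &&
        background_multiplier >= 1)) {
    stop("need occurrence_multiplier > background_multiplier >= 1")
  }
  structure(list(target_forest_id = target_forest_id,
                 outbreak_dts = as.character(outbreak_dts),
                 preferred_hosts = as.character(preferred_hosts),
                 occurrence_multiplier = occurrence_multiplier,
                 background_multiplier = background_multiplier),
            class = "outbreak_spec")
}

#' Full synthetic-study configuration
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration (which includes the seed).
#' @param forests List of [forest_spec()] objects.
#' @param dt_pool List of [dt_spec()] objects.
#' @param outbreak Optional [outbreak_spec()].
#' @param quarry_concentration Dirichlet concentration multiplier for the
#'   quarry-level redraw around its environment's composition; large values
#'   (default 150) keep replicate quarries compositionally tight within an
#'   environment.
#' @param preservation_discount Multiplier (< 1, default 0.5) on the
#'   occurrence probability of piercing-and-sucking DTs, reflecting the
#'   preservation bias against that damage mode in sediment-derived leaves.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, forests, dt_pool, outbreak = NULL,
                       quarry_concentration = 150,
                       preservation_discount = 0.5) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!length(forests)) stop("at least one forest is required")
  for (f in forests) stopifnot(inherits(f, "forest_spec"))
  fid <- vapply(forests, `[[`, "", "forest_id")
  if (anyDuplicated(fid)) stop("duplicate forest_id")
  if (!length(dt_pool)) stop("dt_pool must be non-empty")
  for (d in dt_pool) stopifnot(inherits(d, "dt_spec"))
  dts <- vapply(dt_pool, `[[`, "", "dt_code")
  if (anyDuplicated(dts)) stop("duplicate dt_code in dt_pool")
  if (!is.null(outbreak)) {
    stopifnot(inherits(outbreak, "outbreak_spec"))
    if (!outbreak$target_forest_id %in% fid) {
      stop("outbreak target forest not in config: ", outbreak$target_forest_id)
    }
    missing_dt <- setdiff(outbreak$outbreak_dts, dts)
    if (length(missing_dt)) {
      stop("outbreak DT(s) not in dt_pool: ", paste(missing_dt, collapse = ", "))
    }
    tf <- forests[[match(outbreak$target_forest_id, fid)]]
    missing_host <- setdiff(outbreak$preferred_hosts, names(tf$plant_pool))
    if (length(missing_host)) {
      stop("preferred host(s) not in target forest pool: ",
           paste(missing_host, collapse = ", "))
    }
  }
  if (quarry_concentration <= 0) stop("quarry_concentration must be > 0")
  if (preservation_discount <= 0 || preservation_discount > 1) {
    stop("preservation_discount must be in (0, 1]")
  }
  structure(list(seed = as.integer(seed), forests = forests,
                 dt_pool = dt_pool, outbreak = outbreak,
                 quarry_concentration = quarry_concentration,
                 preservation_discount = preservation_discount),
            class = "sim_config")
}

#' Catalog implied by a simulation config
#' @param config A `sim_config`.
#' @return data.frame with columns `dt_code`, `ffg`, `spec_class`.
#' @export
sim_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(
    dt_code = vapply(config$dt_pool, `[[`, "", "dt_code"),
    ffg = vapply(config$dt_pool, `[[`, "", "ffg"),
    spec_class = vapply(config$dt_pool, `[[`, "", "spec_class"),
    stringsAsFactors = FALSE
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha # pathological underflow guard
  g / sum(g)
}

# Solve the underlying Poisson rate whose zero-truncated mean equals m.
ztpois_lambda <- function(m) {
  if (m <= 1 + 1e-12) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-10, upper = max(10, 2 * m), tol = 1e-10)$root
}

# Zero-truncated Poisson sampler by inverse CDF restricted above F(0).
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer())
  if (lambda <= 0) return(rep(1L, n))
  f0 <- dpois(0, lambda)
  pmax(1L, qpois(runif(n, f0, 1), lambda))
}

#' Generate a synthetic leaf census
#'
#' Sampling proceeds hierarchically, matching the field design the package
#' analyses: each forest has a plant pool with relative-abundance weights;
#' each depositional environment draws its own composition from a Dirichlet
#' centred on the forest weights (concentration `env_shift`); each replicate
#' quarry redraws weakly around its environment's composition
#' (`quarry_concentration`); each leaf gets a taxon from the quarry
#' composition. Every DT owns a fixed pseudo-random host subset per forest
#' (size `ceiling(host_breadth * pool)`), occurs on permitted leaves with its
#' Bernoulli probability (piercing-and-sucking discounted by
#' `preservation_discount`, outbreak multipliers applied when configured),
#' and contributes a zero-truncated Poisson incident count.
#'
#' Deterministic given the configuration: identical configs (including seed)
#' yield identical censuses.
#'
#' @param config A [sim_config()].
#' @return A validated [leaf_census()].
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  catalog <- sim_catalog(config)
  nd <- length(config$dt_pool)
  lambdas <- vapply(config$dt_pool, function(d) ztpois_lambda(d$abundance_mean),
                    0)

  leaves_acc <- vector("list", 0L)
  dmg_leaf <- character(0); dmg_dt <- character(0); dmg_n <- integer(0)

  for (f in config$forests) {
    pool <- names(f$plant_pool)
    w <- f$plant_pool
    np <- length(pool)
    # fixed host set per (forest, DT)
    hosts <- matrix(FALSE, np, nd, dimnames = list(pool, catalog$dt_code))
    for (j in seq_len(nd)) {
      d <- config$dt_pool[[j]]
      h <- ceiling(d$host_breadth * np)
      hosts[sample.int(np, h), j] <- TRUE
    }
    ob <- config$outbreak
    is_target <- !is.null(ob) && identical(ob$target_forest_id, f$forest_id)

    for (ei in seq_len(nrow(f$envs))) {
      e <- f$envs[ei, ]
      comp_env <- rdirichlet1(e$env_shift * w)
      for (qi in seq_len(e$n_quarries)) {
        comp_q <- rdirichlet1(config$quarry_concentration * comp_env)
        nl <- e$leaves_per_quarry
        taxon_idx <- sample.int(np, nl, replace = TRUE, prob = comp_q)
        quarry_id <- sprintf("%s_%s_Q%d", f$forest_id, e$env_id, qi)
        leaf_ids <- sprintf("%s_L%04d", quarry_id, seq_len(nl))
        leaves_acc[[length(leaves_acc) + 1L]] <- data.frame(
          leaf_id = leaf_ids, forest = f$forest_id, env = e$env_id,
          quarry = quarry_id, plant_taxon = pool[taxon_idx],
          stringsAsFactors = FALSE
        )
        for (j in seq_len(nd)) {
          d <- config$dt_pool[[j]]
          permitted <- which(hosts[taxon_idx, j])
          if (!length(permitted)) next
          p <- d$base_occurrence_prob
          if (d$ffg == "piercing_sucking") p <- p * config$preservation_discount
          pvec <- rep(p, length(permitted))
          if (is_target && d$dt_code %in% ob$outbreak_dts) {
            pref <- pool[taxon_idx[permitted]] %in% ob$preferred_hosts
            pvec <- pvec * ifelse(pref, ob$occurrence_multiplier,
                                  ob$background_multiplier)
          }
          pvec <- pmin(pvec, 1)
          # occurrence uniforms and counts are drawn for every permitted
          # leaf, so RNG consumption does not depend on the probabilities:
          # outbreak and control runs under the same seed share all
          # randomness except the outbreak's incremental occurrences
          # (common random numbers; enables tightly paired comparisons)
          u <- runif(length(permitted))
          cnt_all <- rztpois(length(permitted), lambdas[j])
          hit <- u < pvec
          if (!any(hit)) next
          occ <- permitted[hit]
          dmg_leaf <- c(dmg_leaf, leaf_ids[occ])
          dmg_dt <- c(dmg_dt, rep(d$dt_code, length(occ)))
          dmg_n <- c(dmg_n, cnt_all[hit])
        }
      }
    }
  }
  leaf_census(
    leaves = do.call(rbind, leaves_acc),
    damage = data.frame(leaf_id = dmg_leaf, dt_code = dmg_dt, count = dmg_n,
                        stringsAsFactors = FALSE),
    catalog = catalog
  )
}

# The packaged DT pool: codes grouped by FFG; galls and mines specialized,
# chewing and surface damage mostly generalized, piercing-and-sucking
# occurrence later discounted for preservation.
default_dt_pool <- function() {
  c(
    # hole feeding: common generalists plus one narrower type
    list(dt_spec("DT02", "hole", "generalized", 1, 0.17, 2.5),
         dt_spec("DT03", "hole", "generalized", 1, 0.10, 2.5),
         dt_spec("DT05", "hole", "generalized", 1, 0.10, 2.2),
         dt_spec("DT07", "hole", "specialized", 0.25, 0.15, 2.0)),
    # margin feeding
    list(dt_spec("DT12", "margin", "generalized", 1, 0.15, 2.0),
         dt_spec("DT13", "margin", "generalized", 1, 0.08, 2.0),
         dt_spec("DT14", "margin", "generalized", 0.9, 0.07, 1.8),
         dt_spec("DT15", "margin", "generalized", 0.9, 0.06, 1.8)),
    # skeletonization
    list(dt_spec("DT16", "skeletonization", "generalized", 0.8, 0.06, 1.8),
         dt_spec("DT17", "skeletonization", "generalized", 0.8, 0.04, 1.6),
         dt_spec("DT19", "skeletonization", "specialized", 0.2, 0.10, 1.6)),
    # surface feeding: DT33 is the outbreak-capable surface feeder --
    # uncommon at background levels but leaving many feeding patches per
    # occupied leaf (high incident count)
    list(dt_spec("DT29", "surface", "generalized", 0.9, 0.05, 1.8),
         dt_spec("DT30", "surface", "generalized", 0.7, 0.05, 1.6),
         dt_spec("DT31", "surface", "specialized", 0.2, 0.08, 1.5),
         dt_spec("DT33", "surface", "generalized", 1, 0.04, 8.0)),
    # piercing and sucking (occurrence discounted for preservation)
    list(dt_spec("DT46", "piercing_sucking", "generalized", 1, 0.13, 1.8),
         dt_spec("DT48", "piercing_sucking", "generalized", 0.8, 0.06, 1.6),
         dt_spec("DT50", "piercing_sucking", "specialized", 0.2, 0.08, 1.5)),
    # galls: specialized, locally dense where they occur
    list(dt_spec("DT80", "gall", "specialized", 0.12, 0.25, 3.0),
         dt_spec("DT81", "gall", "specialized", 0.12, 0.20, 2.5),
         dt_spec("DT83", "gall", "specialized", 0.10, 0.18, 2.5),
         dt_spec("DT85", "gall", "specialized", 0.10, 0.12, 2.0)),
    # mines: specialized
    list(dt_spec("DT90", "mine", "specialized", 0.12, 0.20, 1.8),
         dt_spec("DT91", "mine", "specialized", 0.12, 0.15, 1.6),
         dt_spec("DT93", "mine", "specialized", 0.10, 0.12, 1.5),
         dt_spec("DT95", "mine", "specialized", 0.10, 0.10, 1.5))
  )
}

default_plant_pools <- function() {
  shared <- sprintf("temp_sp%02d", 1:8)   # taxa shared by the temperate forests
  list(
    # cool-temperate forest: smallest pool (lowest plant diversity), one
    # strongly dominant host that the outbreak scenario prefers
    TF1 = setNames(c(16, 14, 12, 10, 8, 6, 5, 4, 3, 3, 2, 2),
                   c(shared, sprintf("tf1_sp%02d", 1:4))),
    # coastal-temperate forest: larger pool, partial overlap with TF1
    TF2 = setNames(c(10, 9, 9, 8, 8, 7, 7, 6, rep(4, 6), rep(2, 6)),
                   c(shared, sprintf("tf2_sp%02d", 1:12))),
    # wet-tropical forest: large pool, no species shared with the temperates
    WT1 = setNames(c(rep(6, 8), rep(3, 16), rep(1.5, 21)),
                   sprintf("trop_sp%02d", 1:45))
  )
}

#' Default synthetic study configuration
#'
#' Packages the sampling design the analyses were built for: three forests --
#' a cool-temperate forest `TF1` with three depositional environments of
#' three replicate quarries each plus a single upland quarry, a
#' coastal-temperate `TF2` and a wet-tropical `WT1` with three environments
#' of three quarries each -- at 400 leaves per quarry (28 quarries, 11,200
#' leaves). `TF1` has the smallest plant pool (lowest plant diversity); the
#' tropical pool shares no species with the temperate pools, while the two
#' temperate pools overlap. With `outbreak = TRUE` an [outbreak_spec()]
#' targets `TF1`: surface (`DT33`) and hole (`DT03`, `DT05`) feeding types
#' are concentrated on the dominant preferred host `temp_sp01`.
#'
#' @param outbreak Logical; attach the outbreak scenario?
#' @param seed Seed stored in the config (default 1).
#' @param leaves_per_quarry Leaves per quarry (default 400).
#' @return A [sim_config()].
#' @export
default_study_config <- function(outbreak = FALSE, seed = 1L,
                                 leaves_per_quarry = 400L) {
  pools <- default_plant_pools()
  env3 <- function(shift) data.frame(
    env_id = c("swamp", "tributary", "river"),
    n_quarries = 3L, leaves_per_quarry = as.integer(leaves_per_quarry),
    env_shift = shift, stringsAsFactors = FALSE
  )
  # TF1's depositional environments filter the (species-poor) community only
  # weakly, so its environments stay compositionally close to the forest
  # pool; the coastal-temperate and tropical forests get stronger
  # environment-level filtering
  tf1_envs <- rbind(
    env3(40),
    data.frame(env_id = "upland", n_quarries = 1L,
               leaves_per_quarry = as.integer(leaves_per_quarry),
               env_shift = 40, stringsAsFactors = FALSE)
  )
  forests <- list(
    forest_spec("TF1", pools$TF1, tf1_envs),
    forest_spec("TF2", pools$TF2, env3(8)),
    forest_spec("WT1", pools$WT1, env3(10))
  )
  ob <- if (outbreak) {
    outbreak_spec("TF1", outbreak_dts = c("DT33", "DT03", "DT05"),
                  preferred_hosts = "temp_sp04",
                  occurrence_multiplier = 25, background_multiplier = 1.05)
  } else NULL
  sim_config(seed = seed, forests = forests, dt_pool = default_dt_pool(),
             outbreak = ob)
}
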