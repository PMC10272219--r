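test_that("incidence matrices sum incident counts per taxon and DT", {
  lv <- data.frame(leaf_id = c("L1", "L2"), forest = "F", env = "E",
                   quarry = "Q", plant_taxon = "P1")
  dm <- data.frame(leaf_id = c("L1", "L2", "L2"),
                   dt_code = c("DT2", "DT2", "DT3"), count = c(2, 1, 1))
  cat <- data.frame(dt_code = c("DT2", "DT3"), ffg = "hole",
                    spec_class = "generalized")
  m <- build_incidence(leaf_census(lv, dm, cat))
  expect_equal(m, matrix(c(3, 1), 1, 2, dimnames = list("P1", c("DT2", "DT3"))))
  # undamaged taxa are excluded from the rows
  lv2 <- rbind(lv, data.frame(leaf_id = "L3", forest = "F", env = "E",
                              quarry = "Q", plant_taxon = "P2"))
  m2 <- build_incidence(leaf_census(lv2, dm, cat))
  expect_equal(rownames(m2), "P1")
  expect_error(build_incidence(leaf_census(lv2[3, ], NULL, cat)), "no damaged")
  # column marginals equal an independent per-DT tally
  cen <- generate_census(tiny_study_config(seed = 3, leaves_per_quarry = 50))
  v <- aggregate_census(cen, "quarry")[[2]]
  m3 <- build_incidence(v)
  tall <- tapply(v$damage$count, v$damage$dt_code, sum)
  expect_equal(unname(colSums(m3)), as.numeric(tall[colnames(m3)]))
})

test_that("connectance counts realized links", {
  expect_equal(connectance(matrix(1, 3, 4)), 1)
  expect_equal(connectance(matrix(c(1, 0, 0, 0), 2, 2)), 0.25)
  m <- random_incidence(5, 7, seed = 1)
  expect_equal(connectance(m), sum(m > 0) / 35)
})

test_that("NODF hits its definitional anchors and matches two oracles", {
  tri <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(nestedness_nodf(tri), 100)
  expect_equal(nestedness_nodf(diag(2)), 0)
  set.seed(5)
  for (rep in 1:6) {
    m <- random_incidence(sample(4:6, 1), sample(4:6, 1), fill = 0.5)
    v <- nestedness_nodf(m)
    expect_equal(v, oracle_nodf(m), tolerance = 1e-9)
    vg <- vegan::nestednodf(m > 0)$statistic[["NODF"]]
    expect_equal(v, vg, tolerance = 1e-9)
    # permutation invariance
    mp <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nestedness_nodf(mp), v, tolerance = 1e-9)
  }
  expect_true(is.na(nestedness_nodf(matrix(1, 1, 4))))
})

test_that("partner diversity averages per-plant interaction entropies", {
  m1 <- diag(c(3, 2, 5))           # one DT per plant
  expect_equal(partner_diversity_plants(m1), 0)
  m2 <- matrix(c(2, 2), 1, 2)
  expect_equal(partner_diversity_plants(m2), log(2))
  m3 <- rbind(c(1, 1, 1), c(2, 2, 0), c(0, 0, 4))
  expect_equal(partner_diversity_plants(m3), (log(3) + log(2) + 0) / 3)
})

test_that("robustness matches closed forms and the all-orders oracle", {
  expect_equal(robustness_dts(matrix(1, 5, 3)), 1 - 1 / 10)  # complete
  expect_equal(robustness_dts(matrix(1, 1, 4)), 0.5)          # single plant
  set.seed(9)
  for (rep in 1:4) {
    m <- random_incidence(4, sample(3:5, 1), fill = 0.6)
    expect_equal(robustness_dts(m, exact = TRUE), oracle_robustness(m),
                 tolerance = 1e-9)
    # sampled estimate close to the exact enumeration
    sampled <- robustness_dts(m, n_orders = 400, seed = 1, exact = FALSE)
    expect_equal(sampled, oracle_robustness(m), tolerance = 0.05)
  }
  # complete network is more robust than a one-host-per-DT network
  expect_gt(robustness_dts(matrix(1, 4, 4)), robustness_dts(diag(4)))
})

test_that("H2' endpoints and bounds match exhaustive enumeration", {
  expect_equal(as.numeric(h2prime(diag(4) * 4)), 1)
  expect_equal(as.numeric(h2prime(matrix(1, 4, 4))), 0)
  # 2x2 exhaustive marginal-preserving enumeration, totals <= 8
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(sample(0:3, 4, replace = TRUE), 2, 2)
    if (sum(m) < 2 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    r <- rowSums(m); c <- colSums(m)
    oracle <- oracle_h2_bounds(r, c)
    H2max <- attr(h2prime(m), "H2max")
    H2min <- attr(h2prime(m), "H2min")
    expect_equal(H2max, oracle[["max"]], tolerance = 1e-9)
    expect_equal(H2min, oracle[["min"]], tolerance = 1e-9)
  }
  # larger matrices: heuristic bounds must bracket the observed entropy
  # and H2' must stay in [0, 1]
  set.seed(23)
  for (rep in 1:40) {
    m <- random_incidence(sample(3:15, 1), sample(3:15, 1),
                          fill = runif(1, 0.2, 0.8))
    h <- h2prime(m)
    if (is.na(h)) next
    expect_gte(as.numeric(h), 0)
    expect_lte(as.numeric(h), 1)
    expect_lte(attr(h, "H2min"), attr(h, "H2max"))
  }
  expect_true(is.na(h2prime(matrix(c(1, 0, 0, 0), 2, 2) * 0))) # degenerate
})

test_that("bootstrap networks are deterministic and consistent", {
  cen <- generate_census(tiny_study_config(seed = 10, leaves_per_quarry = 60))
  v <- aggregate_census(cen, "quarry")[[1]]
  b1 <- bootstrap_networks(v, sample_size = 40, n_boot = 10, seed = 99,
                           n_orders = 20)
  b2 <- bootstrap_networks(v, sample_size = 40, n_boot = 10, seed = 99,
                           n_orders = 20)
  expect_equal(b1, b2)
  # sample_size = quarry size: no sampling variation in sampling-free metrics
  bfull <- bootstrap_networks(v, sample_size = 60, n_boot = 5, seed = 1,
                              metrics = c("connectance", "h2prime"))
  expect_equal(sd(bfull$per_rep$connectance), 0)
  expect_equal(sd(bfull$per_rep$h2prime), 0)
  expect_equal(bfull$per_rep$connectance[1], connectance(build_incidence(v)))
  expect_error(bootstrap_networks(v, sample_size = 100), "filter_quarries")
})

test_that("bootstrap mean connectance recovers the full-quarry value on a
           homogeneous quarry", {
  # few common interactions: every 40-leaf draw sees (almost) all cells
  envs <- data.frame(env_id = "e", n_quarries = 1L, leaves_per_quarry = 400L,
                     env_shift = 100)
  pool <- list(dt_spec("DT1", "hole", "generalized", 1, 0.35, 2),
               dt_spec("DT2", "margin", "generalized", 1, 0.30, 2),
               dt_spec("DT3", "surface", "generalized", 1, 0.30, 2))
  cfg <- sim_config(seed = 2, forests = list(
    forest_spec("F", c(a = 1, b = 1, c = 1), envs)), dt_pool = pool)
  v <- generate_census(cfg)
  bs <- bootstrap_networks(v, sample_size = 300, n_boot = 100, seed = 5,
                           metrics = "connectance")
  full <- connectance(build_incidence(v))
  se <- bs$summary$sd / sqrt(100)
  expect_lte(abs(bs$summary$mean - full), max(3 * se, 1e-9))
})

test_that("degree profiles count host taxa per DT per quarry", {
  cen <- generate_census(tiny_study_config(seed = 12, leaves_per_quarry = 80))
  dp <- degree_profile(cen)
  qv <- aggregate_census(cen, "quarry")
  expect_equal(ncol(dp$degree), length(qv))
  # spot-check one quarry against a direct tally
  k <- names(qv)[3]
  v <- qv[[k]]
  taxon <- v$leaves$plant_taxon[match(v$damage$leaf_id, v$leaves$leaf_id)]
  direct <- tapply(taxon, v$damage$dt_code, function(x) length(unique(x)))
  for (d in names(direct)) {
    expect_equal(dp$degree[d, k], unname(direct[d]))
  }
  # absent DTs have degree zero
  absent <- setdiff(rownames(dp$degree), unique(v$damage$dt_code))
  if (length(absent)) expect_true(all(dp$degree[absent, k] == 0))
  # degree bounded by the quarry's taxon count
  expect_true(all(dp$degree[, k] <= length(unique(v$leaves$plant_taxon))))
  # generalists out-spread specialists across quarries
  gen <- rownames(dp$degree) %in%
    cen$catalog$dt_code[cen$catalog$spec_class == "generalized"]
  expect_gt(median(dp$degree[gen, ]), median(dp$degree[!gen, ]))
})
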