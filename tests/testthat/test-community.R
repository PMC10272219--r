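test_that("composition tables hold proportions with the right geometry", {
  cen <- generate_census(tiny_study_config(seed = 14, leaves_per_quarry = 60))
  ft <- composition_table(cen, "ffg")
  expect_true(all(ft$props >= 0 & ft$props <= 1))
  expect_equal(colnames(ft$props), ffg_levels())
  pt <- composition_table(cen, "plant")
  expect_equal(unname(rowSums(pt$props)), rep(1, nrow(pt$props)),
               tolerance = 1e-12)
  # FFG column = fraction of leaves bearing that FFG, checked directly
  v <- aggregate_census(cen, "quarry")[[1]]
  k <- ft$meta$quarry_key == names(aggregate_census(cen, "quarry"))[1]
  expect_equal(ft$props[k, "hole"], damage_frequency(v, "hole"))
})

test_that("disjoint plant pools force between-forest Bray-Curtis of 1", {
  envs <- data.frame(env_id = "e", n_quarries = 2L, leaves_per_quarry = 40L,
                     env_shift = 10)
  cfg <- sim_config(seed = 4, forests = list(
    forest_spec("T", stats::setNames(c(1, 1), c("ta", "tb")), envs),
    forest_spec("W", stats::setNames(c(1, 1), c("wa", "wb")), envs)),
    dt_pool = herbnet:::default_dt_pool())
  pt <- composition_table(generate_census(cfg), "plant")
  d <- bray_curtis(pt)
  cross <- outer(pt$meta$forest, pt$meta$forest, "!=")
  expect_true(all(d[cross] == 1))
})

test_that("Bray-Curtis follows its formula and flags empty rows", {
  m <- rbind(x = c(2, 1), y = c(1, 1), z = c(2, 1))
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 0.2)
  expect_equal(d["x", "z"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  m2 <- rbind(a = c(1, 2), b = c(0, 0))
  expect_warning(d2 <- bray_curtis(m2), "zeros")
  expect_true(is.na(d2["a", "b"]))
})

test_that("NMDS embeds exact configurations and respects rank invariance", {
  pts <- matrix(c(0, 0, 1, 0, 0.3, 0.8), 3, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  o <- suppressWarnings(nmds_ordination(d, k = 2, n_restarts = 5, seed = 1))
  expect_lte(o$stress, 1e-6)
  o2 <- suppressWarnings(nmds_ordination(2 * d, k = 2, n_restarts = 5,
                                         seed = 1))
  expect_equal(o$stress, o2$stress, tolerance = 1e-6)
  # more dimensions cannot fit worse
  set.seed(31)
  pts8 <- matrix(rnorm(8 * 4), 8, 4)
  d8 <- as.matrix(dist(pts8))
  s2 <- suppressWarnings(nmds_ordination(d8, k = 2, n_restarts = 20,
                                         seed = 2))$stress
  s3 <- suppressWarnings(nmds_ordination(d8, k = 3, n_restarts = 20,
                                         seed = 2))$stress
  expect_lte(s3, s2 + 1e-8)
  expect_error(nmds_ordination(d8[, 1:3]), "symmetric")
})

test_that("ANOSIM is exactly 1 for full separation and matches vegan", {
  set.seed(41)
  base <- matrix(5, 6, 6)
  base[1:3, 1:3] <- 1; base[4:6, 4:6] <- 1
  noise <- matrix(runif(36, 0, 0.1), 6, 6)
  d <- base + (noise + t(noise)) / 2
  diag(d) <- 0
  g <- rep(c("a", "b"), each = 3)
  a <- anosim_test(d, g)
  expect_equal(a$R, 1)
  expect_true(a$exact)
  # cross-check R against the independent vegan implementation
  av <- vegan::anosim(as.dist(d), grouping = factor(g), permutations = 0)
  expect_equal(a$R, unname(av$statistic), tolerance = 1e-12)
  set.seed(42)
  m <- matrix(runif(12 * 5), 12, 5)
  d2 <- as.matrix(vegan::vegdist(m))
  g2 <- rep(c("a", "b", "c"), each = 4)
  a2 <- anosim_test(d2, g2, seed = 1)
  av2 <- vegan::anosim(as.dist(d2), factor(g2), permutations = 0)
  expect_equal(a2$R, unname(av2$statistic), tolerance = 1e-12)
  expect_gte(a2$R, -1); expect_lte(a2$R, 1)
})

test_that("ANOSIM null behavior: centred R and invariant permutation law", {
  set.seed(55)
  Rs <- replicate(60, {
    m <- matrix(runif(10 * 4), 10, 4)
    d <- as.matrix(vegan::vegdist(m))
    anosim_test(d, sample(rep(c("a", "b"), each = 5)), n_perm = 0,
                exact_limit = 1)$R
  })
  expect_lte(abs(mean(Rs)), 3 * sd(Rs) / sqrt(length(Rs)))
  # exchangeability: relabelling groups leaves the exact null unchanged
  set.seed(56)
  m <- matrix(runif(8 * 4), 8, 4)
  d <- as.matrix(vegan::vegdist(m))
  g <- rep(c("a", "b"), each = 4)
  p1 <- anosim_test(d, g)$p
  gp <- ifelse(g == "a", "b", "a")
  p2 <- anosim_test(d, gp)$p
  expect_equal(p1, p2)
  expect_error(anosim_test(d, c("a", rep("b", 7))), "at least two members")
})

test_that("Rosner test flags gross outliers and respects its critical values", {
  r <- rosner_outliers(c(5.1, 4.9, 5.0, 5.2, 50.0), k_max = 1)
  expect_equal(r$n_outliers, 1L)
  expect_equal(r$outliers, 50.0)
  # hand-computed critical value for i = 1, n = 5, alpha = 0.05
  tt <- qt(1 - 0.05 / 10, 3)
  lam <- 4 * tt / sqrt((3 + tt^2) * 5)
  expect_equal(r$trace$lambda[1], lam, tolerance = 1e-12)
  expect_equal(rosner_outliers(rep(3, 10))$n_outliers, 0L)
  expect_error(rosner_outliers(1:4, k_max = 3), "k_max")
  # contaminated larger sample: both planted outliers found
  set.seed(61)
  x <- c(rnorm(27), 12, -11)
  expect_setequal(rosner_outliers(x, k_max = 4)$outliers, c(12, -11))
})

test_that("Tukey comparisons satisfy the q = sqrt(2)|t| identity and have
           power", {
  set.seed(71)
  v <- c(rnorm(8), rnorm(7) + 1.2)
  g <- rep(c("a", "b"), c(8, 7))
  th <- tukey_hsd_groups(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(th$q, sqrt(2) * abs(unname(tt)), tolerance = 1e-9)
  # a group shifted by 10 pooled SDs is detected against both others
  set.seed(72)
  v3 <- c(rnorm(6), rnorm(6), rnorm(6) + 10)
  g3 <- rep(c("a", "b", "c"), each = 6)
  th3 <- tukey_hsd_groups(v3, g3)
  pc <- th3$p_adj[grepl("c", th3$comparison)]
  expect_true(all(pc < 0.001))
  expect_error(tukey_hsd_groups(rep(1, 6), rep(c("a", "b"), 3)),
               "zero within-group variance")
})
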