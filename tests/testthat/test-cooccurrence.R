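make_pair_census <- function(sets) census_from_sets(sets)

test_that("exact pmf reproduces the hand-enumerated 4-leaf case", {
  # N = 4, both DTs on 2 leaves, always together: pmf {1/6, 4/6, 1/6}
  cen <- make_pair_census(list(L1 = c("DT1", "DT2"), L2 = c("DT1", "DT2"),
                               L3 = character(), L4 = character()))
  pc <- pair_cooccurrence(cen, "DT1", "DT2")
  expect_equal(pc$expected, 1)
  expect_equal(pc$p_gt, 1 / 6, tolerance = 1e-12)
  expect_equal(pc$p_lt, 1, tolerance = 1e-12)
  expect_equal(pc$classification, "random")
  expect_equal(pc$effect, (2 - 1) / 4)
})

test_that("perfect co-occurrence at scale is overwhelmingly positive", {
  sets <- c(
    stats::setNames(rep(list(c("DT1", "DT2")), 50), paste0("A", 1:50)),
    stats::setNames(rep(list(character()), 50), paste0("B", 1:50))
  )
  pc <- pair_cooccurrence(make_pair_census(sets), "DT1", "DT2")
  expect_lt(pc$p_gt, 1e-15)
  expect_equal(pc$classification, "positive")
})

test_that("pair results are symmetric and tails include the observed value", {
  set.seed(7)
  sets <- lapply(1:40, function(i) {
    sample(c("DT1", "DT2", "DT5"), sample(0:3, 1))
  })
  names(sets) <- paste0("L", 1:40)
  cen <- make_pair_census(sets)
  a <- pair_cooccurrence(cen, "DT1", "DT2")
  b <- pair_cooccurrence(cen, "DT2", "DT1")
  expect_equal(a[c("N", "N1", "N2", "j_obs", "expected", "p_lt", "p_gt",
                   "effect", "classification")],
               b[c("N", "N2", "N1", "j_obs", "expected", "p_lt", "p_gt",
                   "effect", "classification")],
               ignore_attr = TRUE)
  expect_gte(a$p_lt + a$p_gt, 1)
})

test_that("tail probabilities agree with exhaustive placement enumeration", {
  set.seed(11)
  for (rep in 1:8) {
    N <- sample(5:12, 1)
    N1 <- sample(1:(N - 1), 1)
    N2 <- sample(1:(N - 1), 1)
    sets <- lapply(seq_len(N), function(i) {
      out <- character()
      if (i <= N1) out <- "DT1"
      out
    })
    # place DT2 on a random N2-subset and read off j_obs
    pos2 <- sample(N, N2)
    for (i in pos2) sets[[i]] <- c(sets[[i]], "DT2")
    names(sets) <- paste0("L", seq_len(N))
    pc <- pair_cooccurrence(make_pair_census(sets), "DT1", "DT2")
    oracle <- oracle_cooccur_tails(N, N1, N2, pc$j_obs)
    expect_equal(pc$p_lt, oracle[["p_lt"]], tolerance = 1e-9)
    expect_equal(pc$p_gt, oracle[["p_gt"]], tolerance = 1e-9)
  }
})

test_that("classification is monotone in alpha", {
  set.seed(13)
  sets <- lapply(1:60, function(i) {
    dts <- character()
    u <- runif(1)
    if (u < 0.4) dts <- c("DT1", "DT2")  # induced positive association
    else if (u < 0.7) dts <- sample(c("DT1", "DT2", "DT5"), 1)
    dts
  })
  names(sets) <- paste0("L", 1:60)
  cen <- make_pair_census(sets)
  strict <- cooccurrence_matrix(cen, alpha = 0.01, min_expected = 0)$pairs
  loose <- cooccurrence_matrix(cen, alpha = 0.05, min_expected = 0)$pairs
  key <- function(p) paste(p$dt_a, p$dt_b)
  pos_strict <- key(strict[strict$classification == "positive", ])
  pos_loose <- key(loose[loose$classification == "positive", ])
  expect_true(all(pos_strict %in% pos_loose))
  neg_strict <- key(strict[strict$classification == "negative", ])
  neg_loose <- key(loose[loose$classification == "negative", ])
  expect_true(all(neg_strict %in% neg_loose))
})

test_that("matrix-level filters drop singletons and low-expectation pairs", {
  sets <- c(
    stats::setNames(rep(list(c("DT1", "DT2")), 20), paste0("A", 1:20)),
    list(S1 = "DT5"),                      # singleton DT
    stats::setNames(rep(list(character()), 9), paste0("B", 1:9))
  )
  cen <- make_pair_census(sets)
  res <- cooccurrence_matrix(cen, drop_singletons = TRUE)
  expect_equal(res$dropped_dts, "DT5")
  expect_false(any(c(res$pairs$dt_a, res$pairs$dt_b) == "DT5"))
  res2 <- cooccurrence_matrix(cen, drop_singletons = FALSE, min_expected = 1)
  # DT5 pairs have expected = 20*1/30 < 1: excluded but recorded
  expect_true(all(res2$excluded_pairs$expected < 1))
  expect_true("DT5" %in% c(res2$excluded_pairs$dt_a, res2$excluded_pairs$dt_b))
  # effect matrix is symmetric with NA diagonal untouched pairs
  expect_equal(res$effect_matrix, t(res$effect_matrix))
})

test_that("a forest's full pair set has C(D, 2) candidates", {
  set.seed(3)
  sets <- lapply(1:50, function(i) sample(c("DT1", "DT2", "DT5"), 2))
  names(sets) <- paste0("L", 1:50)
  res <- cooccurrence_matrix(make_pair_census(sets), min_expected = 0)
  expect_equal(nrow(res$pairs), choose(3, 2))
})

test_that("pairing summary splits significant pairs into percentages", {
  pairs <- data.frame(
    dt_a = c("A", "A", "A", "B", "B"),
    dt_b = c("B", "C", "D", "C", "D"),
    classification = c("positive", "positive", "positive", "negative",
                       "random"),
    stringsAsFactors = FALSE
  )
  s <- pairing_summary(pairs)
  expect_equal(s$pct_positive[s$dt_code == "A"], 100)
  expect_equal(s$pct_negative[s$dt_code == "A"], 0)
  expect_equal(s$pct_positive[s$dt_code == "B"], 50)
  pairs$classification <- "random"
  s2 <- pairing_summary(pairs)
  expect_true(all(s2$n_significant == 0))
  expect_true(all(is.na(s2$pct_positive)))
})

test_that("a DT present on every leaf is forced to random with a note", {
  sets <- list(L1 = c("DT1", "DT2"), L2 = "DT1", L3 = "DT1", L4 = "DT1")
  pc <- pair_cooccurrence(make_pair_census(sets), "DT1", "DT2")
  expect_equal(pc$classification, "random")
  expect_match(pc$note, "every leaf")
})
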