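example_2x2 <- mating_network(rbind(c(1, 1), c(1, 0)))

test_that("edge trait pairs list degrees per oriented edge", {
  p <- edge_trait_pairs(example_2x2, "directed")
  expect_equal(p[, "j"], c(2, 2, 1))
  expect_equal(p[, "k"], c(2, 1, 2))

  pu <- edge_trait_pairs(example_2x2, "undirected")
  expect_equal(nrow(pu), 6)
  expect_equal(pu[4:6, ], p[, 2:1], ignore_attr = TRUE)

  mono <- mating_network(diag(2))
  expect_equal(unname(edge_trait_pairs(mono, "directed")),
               cbind(c(1, 1), c(1, 1)), ignore_attr = TRUE)
  expect_error(edge_trait_pairs(mating_network(matrix(0, 2, 2)), "directed"),
               "empty")
})

test_that("Newman assortativity matches the worked 2x2 value in both modes", {
  expect_equal(newman_assortativity(example_2x2, "directed")$value, -0.5)
  expect_equal(newman_assortativity(example_2x2, "undirected")$value, -0.5)

  complete <- mating_network(matrix(1, 2, 2))
  r <- newman_assortativity(complete, "directed")
  expect_true(is_undefined(r))
  expect_equal(r$reason, "no-edge-end-variance")
})

test_that("Newman formula agrees with a generic Pearson oracle", {
  # every 2x2 binary matrix with at least one edge, then random 3x3s
  mats <- lapply(1:15, function(bits) {
    matrix(as.integer(intToBits(bits)[1:4]), 2, 2)
  })
  set.seed(21)
  mats <- c(mats, lapply(1:30, function(i) random_incidence(3, 3)))
  tested <- 0
  for (A in mats) {
    net <- mating_network(A)
    for (mode in c("directed", "undirected")) {
      p <- edge_trait_pairs(net, mode)
      expected <- suppressWarnings(stats::cor(p[, 1], p[, 2]))
      got <- newman_assortativity(net, mode)
      if (is.na(expected)) {
        expect_true(is_undefined(got))
      } else {
        expect_equal(got$value, expected, tolerance = 1e-12)
        expect_true(abs(got$value) <= 1 + 1e-12)
        tested <- tested + 1
      }
    }
  }
  expect_gt(tested, 20)
})

test_that("directed and undirected agree on symmetric incidence matrices", {
  set.seed(5)
  for (i in 1:20) {
    A <- random_incidence(4, 4)
    A <- (A + t(A) > 0) + 0  # symmetrise
    net <- mating_network(A)
    rd <- newman_assortativity(net, "directed")
    ru <- newman_assortativity(net, "undirected")
    expect_identical(is_undefined(rd), is_undefined(ru))
    if (!is_undefined(rd)) expect_equal(rd$value, ru$value, tolerance = 1e-12)
  }
})

test_that("NODF handles the canonical cases", {
  stair <- mating_network(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  expect_equal(nodf(stair, detail = FALSE), 100)
  expect_equal(nodf(mating_network(matrix(1, 4, 4)), detail = FALSE), 0)

  det <- nodf(stair)
  expect_equal(det$nodf, 100)
  # detail invariants: N = 0 where DF = 0, N = PO where DF = 100
  pairs <- rbind(det$row_pairs, det$col_pairs)
  expect_true(all(pairs$N[pairs$DF == 0] == 0))
  expect_equal(pairs$N[pairs$DF == 100], pairs$PO[pairs$DF == 100])
  expect_true(all(pairs$PO >= 0 & pairs$PO <= 100))
})

test_that("NODF equals the independent pairwise oracle and vegan", {
  set.seed(31)
  for (i in 1:25) {
    m <- sample(3:6, 1); f <- sample(3:6, 1)
    A <- random_incidence(m, f)
    net <- mating_network(A)
    kept <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
    if (nrow(kept) < 2 && ncol(kept) < 2) next
    expect_equal(nodf(net, detail = FALSE), oracle_nodf(kept),
                 tolerance = 1e-12)
    expect_equal(nodf(net)$nodf, oracle_nodf(kept), tolerance = 1e-12)
    if (nrow(kept) >= 2 && ncol(kept) >= 2 && sum(kept) > 0) {
      v <- unname(vegan::nestednodf(kept, order = TRUE)$statistic["NODF"])
      expect_equal(nodf(net, detail = FALSE), v, tolerance = 1e-8)
    }
  }
})

test_that("NODF is invariant to row/column permutations", {
  set.seed(41)
  net <- random_mating_network(6, 6, 0.5)
  base <- nodf(net, detail = FALSE)
  for (i in 1:10) {
    A <- net$incidence[sample(6), sample(6)]
    expect_equal(nodf(mating_network(A), detail = FALSE), base,
                 tolerance = 1e-12)
  }
})

test_that("SCI reproduces the worked harmonic-mean example", {
  s <- sperm_competition_intensity(worked_sci_network())
  expect_equal(s$share[["A"]], 2 / 3)
  expect_equal(s$sci[["A"]], 1.5)
  # the other males share one trigamous female and face her two co-males
  expect_equal(s$sci[["B"]], 3)

  mono <- sperm_competition_intensity(mating_network(diag(3)))
  expect_equal(unname(mono$sci), c(1, 1, 1))
})

test_that("weighted SCI counts copulations as raffle tickets", {
  # one shared female; focal male holds 2 of her 3 copulations
  net <- from_edge_list(data.frame(
    male_id = c("A", "B"), female_id = c("x", "x"), count = c(2, 1)))
  res <- sperm_competition_intensity(net, weighted = TRUE)
  expect_equal(res$share[["A"]], 2 / 3)
  expect_equal(res$sci[["A"]], 1.5)
  expect_error(sperm_competition_intensity(example_2x2, weighted = TRUE),
               "counts")
})

test_that("unweighted SCI is bounded by partner degrees", {
  set.seed(51)
  for (i in 1:20) {
    net <- random_mating_network(sample(3:8, 1), sample(3:8, 1),
                                 runif(1, 0.4, 0.9))
    d <- degrees(net)
    res <- sperm_competition_intensity(net)
    for (male in seq_len(n_males(net))) {
      partners <- d$female_degrees[net$incidence[male, ] == 1]
      expect_gte(res$sci[male] + 1e-12, min(partners))
      expect_lte(res$sci[male] - 1e-12, max(partners))
      expect_equal(unname(res$sci[male]) == 1, all(partners == 1))
    }
  }
})

test_that("SCIC handles undefined cases and the block network", {
  mono <- mating_network(diag(3))
  u <- scic(mono)
  expect_true(is_undefined(u))
  expect_equal(u$reason, "no-male-degree-variance")

  # 3x3 complete block plus an isolated monogamous pair: M = SCI exactly
  A <- matrix(0, 4, 4); A[1:3, 1:3] <- 1; A[4, 4] <- 1
  blk <- mating_network(A)
  expect_equal(scic(blk, "correlation")$value, 1)
  expect_equal(scic(blk, "slope")$value, 1)

  expect_error(scic(mating_network(matrix(1, 1, 3))), "2 mated males")
})

test_that("SCIC correlation equals the Pearson oracle on simulator output", {
  set.seed(61)
  for (i in 1:5) {
    net <- random_mating_network(20, 20, 0.5)
    d <- degrees(net)
    sci <- sperm_competition_intensity(net)$sci
    expect_equal(scic(net, "correlation")$value,
                 stats::cor(d$male_degrees, sci), tolerance = 1e-12)
    # slope form with z-scored variables collapses to the correlation
    zs <- scale(sci)[, 1]; zm <- scale(d$male_degrees)[, 1]
    slope_z <- sum(zm * zs) / sum(zm^2)
    expect_equal(scic(net, "correlation")$value, slope_z, tolerance = 1e-12)
  }
})

test_that("metric_report mirrors defined/undefined semantics", {
  # single polygynous male with monandrous partners: no male variance to
  # correlate, no variance at either edge end
  poly1 <- mating_network(matrix(1, 1, 4))
  rp <- metric_report(poly1)
  expect_equal(rp$nodf$value, 0)
  expect_true(is_undefined(rp$r_newman_d))
  expect_true(is_undefined(rp$scic_corr))

  mono <- metric_report(mating_network(diag(4)))
  expect_equal(mono$nodf$value, 0)
  for (nm in c("r_newman_u", "r_newman_d", "scic_corr", "scic_slope"))
    expect_true(is_undefined(mono[[nm]]))

  # disassortative structure: all correlation metrics negative
  dis <- mating_network(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  rpd <- metric_report(dis)
  expect_lt(rpd$r_newman_u$value, 0)
  expect_lt(rpd$r_newman_d$value, 0)
  expect_lt(rpd$scic_corr$value, 0)
  expect_gte(rpd$nodf$value, 0)

  # degree-0 individuals are excluded: padding with non-maters must not
  # change any metric
  pad <- matrix(0, 4, 4); pad[1:3, 1:3] <- dis$incidence
  rpp <- metric_report(mating_network(pad))
  expect_equal(report_values(rpp), report_values(rpd))
  expect_equal(rpp$density, sum(dis$incidence) / 16)
})
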