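test_that("spearman_rho matches hand-computed values and flags degeneracies", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30))$rho, 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1.0)
  # tie-averaged ranks: rho = 4.5 / sqrt(4.5 * 5.0)
  res <- spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(res$rho, 4.5 / sqrt(4.5 * 5.0), tolerance = 1e-12)
  expect_equal(res$n_used, 4L)

  # pairwise missing-removal
  res2 <- spearman_rho(c(1, 2, NA, 4, 5), c(2, 4, 9, NA, 10))
  expect_equal(res2$n_used, 3L)
  expect_equal(res2$rho, 1.0)

  const <- spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(const$rho))
  expect_equal(const$reason, "constant_input")
  few <- spearman_rho(c(1, NA, NA, NA), c(1, 2, 3, 4))
  expect_equal(few$reason, "too_few_pairs")
})

test_that("spearman_rho equals the exhaustive rank oracle on short tied vectors", {
  # all pairs of length-4 vectors over {1,2,3} (ties everywhere)
  grid4 <- as.matrix(expand.grid(rep(list(1:3), 4)))
  set.seed(1)
  pick <- sample.int(nrow(grid4), 40)
  for (i in pick) for (j in sample.int(nrow(grid4), 15)) {
    x <- grid4[i, ]; y <- grid4[j, ]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # longer vectors with ties, lengths 5..8
  set.seed(2)
  for (n in 5:8) for (rep in 1:50) {
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_rho is rank-invariant and symmetric", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y^3 + 2 * y)$rho, base,
                 tolerance = 1e-12)
    expect_equal(spearman_rho(y, x)$rho, base, tolerance = 1e-12)
  }
})

test_that("correlation_matrix has unit diagonal and honours negation", {
  g <- bin_genome(c(s = 1e5), 10000)
  set.seed(4)
  a <- feature_track(rnorm(10), g, "a")
  b <- feature_track(rnorm(10), g, "b")
  neg <- feature_track(-a$values, g, "neg_a")
  cm <- correlation_matrix(list(a, b, neg))
  expect_equal(unname(diag(cm$rho)), c(1, 1, 1))
  expect_equal(cm$rho["a", "neg_a"], -1)
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(abs(cm$rho) <= 1))
  expect_true(all(cm$n_used <= length(g)))

  g2 <- bin_genome(c(s = 1e5), 5000)
  expect_error(correlation_matrix(list(a), list(feature_track(1:20, g2, "c"))),
               "mismatched grids")
})

test_that("stratify_intervals applies strict-greater rich and exact-zero poor rules", {
  g <- bin_genome(c(s = 5e4), 10000)
  tr <- feature_track(c(0, 5, 12, 0, 11), g, "L1")
  sel <- stratify_intervals(tr)
  expect_equal(sel$rich_indices, c(3L, 5L))
  expect_equal(sel$poor_indices, c(1L, 4L))
  expect_length(intersect(sel$rich_indices, sel$poor_indices), 0L)

  g0 <- bin_genome(c(s = 3e4), 10000)
  expect_warning(sel0 <- stratify_intervals(feature_track(c(0, 0, 0), g0, "x")),
                 "rich stratum")
  expect_length(sel0$rich_indices, 0L)
  expect_equal(sel0$poor_indices, 1:3)

  expect_error(stratify_intervals(feature_track(c(0.5, 1, 2), g0, "x")),
               "integer")
})

test_that("rich-stratum size matches the Poisson tail probability", {
  n <- 10000
  lambda <- 3
  g <- bin_genome(c(s = n * 1e4), 10000)
  set.seed(5)
  counts <- rpois(n, lambda)
  sel <- suppressWarnings(stratify_intervals(feature_track(counts, g, "x")))
  p_tail <- ppois(10, lambda, lower.tail = FALSE)
  sd3 <- 3 * sqrt(n * p_tail * (1 - p_tail))
  expect_lt(abs(length(sel$rich_indices) - n * p_tail), max(sd3, 3))
})

test_that("stratified matrices reduce to the unstratified matrix when strata cover all", {
  g <- bin_genome(c(s = 2e5), 10000)
  set.seed(6)
  x <- feature_track(rnorm(20), g, "x")
  y <- feature_track(rnorm(20), g, "y")
  sel <- structure(list(rich_indices = 1:20, poor_indices = 1:20,
                        threshold_rich = 0, threshold_poor = 0),
                   class = "stratified_selection")
  sm <- stratified_matrix(list(x), list(y), sel)
  full <- correlation_matrix(list(x), list(y))
  expect_equal(sm$rich$rho, full$rho)
  expect_equal(sm$poor$rho, full$rho)

  # degenerate stratum: missing cells with a reason, not an error
  sel2 <- structure(list(rich_indices = 1:2, poor_indices = 3:20,
                         threshold_rich = 0, threshold_poor = 0),
                    class = "stratified_selection")
  sm2 <- stratified_matrix(list(x), list(y), sel2)
  expect_true(is.na(sm2$rich$rho[1, 1]))
  expect_equal(sm2$rich$reason[1, 1], "too_few_pairs")
})

test_that("planted stratum-specific correlations are recovered", {
  ss <- simulate_stratified_tracks(10000, rho_rich = 0.2, rho_poor = 0.7,
                                   seed = 13)
  sel <- stratify_intervals(ss$tracks$counts)
  expect_gte(length(sel$rich_indices), 2000)
  expect_gte(length(sel$poor_indices), 2000)
  sm <- stratified_matrix(list(ss$tracks$x), list(ss$tracks$y), sel)
  expect_lt(abs(sm$rich$rho[1, 1] - 0.2), 0.07)
  expect_lt(abs(sm$poor$rho[1, 1] - 0.7), 0.07)
})
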