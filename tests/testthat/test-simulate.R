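test_that("generators are bit-reproducible for identical spec and seed", {
  a <- simulate_tracks(500, matrix(c(1, 0.4, 0.4, 1), 2), seed = 5)
  b <- simulate_tracks(500, matrix(c(1, 0.4, 0.4, 1), 2), seed = 5)
  expect_identical(a$tracks[[1]]$values, b$tracks[[1]]$values)

  r1 <- simulate_reads(n_reads = 200, seed = 6)
  r2 <- simulate_reads(n_reads = 200, seed = 6)
  expect_identical(r1$placements, r2$placements)
  expect_identical(r1$truth, r2$truth)

  i1 <- simulate_image(image_sim_spec(seed = 7))
  i2 <- simulate_image(image_sim_spec(seed = 7))
  expect_identical(i1$stack$channels, i2$stack$channels)
  expect_identical(i1$truth$foci_labels, i2$truth$foci_labels)

  i3 <- simulate_image(image_sim_spec(seed = 8))
  expect_false(identical(i1$stack$channels$gH2AX, i3$stack$channels$gH2AX))
})

test_that("copula tracks realise their planted Spearman structure", {
  # independent pair: empirical rho within the 3/sqrt(n) null bound
  s0 <- simulate_tracks(10000, diag(2), seed = 9)
  expect_lt(abs(spearman_rho(s0$tracks[[1]], s0$tracks[[2]])$rho),
            3 / sqrt(10000) * 1.5)
  # comonotone: exactly 1
  s1 <- simulate_tracks(200, matrix(c(1, 1, 1, 1), 2), seed = 10)
  expect_equal(spearman_rho(s1$tracks[[1]], s1$tracks[[2]])$rho, 1.0)
  # intermediate target recovered within sampling error
  s6 <- simulate_tracks(10000, matrix(c(1, 0.6, 0.6, 1), 2), seed = 11)
  expect_lt(abs(spearman_rho(s6$tracks[[1]], s6$tracks[[2]])$rho - 0.6), 0.05)
  # unattainable target errors out
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(simulate_tracks(100, bad, seed = 1), "not attainable")
})

test_that("marginal types produce the requested distributions", {
  st <- simulate_tracks(5000, diag(2),
                        marginals = list(list(type = "poisson", lambda = 3),
                                         list(type = "uniform")),
                        seed = 12)
  v1 <- st$tracks[[1]]$values
  expect_true(all(v1 == round(v1)))
  expect_lt(abs(mean(v1) - 3), 3 * sqrt(3 / 5000))
  v2 <- st$tracks[[2]]$values
  expect_true(all(v2 >= 0 & v2 <= 1))
  expect_lt(abs(mean(v2) - 0.5), 3 * sqrt(1 / 12 / 5000))
})

test_that("read simulator edge rates produce the promised truths", {
  # no multi-mapping: classifier is exact and everything is classifiable
  pure <- simulate_reads(n_reads = 1500, multimap_rate = 0,
                         nonrepeat_rate = 0, seed = 13)
  asn <- classify_reads(pure$placements, pure$annotations)
  expect_equal(unname(asn[pure$truth$read_id]), pure$truth$truth)
  expect_false(any(asn %in% c("DISCARD", "NONREPEAT")))

  # all multi-mappers cross-class: every multi-mapped read is DISCARD truth
  cross <- simulate_reads(n_reads = 1500, multimap_rate = 1,
                          cross_class_frac = 1, nonrepeat_rate = 0,
                          seed = 14)
  expect_true(all(cross$truth$truth == "DISCARD"))
  asn2 <- classify_reads(cross$placements, cross$annotations)
  expect_true(all(asn2 == "DISCARD"))
})

test_that("image simulator geometry and planted structures are consistent", {
  cell <- simulate_image(image_sim_spec(seed = 15))
  tv <- sum(cell$truth$nucleus) * prod(cell$stack$voxel_size)
  av <- 4 / 3 * pi * prod(c(6, 6, 3.5))
  expect_lt(abs(tv - av) / av, 0.05)
  expect_equal(max(cell$truth$foci_labels), 15L)
  # focus centers respect the minimum separation
  dd <- as.matrix(dist(cell$truth$foci_centers))
  expect_gte(min(dd[dd > 0]), 2)
  # channels share shape and are non-negative
  expect_true(all(vapply(cell$stack$channels,
                         function(ch) all(ch >= 0), TRUE)))
})

test_that("repair time course plants the requested decay with a valid manifest", {
  tc <- simulate_repair_timecourse(n_cells = 5, seed = 16)
  expect_equal(nrow(tc$manifest), 15L)
  expect_equal(sort(unique(tc$manifest$timepoint)), c(0.5, 3, 24))
  med <- tapply(tc$manifest$overlap_truth, tc$manifest$timepoint, median)
  expect_lt(abs(med[["3"]] / med[["0.5"]] - 0.5), 0.2)
  cell <- tc$make_cell(1)
  expect_equal(cell$truth$overlap_fraction,
               tc$manifest$overlap_truth[1])

  # single-timepoint design: kinetics normalisation has no baseline
  tc1 <- simulate_repair_timecourse(n_cells = 2, timepoints = 3, decay = 1,
                                    seed = 17)
  rec <- data.frame(cell_id = tc1$manifest$cell_id,
                    timepoint = tc1$manifest$timepoint,
                    raw_fraction = c(0.2, 0.3))
  expect_error(normalize_kinetics(rec), "baseline")
})

test_that("TIFF round-trip preserves integer counts and voxel size", {
  td <- withr::local_tempdir()
  cell <- simulate_image(image_sim_spec(seed = 18))
  write_stack_tiff(cell$stack, td)
  back <- read_stack_tiff(td)
  for (nm in names(cell$stack$channels))
    expect_equal(back$channels[[nm]], cell$stack$channels[[nm]],
                 ignore_attr = TRUE)
  expect_equal(back$voxel_size, cell$stack$voxel_size)
})
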