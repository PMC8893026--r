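test_that("source pool normalization, evenness limit and determinism", {
  even <- generateSourcePool(3, 0, seed = 11)
  expect_equal(even$p, rep(1 / 3, 3))

  expect_identical(generateSourcePool(100, 1, seed = 7),
                   generateSourcePool(100, 1, seed = 7))

  pool <- generateSourcePool(500, 2, seed = 1)
  expect_equal(sum(pool$p), 1, tolerance = 1e-12)
  ranked <- sort(pool$p, decreasing = TRUE)
  expect_true(all(diff(ranked) < 0))
  expect_setequal(pool$tree$tip.label, pool$taxon_ids)
  expect_true(ape::is.rooted(pool$tree))

  expect_error(generateSourcePool(1), "n_taxa")
})

test_that("neutral sampler matches Dirichlet-multinomial moments", {
  pool <- list(taxon_ids = paste0("t", 1:4), p = c(0.01, 0.1, 0.5, 0.39))

  # zero-mass taxon never appears
  z <- list(taxon_ids = paste0("t", 1:3), p = c(0, 0.6, 0.4))
  counts <- simulateNeutralSample(z, Nm = 10, reads = 500, seed = 4)
  expect_equal(unname(counts[1]), 0)
  expect_equal(sum(counts), 500)

  # huge Nm concentrates at p: mean count ~ reads * p
  draws <- withr::with_seed(5, t(replicate(2000, simulateNeutralSample(
    pool, Nm = 1e9, reads = 1000, seed = NULL))))
  expect_equal(unname(colMeans(draws)) / 1000, pool$p, tolerance = 0.02)

  # Beta marginal variance p(1-p)/(Nm+1) at Nm = 50, within 10%
  draws <- withr::with_seed(6, t(replicate(10000, simulateNeutralSample(
    pool, Nm = 50, reads = 10000, seed = NULL)))) / 10000
  beta_var <- pool$p * (1 - pool$p) / 51
  for (k in c(1, 2, 3))  # p = 0.01, 0.1, 0.5
    expect_equal(stats::var(draws[, k]), beta_var[k], tolerance = 0.1)
  expect_equal(unname(colMeans(draws)), pool$p, tolerance = 0.05)
})

test_that("mean relative abundance across many neutral samples tracks the pool", {
  pool <- generateSourcePool(10, 1, seed = 2)
  draws <- withr::with_seed(3, t(replicate(1000, simulateNeutralSample(
    pool, Nm = 50, reads = 1000, seed = NULL)))) / 1000
  se <- apply(draws, 2, stats::sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - pool$p) <= 3 * se + 1e-12))
})

test_that("niche filter reduces to neutral at w = 0 and selects at w = 1", {
  pool <- list(taxon_ids = paste0("t", 1:3), p = c(0.2, 0.5, 0.3))
  traits <- list(optimum = c(20, 25, 30), tolerance = c(3, 3, 3))

  expect_identical(
    simulateNicheSample(pool, traits, env_value = 25, w = 0, Nm = 20,
                        reads = 400, seed = 9),
    simulateNeutralSample(pool, Nm = 20, reads = 400, seed = 9))

  # matched optimum with tiny tolerance dominates
  tight <- list(optimum = c(25, 10, 40), tolerance = c(0.5, 0.5, 0.5))
  counts <- simulateNicheSample(pool, tight, env_value = 25, w = 1,
                                Nm = 1000, reads = 2000, seed = 2)
  expect_gt(counts[1] / 2000, 0.999)

  # symmetric optima with equal pool mass get equal expected abundance
  sym <- list(taxon_ids = c("a", "b"), p = c(0.5, 0.5))
  straits <- list(optimum = c(23, 27), tolerance = c(2, 2))
  draws <- withr::with_seed(8, t(replicate(1500, simulateNicheSample(
    sym, straits, env_value = 25, w = 1, Nm = 100, reads = 500,
    seed = NULL)))) / 500
  expect_equal(mean(draws[, 1]), mean(draws[, 2]), tolerance = 0.05)

  expect_error(simulateNicheSample(pool, traits, 25, w = 2, Nm = 1, reads = 10),
               "w must")
})

test_that("metadata construction: geometry, temperature gradient, regions", {
  cfg0 <- simConfig(n_stations = 10, temp_noise_sd = 0, seed = 1)
  md <- generateMetadata(cfg0)
  expect_equal(abs(stats::cor(md$temperature[md$depth_category == "surface"],
                              md$latitude[md$depth_category == "surface"])), 1)
  expect_true(all(table(md$station) == 2))

  cfg <- simConfig(n_stations = 20, temp_slope = -0.9, temp_noise_sd = 0.8,
                   seed = 3)
  md <- generateMetadata(cfg)
  surf <- md$depth_category == "surface"
  r <- stats::cor(md$temperature[surf], md$latitude[surf])
  expect_true(abs(r) > 0.7 && abs(r) < 0.99)
  expect_lt(r, 0)  # colder at higher latitude
  expect_true(all(md$region %in% c("AC", "SSS", "NSS", "NAtl")))
})

test_that("dataset simulation: totals, determinism, degenerate reads", {
  cfg <- simConfig(n_stations = 4, reads_per_sample = 500, seed = 6)
  pool <- generateSourcePool(50, 1, seed = 6)
  ds <- simulateDataset(cfg, pool = pool)
  m <- otuCounts(ds$table)
  expect_true(all(rowSums(m) == 500))
  expect_identical(m, otuCounts(simulateDataset(cfg, pool = pool)$table))

  cfg1 <- simConfig(n_stations = 3, reads_per_sample = 1, seed = 2)
  m1 <- otuCounts(simulateDataset(cfg1, pool = pool)$table)
  expect_true(all(rowSums(m1) == 1))
  expect_true(all(rowSums(m1 > 0) == 1))
})

test_that("contaminant taxa are attached with a consistent tree and control", {
  cfg <- simConfig(n_stations = 3, reads_per_sample = 300, seed = 8)
  ds <- simulateDataset(cfg, pool = generateSourcePool(30, 1, seed = 8),
                        n_contaminants = 2)
  expect_length(ds$negctrl, ncol(otuCounts(ds$table)))
  expect_true(all(ds$negctrl[grep("CONTAM", names(ds$negctrl))] > 0))
  expect_true(ape::is.rooted(ds$tree))
  fl <- removeContaminants(ds$table, ds$negctrl)
  expect_setequal(fl$report$otu_id, grep("CONTAM", names(ds$negctrl),
                                         value = TRUE))
})
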