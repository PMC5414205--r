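test_that("noise levels map to the configured relative sd", {
  expect_equal(noiseSpec("none")$relSd, 0)
  expect_equal(noiseSpec("low")$relSd, 0.05)
  expect_equal(noiseSpec("medium")$relSd, 0.10)
  expect_equal(noiseSpec("high")$relSd, 0.20)
  expect_error(noiseSpec("low", relSd = -0.1), ">= 0")
})

test_that("zero-noise synthetic data reproduce grid predictions exactly", {
  grid <- mockGrid(function(P, C) c(P + C, P - C / 2, 50))
  ds <- generateSyntheticDataset(grid, c(P = 80, C = 60), noiseSpec("none"),
                                 seed = 1)
  pred <- observableValues(predictObservables(grid, c(P = 80, C = 60)))
  expect_equal(ds$value, unname(pred))
  # determinism: same seed gives the identical dataset
  dsA <- generateSyntheticDataset(grid, c(P = 80, C = 60), noiseSpec("high"),
                                  seed = 9)
  dsB <- generateSyntheticDataset(grid, c(P = 80, C = 60), noiseSpec("high"),
                                  seed = 9)
  expect_identical(dsA$value, dsB$value)
  expect_false(identical(dsA$value,
                         generateSyntheticDataset(grid, c(P = 80, C = 60),
                                                  noiseSpec("high"),
                                                  seed = 10)$value))
})

test_that("noise draws have the requested standard deviation", {
  grid <- mockGrid(function(P, C) c(200, 350, 120))
  v <- vapply(seq_len(8000), function(s)
    generateSyntheticDataset(grid, c(P = 80, C = 60), noiseSpec("medium"),
                             seed = s)$value[2], 0)
  # sigma = 0.10 * 350 = 35; Monte-Carlo sd estimate within 3%
  expect_equal(sd(v), 35, tolerance = 0.03)
  expect_equal(mean(v), 350, tolerance = 0.01)
})

test_that("synthetic values are clamped to physical ranges", {
  sch <- data.frame(id = c("d1", "f1", "a1"),
                    dataset = c("O5", "O8", "O2"),
                    class = c("mean_3d_distance", "contact_summary_intra",
                              "median_angle"),
                    chrom_a = NA, pos_a = NA, chrom_b = NA, pos_b = NA,
                    sep_bp = NA,
                    group = c("fixed_imaging", "hic_A", "live_imaging"))
  grid <- mockGrid(function(P, C) c(0.4, 0.9, 178), schema = sch)
  huge <- noiseSpec("high", relSd = 3)
  vals <- replicate(200, generateSyntheticDataset(
    grid, c(P = 80, C = 60), huge, seed = sample.int(1e6, 1))$value)
  expect_true(all(vals[1, ] >= 0))
  expect_true(all(vals[2, ] >= 0 & vals[2, ] <= 1))
  expect_true(all(vals[3, ] >= 0 & vals[3, ] <= 180))
})

test_that("the yeast schema emits 266 observables with the Table-2 split", {
  sch <- buildObservableSchema(yeastGenome())
  expect_equal(nrow(sch), 266)
  expect_equal(unname(table(sch$dataset)[paste0("O", 1:9)]),
               c(62, 37, 15, 12, 13, 8, 7, 56, 56),
               ignore_attr = TRUE)
})

test_that("zero-noise recovery at a grid node returns the truth", {
  grid <- reducedTestGrid()
  rec <- recoveryExperiment(grid, data.frame(P = 80, C = 60),
                            noiseSpec("none"), nRepeats = 1, seed = 3)
  # MAP equals the node up to the KDE smoothing bandwidth
  expect_lt(rec$rms$rms_P, 2)
  expect_lt(rec$rms$rms_C, 1.5)
})

test_that("mismatch control arm recovers the truth from held-out replicas", {
  # V = 14% equals the grid geometry: data come from fresh (held-out)
  # simulations with the same settings as the grid build, so residual
  # errors reflect replica sampling noise, not model mismatch
  grid <- reducedTestGrid()
  mm <- mismatchExperiment(grid, vFractions = 0.14, truth = c(P = 80, C = 60),
                           noise = noiseSpec("none"), nReplicas = 2, seed = 21)
  expect_equal(names(mm), c("V", "truth_P", "map_P", "err_P",
                            "truth_C", "map_C", "err_C"))
  # errors bounded by about one lattice spacing (40 nm in P, 30 bp/nm in C)
  expect_lt(mm$err_P, 45)
  expect_lt(mm$err_C, 33)
})
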