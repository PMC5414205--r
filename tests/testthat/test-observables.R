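chainsT <- discretizeGenome(tinyGenome(), parameterPoint(60, 50, 30, 100),
                            tinyGeometry())

test_that("distance statistics reproduce hand-computed values", {
  n <- nBeads(chainsT)
  base <- matrix(0, n, 3)
  # beads 1 and 2: fixed displacement (3, 4, 0) -> distance 5
  mk <- function(d2) {
    m <- base
    m[2, ] <- d2
    m
  }
  frames <- rep(list(mk(c(3, 4, 0))), 210)
  tr <- fakeTrajectory(chainsT, frames)
  la <- list(chrom = "tA", pos = 1)
  lb <- list(chrom = "tA", pos = 1501)
  expect_equal(pairwiseDistanceStats(tr, la, lb, "median"), 5)
  expect_equal(pairwiseDistanceStats(tr, la, lb, "mean"), 5)
  # distances {1, 2, 9} (repeated) -> median 2
  frames <- rep(list(mk(c(1, 0, 0)), mk(c(2, 0, 0)), mk(c(9, 0, 0))), 70)
  tr <- fakeTrajectory(chainsT, frames)
  expect_equal(pairwiseDistanceStats(tr, la, lb, "median"), 2)
  # sample-size preconditions
  tr2 <- fakeTrajectory(chainsT, frames[1:50])
  expect_error(pairwiseDistanceStats(tr2, la, lb, "mode"), ">= 200")
})

test_that("2D projections are rotation-consistent and below 3D distances", {
  set.seed(1)
  n <- nBeads(chainsT)
  frames <- lapply(1:300, function(i) {
    m <- matrix(0, n, 3)
    m[2, ] <- c(10, 0, 0)
    m
  })
  tr <- fakeTrajectory(chainsT, frames)
  la <- list(chrom = "tA", pos = 1)
  lb <- list(chrom = "tA", pos = 1501)
  d3 <- pairwiseDistanceStats(tr, la, lb, "median", "3d")
  set.seed(2)
  d2 <- pairwiseDistanceStats(tr, la, lb, "median", "2d")
  expect_equal(d3, 10)
  expect_lt(d2, d3)
  expect_gt(d2, 5)  # random projection median of 10 nm is ~8.7 nm
})

test_that("mode estimation finds the density peak of a known distribution", {
  set.seed(7)
  x <- rnorm(1e4, mean = 5, sd = 0.5)
  m <- chromInfer:::.modeEstimate(x)
  expect_equal(m, 5, tolerance = 0.15)
})

test_that("angles to the nucleolar axis hit geometric reference cases", {
  n <- nBeads(chainsT)
  rd <- chainsT@rdnaBeads
  mk <- function(locusPos) {
    m <- matrix(0, n, 3)
    m[, 3] <- 1e-6
    m[rd, ] <- matrix(rep(c(0, 0, -100), length(rd)), ncol = 3, byrow = TRUE)
    m[1, ] <- locusPos
    m
  }
  trAnti <- fakeTrajectory(chainsT, rep(list(mk(c(0, 0, 120))), 40))
  expect_equal(angleToNucleolarAxis(trAnti, list(chrom = "tA", pos = 1)), 180,
               tolerance = 0.01)
  trOrth <- fakeTrajectory(chainsT, rep(list(mk(c(110, 0, 0))), 40))
  expect_equal(angleToNucleolarAxis(trOrth, list(chrom = "tA", pos = 1)), 90,
               tolerance = 0.01)
  trSame <- fakeTrajectory(chainsT, rep(list(mk(c(0, 0, -120))), 40))
  expect_equal(angleToNucleolarAxis(trSame, list(chrom = "tA", pos = 1)), 0,
               tolerance = 0.01)
})

test_that("contact maps match brute-force enumeration on a fixed geometry", {
  n <- nBeads(chainsT)
  # two frames; beads 1-2 always in contact, 1-3 in contact in frame 2 only
  m1 <- matrix(seq(0, by = 400, length.out = n), n, 3)
  m1[2, ] <- m1[1, ] + c(10, 0, 0)
  m1[3, ] <- m1[1, ] + c(200, 0, 0)
  m2 <- m1
  m2[3, ] <- m1[1, ] + c(0, 20, 0)
  tr <- fakeTrajectory(chainsT, c(rep(list(m1), 5), rep(list(m2), 5)))
  st <- chromInfer:::.beadContacts(tr, cutoff = 60)
  cm <- contactMap(tr, binSizeBp = 3000, contactCutoff = 60)
  expect_true(isSymmetric(cm@matrix))
  expect_true(all(cm@matrix >= 0 & cm@matrix <= 1))
  # bead 1-2 same bin? beads are 1500 bp tiles, bin 3000 -> beads 1,2 in bin 1
  expect_equal(cm@matrix[1, 1], 1)  # permanent contact
  b3 <- 2  # bead 3 lives in bin 2
  expect_equal(cm@matrix[1, b3], 0.5 * 1 / 2)  # 1 of 2 pairs, half the frames
  expect_error(contactMap(tr, binSizeBp = 1000), "bin size")
})

test_that("contact frequency is monotone in the cutoff", {
  set.seed(3)
  tr <- runSimulation(chainsT, nSteps = 4000, sampleEvery = 100,
                      equilibrationSteps = 0, seed = 4,
                      checkEquilibration = FALSE)
  f1 <- contactMap(tr, 3000, contactCutoff = 45)@matrix
  f2 <- contactMap(tr, 3000, contactCutoff = 90)@matrix
  expect_true(all(f2 - f1 >= -1e-12))
})

test_that("hic summaries have the Table-2 shape and frame exchangeability", {
  g <- yeastGenome()
  nb <- ceiling(g@chromosomes$length_bp / 30000)
  bins <- data.frame(chrom = rep(g@chromosomes$name, nb),
                     start_bp = unlist(lapply(nb, function(k) (seq_len(k) - 1) * 30000)))
  nbin <- nrow(bins)
  # uniform map: every intra value identical
  cmU <- new("ContactMap", matrix = matrix(0.2, nbin, nbin), binSize = 30000,
             bins = bins)
  hs <- hicSummaries(cmU, g)
  expect_equal(length(observableValues(hs)), 56)
  v <- observableValues(hs)
  expect_equal(unname(v[1:16]), rep(0.2, 16))
  expect_equal(hs@schema$sep_bp[33:44], seq(25000, 80000, 5000))
  # frame order invariance of trajectory-level summaries
  set.seed(5)
  tr <- runSimulation(chainsT, nSteps = 4000, sampleEvery = 100,
                      equilibrationSteps = 0, seed = 6,
                      checkEquilibration = FALSE)
  perm <- sample(dim(tr@frames)[3])
  trP <- tr
  trP@frames <- tr@frames[, , perm]
  sch <- buildObservableSchema(tinyGenome(),
                               counts = c(O1 = 4, O2 = 3, O3 = 2, O4 = 2,
                                          O5 = 2, O6 = 0, O7 = 0))
  sch <- sch[sch$class %in% c("contact_summary_intra", "contact_summary_inter",
                              "contact_vs_s_genomewide",
                              "contact_vs_s_centromeric"), ]
  set.seed(1); v1 <- observableValues(computeObservables(tr, sch))
  set.seed(1); v2 <- observableValues(computeObservables(trP, sch))
  expect_equal(v1, v2)
})

test_that("msd handles reference motions exactly", {
  n <- nBeads(chainsT)
  still <- rep(list(matrix(1, n, 3)), 50)
  trS <- fakeTrajectory(chainsT, still)
  m <- msd(trS, 1, lags = c(1, 5, 10))
  expect_equal(m$msd, rep(0, 3))
  # ballistic drift x = v t
  v <- 2
  drift <- lapply(1:50, function(t) matrix(v * t, n, 3))
  trD <- fakeTrajectory(chainsT, drift, dt = 1, sampleEvery = 1)
  m <- msd(trD, 1, lags = c(1, 4))
  expect_equal(m$msd, 3 * v^2 * c(1, 16))
  expect_error(msd(trD, 1, lags = 100), "span")
})

test_that("time-scale fitting recovers known scalings", {
  sim <- data.frame(time = exp(seq(log(1), log(1000), length.out = 40)))
  sim$msd <- 12 * sim$time^0.5
  exp2 <- data.frame(time = sim$time * 2, msd = sim$msd)
  expect_equal(fitTimeScale(sim, exp2), 2, tolerance = 0.01)
  expect_equal(fitTimeScale(sim, sim), 1, tolerance = 0.01)
  set.seed(9)
  expN <- data.frame(time = sim$time * 0.37,
                     msd = sim$msd * exp(rnorm(40, 0, 0.05)))
  expect_equal(fitTimeScale(sim, expN), 0.37, tolerance = 0.05 * 0.37)
})

test_that("distance statistics are invariant under global rotation", {
  set.seed(11)
  tr <- runSimulation(chainsT, nSteps = 3100, sampleEvery = 100,
                      equilibrationSteps = 0, seed = 8,
                      checkEquilibration = FALSE)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  trR <- tr
  for (f in seq_len(dim(tr@frames)[3]))
    trR@frames[, , f] <- R %*% tr@frames[, , f]
  la <- list(chrom = "tA", pos = 1)
  lb <- list(chrom = "tB", pos = 9000)
  expect_equal(pairwiseDistanceStats(tr, la, lb, "median"),
               pairwiseDistanceStats(trR, la, lb, "median"), tolerance = 1e-9)
})
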