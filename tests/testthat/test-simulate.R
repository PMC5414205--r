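freeChain <- function(nBeads = 40, P = 5, seed = NULL) {
  g <- genomeSpec(data.frame(name = "cF", length_bp = nBeads * 1500,
                             centromere_bp = round(nBeads * 750)))
  discretizeGenome(g, parameterPoint(P, 50, 30, 300), NULL)
}

test_that("identical seeds and configs give identical trajectories", {
  chains <- discretizeGenome(tinyGenome(), parameterPoint(60, 50, 30, 100),
                             tinyGeometry())
  t1 <- runSimulation(chains, nSteps = 2000, sampleEvery = 500,
                      equilibrationSteps = 0, seed = 11,
                      checkEquilibration = FALSE)
  t2 <- runSimulation(chains, nSteps = 2000, sampleEvery = 500,
                      equilibrationSteps = 0, seed = 11,
                      checkEquilibration = FALSE)
  t3 <- runSimulation(chains, nSteps = 2000, sampleEvery = 500,
                      equilibrationSteps = 0, seed = 12,
                      checkEquilibration = FALSE)
  expect_identical(t1@frames, t2@frames)
  expect_false(identical(t1@frames, t3@frames))
})

test_that("zero temperature and zero forces give zero displacement", {
  chains <- freeChain(5)
  st <- initConfiguration(chains, NULL, seed = 1)
  # place beads exactly at bond rest lengths along a line: all forces zero
  st@positions <- cbind(seq(0, by = 30, length.out = 5), 0, 0)
  ff <- forceField(kExcludedVolume = 0)
  st2 <- langevinStep(st, chains, ff, dt = 0.5, nSteps = 10, kT = 0)
  expect_equal(st2@positions, st@positions, tolerance = 1e-12)
})

test_that("a stretched bond relaxes to its rest length at zero temperature", {
  chains <- freeChain(2)
  st <- initConfiguration(chains, NULL, seed = 1)
  st@positions <- cbind(c(0, 40), 0, 0)  # stretched past r0 = 30
  st2 <- langevinStep(st, chains, forceField(kExcludedVolume = 0), dt = 0.2,
                      nSteps = 500, kT = 0)
  expect_equal(abs(diff(st2@positions[, 1])), 30, tolerance = 1e-3)
})

test_that("a single free bead diffuses per the Einstein relation", {
  chains <- freeChain(1)
  tr <- runSimulation(chains, forceField(kExcludedVolume = 0), nSteps = 4e4,
                      sampleEvery = 10, equilibrationSteps = 0, seed = 3,
                      dt = 0.5, maxDisplacement = 1e6,
                      checkEquilibration = FALSE)
  m <- msd(tr, 1, lags = c(2, 5, 10, 20))
  # MSD(t) = 6 D t with D = kT / gamma = 1 nm^2 per time unit
  expect_equal(m$msd / (6 * m$lag_time), rep(1, 4), tolerance = 0.15)
})

test_that("confined beads stay inside the nuclear envelope", {
  chains <- discretizeGenome(tinyGenome(), parameterPoint(60, 50, 30, 100),
                             tinyGeometry())
  tr <- runSimulation(chains, nSteps = 5000, sampleEvery = 250,
                      equilibrationSteps = 0, seed = 5,
                      checkEquilibration = FALSE)
  r <- sqrt(colSums(matrix(tr@frames, 3)^2))
  expect_true(all(r <= tinyGeometry()@radius + 30))
  # centromeres stay tethered near the SPB within spring reach
  geom <- tinyGeometry()
  for (ci in 1:2) {
    cpos <- tr@frames[, chains@centromereBead[ci], ]
    dspb <- sqrt(colSums((cpos - geom@spbPosition)^2))
    expect_true(all(dspb < chains@params@L + 150))
  }
})

test_that("overcrowded systems are rejected at initialization", {
  g <- genomeSpec(data.frame(name = "big", length_bp = 3e6,
                             centromere_bp = 1.5e6))
  geom <- nucleusGeometry(radius = 60, nRdnaBeads = 0L, rdnaDiameter = 10)
  chains <- discretizeGenome(g, parameterPoint(60, 50, 30, 50), geom)
  expect_error(initConfiguration(chains, geom, seed = 1), "overcrowded")
})

test_that("initial configurations are deterministic and inside the sphere", {
  chains <- discretizeGenome(tinyGenome(), parameterPoint(60, 50, 30, 100),
                             tinyGeometry())
  s1 <- initConfiguration(chains, seed = 9)
  s2 <- initConfiguration(chains, seed = 9)
  expect_identical(s1@positions, s2@positions)
  r <- sqrt(rowSums(s1@positions^2))
  expect_true(all(r <= tinyGeometry()@radius - chains@beadDiameter / 2 + 1e-9))
})

test_that("sample bookkeeping matches the configured windows", {
  chains <- freeChain(5)
  tr <- runSimulation(chains, forceField(kExcludedVolume = 0), nSteps = 1000,
                      sampleEvery = 10, equilibrationSteps = 200, seed = 1,
                      checkEquilibration = FALSE)
  expect_equal(dim(tr@frames)[3], 80)
  expect_equal(tr@steps[1], 210)
  expect_error(runSimulation(chains, nSteps = 100, equilibrationSteps = 100),
               "exceed")
})

test_that("semiflexible phantom chains match the worm-like-chain closed form", {
  P <- 90
  nb <- 100
  chains <- freeChain(nb, P = P)
  ff <- forceField(kExcludedVolume = 0)
  ree2 <- numeric(0)
  for (r in 1:24) {
    tr <- runSimulation(chains, ff, nSteps = 1e4, sampleEvery = 2000,
                        equilibrationSteps = 0, seed = 100 + r, dt = 0.25,
                        checkEquilibration = FALSE)
    d <- tr@frames[, nb, ] - tr@frames[, 1, ]
    ree2 <- c(ree2, mean(colSums(d^2)))
  }
  Lc <- (nb - 1) * 30
  theory <- 2 * P * Lc - 2 * P^2 * (1 - exp(-Lc / P))
  se <- sd(ree2) / sqrt(length(ree2))
  expect_lt(abs(mean(ree2) - theory), 3 * se + 0.02 * theory)
})

test_that("chains do not cross at default excluded-volume settings", {
  chains <- discretizeGenome(tinyGenome(), parameterPoint(60, 50, 30, 100),
                             tinyGeometry())
  tr <- runSimulation(chains, nSteps = 2e4, sampleEvery = 200,
                      equilibrationSteps = 0, seed = 2,
                      checkEquilibration = FALSE)
  gap <- chromInfer:::cpp_min_bond_gap(tr@frames, chains@bonds - 1L)
  # non-adjacent bond segments never approach within a bead radius
  expect_gt(gap, 0.5 * 30 * 0.5)
})

test_that("trajectories persist and export to XYZ text", {
  chains <- freeChain(4)
  tr <- runSimulation(chains, forceField(kExcludedVolume = 0), nSteps = 500,
                      sampleEvery = 100, equilibrationSteps = 0, seed = 1,
                      checkEquilibration = FALSE)
  p <- tempfile(fileext = ".rds")
  writeTrajectory(tr, p)
  tr2 <- readTrajectory(p)
  expect_identical(tr2@frames, tr@frames)
  xyz <- tempfile(fileext = ".xyz")
  exportXYZ(tr, xyz, frames = 1:2)
  lines <- readLines(xyz)
  expect_equal(length(lines), 2 * (4 + 2))
})
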