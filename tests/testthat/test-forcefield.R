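test_that("continuum bending mapping is P / b", {
  expect_equal(bendingConstantFromP(30, 30, mapping = "continuum"), 1.0)
  expect_equal(bendingConstantFromP(69, 30, mapping = "continuum"), 2.3)
  expect_error(bendingConstantFromP(-1, 30), "positive")
  expect_error(bendingConstantFromP(30, 0), "positive")
})

test_that("discrete-corrected mapping reproduces the target tangent decay", {
  # the Langevin-function calibration makes <cos theta> equal exp(-b/P)
  lang <- function(k) 1 / tanh(k) - 1 / k
  for (P in c(27, 69, 150, 252)) {
    k <- bendingConstantFromP(P, 30, mapping = "langevin")
    expect_equal(lang(k), exp(-30 / P), tolerance = 1e-8)
  }
  # continuum limit: both mappings agree when b << P
  expect_equal(bendingConstantFromP(3000, 30),
               bendingConstantFromP(3000, 30, mapping = "continuum"),
               tolerance = 0.01)
})

test_that("simulated free-chain tangent correlations decay as exp(-s/P)", {
  # semiflexible phantom chain; fitted persistence length within 10%.
  # chain-collective modes relax slowly, so the average pools many
  # independent replicas rather than one long run
  P <- 90
  nb <- 40
  g <- genomeSpec(data.frame(name = "cF", length_bp = nb * 1500,
                             centromere_bp = 30000))
  chains <- discretizeGenome(g, parameterPoint(P, 50, 30, 300), NULL)
  ff <- forceField(kExcludedVolume = 0)
  smax <- 6
  cors <- matrix(0, 30, smax)
  for (r in 1:30) {
    tr <- runSimulation(chains, ff, nSteps = 2e4, sampleEvery = 2000,
                        equilibrationSteps = 0, seed = r, dt = 0.25,
                        checkEquilibration = FALSE)
    fr <- tr@frames
    tang <- fr[, -1, , drop = FALSE] - fr[, -nb, , drop = FALSE]
    tn <- sqrt(tang[1, , ]^2 + tang[2, , ]^2 + tang[3, , ]^2)
    for (d in 1:3) tang[d, , ] <- tang[d, , ] / tn
    for (s in seq_len(smax)) {
      i <- 1:(nb - 1 - s)
      cors[r, s] <- mean(tang[1, i, ] * tang[1, i + s, ] +
                         tang[2, i, ] * tang[2, i + s, ] +
                         tang[3, i, ] * tang[3, i + s, ])
    }
  }
  cbar <- colMeans(cors)
  fit <- lm(log(cbar) ~ seq_len(smax))
  Pfit <- -30 / coef(fit)[2]
  expect_equal(unname(Pfit), P, tolerance = 0.1)
})

test_that("force field constructor validates its scales", {
  expect_error(forceField(kBond = -1))
  expect_error(forceField(maxExtension = 0.9))
  ff <- forceField()
  expect_s3_class(ff, "ForceField")
  expect_true(ff$kExcludedVolume > 0)
})
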