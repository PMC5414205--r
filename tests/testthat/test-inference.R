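# helper: wrap a plain log-density as a sampler target
plainTarget <- function(f, names, box = NULL) {
  lp <- function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, 1)
    apply(theta, 1, f)
  }
  attr(lp, "paramNames") <- names
  if (!is.null(box)) attr(lp, "box") <- box
  lp
}

test_that("log-likelihood matches hand-computed Gaussian terms", {
  # sigma = xi * s with s = max(|Y|, 0.1 median|Y|): Y = 2, xi = 0.5 -> sigma 1
  ds <- data.frame(id = "a", dataset = "O5", value = 2, group = "fixed_imaging")
  nu <- c(xi_fixed_imaging = 0.5)
  expect_equal(logLikelihood(ds, c(a = 2), nu), -0.5 * log(2 * pi))
  # residual of one sigma adds -1/2
  expect_equal(logLikelihood(ds, c(a = 1), nu), -0.5 * log(2 * pi) - 0.5)
  # three data, mixed scales, hand-summed
  ds3 <- data.frame(id = c("a", "b", "c"), dataset = "O5",
                    value = c(10, 20, 40), group = "fixed_imaging")
  pred <- c(a = 12, b = 20, c = 30)
  xi <- 0.25
  s <- pmax(abs(ds3$value), 0.1 * median(abs(ds3$value)))
  byHand <- sum(-(ds3$value - pred)^2 / (2 * (xi * s)^2) -
                0.5 * log(2 * pi * (xi * s)^2))
  expect_equal(logLikelihood(ds3, pred, c(xi_fixed_imaging = xi)), byHand)
  expect_error(logLikelihood(ds3, pred[1:2], c(xi_fixed_imaging = xi)),
               "missing prediction")
  expect_error(logLikelihood(ds, c(a = 2), c(xi_fixed_imaging = -1)),
               "non-positive")
})

test_that("posterior support is the flat prior box", {
  grid <- mockGrid(function(P, C) c(P + C, P - C, 2))
  ds <- generateSyntheticDataset(grid, c(P = 80, C = 60), noiseSpec("none"))
  lp <- makeLogPosterior(grid, ds)
  nuis <- c(0.2)
  expect_equal(logPosterior(c(P = 300, C = 60), c(xi_fixed_imaging = 0.2),
                            ds, grid), -Inf)
  v1 <- lp(c(60, 50, 0.2))
  v2 <- lp(c(100, 70, 0.2))
  expect_true(is.finite(v1) && is.finite(v2))
  expect_equal(as.numeric(lp(c(40, 95, 0.2))), -Inf)  # outside C range
  expect_equal(as.numeric(lp(c(60, 50, -0.1))), -Inf) # nuisance support
  # reordering dataset rows leaves the posterior unchanged
  perm <- sample(nrow(ds))
  lpPerm <- makeLogPosterior(grid, ds[perm, ])
  expect_equal(as.numeric(lp(c(77, 44, 0.3))),
               as.numeric(lpPerm(c(77, 44, 0.3))))
})

test_that("ensemble sampler recovers Gaussian moments and is reproducible", {
  mu <- c(2, -1)
  S <- matrix(c(1.0, 0.6, 0.6, 2.0), 2)
  Si <- solve(S)
  f <- function(th) -0.5 * t(th - mu) %*% Si %*% (th - mu)
  lp <- plainTarget(function(v) as.numeric(f(v)), c("x", "y"))
  set.seed(1)
  init <- cbind(rnorm(16, 2), rnorm(16, -1))
  ps <- runEnsembleMCMC(lp, init, nSteps = 3000, seed = 5)
  dr <- posteriorDraws(ps, 0.3)
  expect_equal(unname(colMeans(dr)), mu, tolerance = 0.12)
  expect_equal(unname(cov(dr)), S, tolerance = 0.25)
  ps2 <- runEnsembleMCMC(lp, init, nSteps = 3000, seed = 5)
  expect_identical(ps@draws, ps2@draws)
  expect_error(runEnsembleMCMC(lp, init[1:3, ], nSteps = 10),
               "2 x dimension")
})

test_that("flat targets give uniform marginals on the box", {
  f <- function(v) if (all(v >= 0 & v <= 1)) 0 else -Inf
  lp <- plainTarget(f, c("u1", "u2"))
  set.seed(2)
  init <- matrix(runif(32), 16, 2)
  ps <- runEnsembleMCMC(lp, init, nSteps = 4000, seed = 9)
  dr <- posteriorDraws(ps, 0.3)
  # thin heavily to approximate independence before the GOF test
  u <- dr[seq(1, nrow(dr), by = 97), 1]
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(dr[, 2]), 0.5, tolerance = 0.05)
})

test_that("marginal densities normalize and factor for product targets", {
  set.seed(3)
  dr <- cbind(a = rnorm(20000, 1, 0.5), b = rgamma(20000, 4, 2))
  ps <- new("PosteriorSample", draws = dr, logProb = rep(0, nrow(dr)),
            meta = list(walkers = 20, steps = 1000, burnIn = 0,
                        acceptance = 1, seed = 1))
  md2 <- marginalDensity(ps, c("a", "b"))
  expect_equal(sum(md2$z * md2$cell), 1, tolerance = 1e-6)
  md1 <- marginalDensity(ps, "a")
  expect_equal(sum(md1$z * md1$cell), 1, tolerance = 1e-6)
  # marginal of the independent pair matches the component density
  dx <- density(dr[, "a"], n = 101)
  at <- approx(md1$x, md1$z, xout = dx$x[20:80])$y
  expect_equal(at, dx$y[20:80], tolerance = 0.05)
  expect_error(marginalDensity(ps, "zz"), "unknown parameters")
})

test_that("MAP estimation finds the mode of unimodal targets", {
  set.seed(4)
  dr <- cbind(P = rnorm(12000, 80, 6), C = rnorm(12000, 55, 4))
  ps <- new("PosteriorSample", draws = dr, logProb = rep(0, nrow(dr)),
            meta = list(walkers = 20, steps = 600, burnIn = 0,
                        acceptance = 1, seed = 1))
  m <- mapEstimate(ps, c("P", "C"))
  expect_equal(unname(m$estimate["P"]), 80, tolerance = 2.5)
  expect_equal(unname(m$estimate["C"]), 55, tolerance = 2)
  expect_false(m$multimodal)
})

test_that("credible regions enclose the requested mass and nest", {
  set.seed(6)
  dr <- cbind(x = rnorm(40000), y = rnorm(40000))
  ps <- new("PosteriorSample", draws = dr, logProb = rep(0, nrow(dr)),
            meta = list(walkers = 20, steps = 2000, burnIn = 0,
                        acceptance = 1, seed = 1))
  md <- marginalDensity(ps, c("x", "y"), n = 151)
  r95 <- credibleRegion(md, 0.95)
  r68 <- credibleRegion(md, 0.68)
  expect_equal(r95$mass, 0.95, tolerance = 0.02)
  expect_equal(r68$mass, 0.68, tolerance = 0.02)
  expect_gt(r68$level, r95$level)  # 68% region nested inside 95%
  # standard 2D Gaussian: 95% boundary at Mahalanobis radius^2 = 5.99
  rad95 <- sqrt(qchisq(0.95, df = 2))
  expect_true(regionContains(md, r95, c(x = 0.85 * rad95, y = 0)))
  expect_false(regionContains(md, r95, c(x = 1.25 * rad95, y = 0)))
  expect_error(credibleRegion(md, 1.2), "mass")
})
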