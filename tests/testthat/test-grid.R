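test_that("multilinear interpolation is exact for linear response surfaces", {
  # observables linear in (P, C): interpolation must be exact everywhere
  fun <- function(P, C) c(2 * P + 3 * C, 100 - P + 0.5 * C, P * 0 + 7)
  grid <- mockGrid(fun)
  for (q in list(c(P = 40, C = 30), c(P = 100, C = 45), c(P = 119, C = 89))) {
    got <- observableValues(predictObservables(grid, q))
    expect_equal(unname(got), unname(fun(q[["P"]], q[["C"]])),
                 tolerance = 1e-12)
  }
  # exact at nodes: returns the node's averaged observables
  node <- observableValues(predictObservables(grid, c(P = 80, C = 60)))
  i <- which(grid@points$P == 80 & grid@points$C == 60)
  expect_equal(unname(node), unname(grid@observables[i, ]))
  # extrapolation is an error
  expect_error(predictObservables(grid, c(P = 20, C = 60)), "outside")
  expect_error(predictObservables(grid, c(P = 80, C = 95)), "outside")
})

test_that("interpolation is continuous across cell boundaries", {
  fun <- function(P, C) c(sqrt(P) * C, P + C^1.5, 3)
  grid <- mockGrid(fun)
  eps <- 1e-7
  a <- predictObservables(grid, matrix(c(80 - eps, 50, 80 + eps, 50), 2,
                                       byrow = TRUE,
                                       dimnames = list(NULL, c("P", "C"))))
  expect_equal(a[1, ], a[2, ], tolerance = 1e-4)
})

test_that("grid building runs replicas and records spread", {
  genome <- tinyGenome()
  sch <- buildObservableSchema(genome,
                               counts = c(O1 = 3, O2 = 2, O3 = 2, O4 = 2,
                                          O5 = 2, O6 = 0, O7 = 0),
                               hicBins = c(5000, 10000))
  pts <- expand.grid(P = c(40, 90), C = c(40, 70))
  pts$W <- 30
  pts$L <- 100
  cache <- tempfile("gridcache")
  grid <- buildModelGrid(pts, genome, tinyGeometry(), schema = sch,
                         simConfig = list(nSteps = 4000, sampleEvery = 100,
                                          equilibrationSteps = 1000,
                                          dt = 0.5),
                         nReplicas = 2L, seed = 3, cacheDir = cache)
  expect_equal(nrow(grid@points), 4)
  expect_true(all(grid@points$status == "ok"))
  expect_equal(length(grid@replicates), 4)
  expect_equal(dim(grid@replicates[[1]]), c(2, nrow(sch)))
  expect_true(all(is.finite(grid@observables)))
  # replica spread is reported as a standard error
  expect_equal(grid@stderr[1, ],
               apply(grid@replicates[[1]], 2, sd) / sqrt(2),
               ignore_attr = TRUE)
  # cached rebuild reproduces the identical grid
  grid2 <- buildModelGrid(pts, genome, tinyGeometry(), schema = sch,
                          simConfig = list(nSteps = 4000, sampleEvery = 100,
                                           equilibrationSteps = 1000,
                                           dt = 0.5),
                          nReplicas = 2L, seed = 3, cacheDir = cache)
  expect_identical(grid2@observables, grid@observables)
  man <- tempfile(fileext = ".tsv")
  writeGridManifest(grid, man)
  expect_equal(nrow(readGridManifest(man)), 4)
})

test_that("replica convergence report flags divergent points", {
  grid <- mockGrid(function(P, C) c(P, C, P + C))
  rep1 <- replicaConvergenceReport(grid)
  expect_true(all(rep1$median_cv == 0))
  expect_false(any(rep1$flagged))
  # corrupt one replicate
  grid@replicates[[2]][2, ] <- grid@replicates[[2]][2, ] * 8
  rep2 <- replicaConvergenceReport(grid)
  expect_true(rep2$flagged[2])
  expect_false(rep2$flagged[1])
})

test_that("gradients along P and C follow the polymer scaling signs", {
  # mean intrachromosomal distances from the simulated reduced grid:
  # larger P stretches the fiber, larger C shortens it at fixed bp
  grid <- reducedTestGrid()
  sch <- grid@schema
  intra <- sch$id[sch$dataset %in% c("O5", "O6")]
  ax <- gridAxes(grid)
  val <- function(iP, iC) {
    i <- which(grid@points$P == ax$P[iP] & grid@points$C == ax$C[iC])
    mean(grid@observables[i, intra])
  }
  nP <- length(ax$P); nC <- length(ax$C)
  # grid-range contrasts (replica noise makes single-step contrasts noisy)
  expect_gt(val(nP, 2), val(1, 2))  # stiffer fiber -> longer distances
  expect_gt(val(2, 1), val(2, nC))  # more compact fiber -> shorter distances
})
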