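# Shared fixtures: fabricated trajectories, mock grids, and a lazily built
# reduced-scale simulation grid reused across test files.

# a tiny two-chromosome genome with an rDNA interval on the second
tinyGenome <- function() {
  genomeSpec(data.frame(name = c("tA", "tB"),
                        length_bp = c(15000, 24000),
                        centromere_bp = c(6000, 9000)),
             list(name = "tB", start_bp = 15001, end_bp = 18000))
}

tinyGeometry <- function() {
  nucleusGeometry(radius = 150, nRdnaBeads = 3L, rdnaVolumeFraction = 0.05)
}

# a Trajectory with hand-set coordinates: positions is a list of n x 3
# matrices (one per frame) for the beads of a chain set
fakeTrajectory <- function(chains, frameList, dt = 1, sampleEvery = 1L) {
  nf <- length(frameList)
  n <- nBeads(chains)
  fr <- array(0, dim = c(3, n, nf))
  for (t in seq_len(nf)) fr[, , t] <- t(frameList[[t]])
  new("Trajectory", frames = fr, steps = seq_len(nf), chains = chains,
      dt = dt, sampleEvery = as.integer(sampleEvery), seed = 0,
      rg = rep(1, nf), energy = rep(0, nf))
}

# mock ModelGrid whose observables follow a supplied function of (P, C):
# used to test interpolation, inference and dataset generation without
# simulations (values are synthetic, not simulated)
mockGrid <- function(fun, Ps = c(40, 80, 120), Cs = c(30, 60, 90),
                     schema = NULL, nReplicas = 2L) {
  if (is.null(schema)) {
    schema <- data.frame(id = sprintf("obs_%02d", 1:3),
                         dataset = "O5", class = "mean_3d_distance",
                         chrom_a = "tA", pos_a = 1000, chrom_b = "tA",
                         pos_b = 5000, sep_bp = NA, group = "fixed_imaging")
  }
  pts <- expand.grid(P = Ps, C = Cs)
  pts$W <- 30
  pts$L <- 130
  obs <- t(vapply(seq_len(nrow(pts)),
                  function(i) fun(pts$P[i], pts$C[i]),
                  numeric(nrow(schema))))
  colnames(obs) <- schema$id
  pts$status <- "ok"
  new("ModelGrid", points = pts, observables = obs,
      stderr = obs * 0, replicates = lapply(seq_len(nrow(pts)), function(i)
        matrix(rep(obs[i, ], nReplicas), nReplicas, byrow = TRUE)),
      schema = schema,
      config = list(genome = tinyGenome(), geometry = tinyGeometry(),
                    ff = forceField(), nReplicas = nReplicas, seed = 1,
                    simConfig = list(nSteps = 0, sampleEvery = 1,
                                     equilibrationSteps = 0, dt = 0.5)))
}

# yeast-schema mock grid: per-observable values from a smooth closed-form
# response surface in (P, C) (synthetic stand-in for simulated predictions;
# schema conformance and generator behaviour do not depend on the values)
mockYeastGrid <- function() {
  schema <- buildObservableSchema(yeastGenome())
  isContact <- grepl("contact", schema$class)
  isAngle <- schema$class == "median_angle"
  base <- seq(0.5, 1.5, length.out = nrow(schema))
  fun <- function(P, C) {
    v <- 300 * base * (P / 80)^0.5 * (60 / C)^0.5
    v[isAngle] <- 90 * base[isAngle] / base[isAngle]
    v[isContact] <- pmin(0.05 * base[isContact] * (C / 60), 1)
    v
  }
  mockGrid(fun, schema = schema)
}

# the shared reduced-scale simulation grid (built once per test session)
.testEnv <- new.env(parent = emptyenv())
reducedTestGrid <- function() {
  if (is.null(.testEnv$grid)) {
    .testEnv$grid <- buildReducedGrid(
      seed = 42, nReplicas = 2L,
      simConfig = reducedSimConfig(nSteps = 1.7e5, sampleEvery = 550,
                                   equilibrationSteps = 6e4, dt = 0.5))
  }
  .testEnv$grid
}
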