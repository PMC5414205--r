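# Synthetic-data validation harness: noisy datasets from a chosen
# ground-truth model, parameter-recovery experiments at several noise
# levels, and the rDNA-volume model-mismatch experiment.

#' Synthetic noise specification
#'
#' Relative measurement noise added to model predictions:
#' Y_k^S = Y_k^M0 + e_k with e_k ~ Normal(0, (relSd * |Y_k^M0|)^2).
#' Levels: none = 0, low = 5\%, medium = 10\%, high = 20\% relative
#' standard deviation (high chosen to be at or above realistic
#' experimental noise).
#'
#' @param level "none", "low", "medium" or "high".
#' @param relSd optional explicit relative sd overriding the level.
#' @return list with \code{label} and \code{relSd}.
#' @export
noiseSpec <- function(level = c("none", "low", "medium", "high"),
                      relSd = NULL) {
  level <- match.arg(level)
  if (is.null(relSd))
    relSd <- c(none = 0, low = 0.05, medium = 0.10, high = 0.20)[[level]]
  if (relSd < 0) stop("relative sd must be >= 0")
  list(label = level, relSd = relSd)
}

#' Generate a noisy synthetic dataset from a ground-truth model
#'
#' Predictions at the truth point (a grid node reproduces the node's
#' replica-averaged observables exactly; interior points are interpolated)
#' plus Gaussian noise with per-observable sd \code{relSd * |Y_k|}, clamped
#' to physical ranges (distances >= 0, contact frequencies in [0, 1],
#' angles in [0, 180] degrees).
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param truth a \linkS4class{ParameterPoint} or named numeric of the
#'   grid's varying parameters.
#' @param noise a spec from \code{\link{noiseSpec}}.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return data.frame: the grid schema plus a \code{value} column.
#' @export
generateSyntheticDataset <- function(grid, truth, noise = noiseSpec("low"),
                                     seed = 1) {
  os <- predictObservables(grid, truth)
  y <- observableValues(os)
  schema <- grid@schema
  set.seed(seed)
  yS <- y + rnorm(length(y), 0, noise$relSd * abs(y))
  isDist <- grepl("distance", schema$class)
  isContact <- grepl("contact", schema$class)
  isAngle <- schema$class == "median_angle"
  yS[isDist] <- pmax(yS[isDist], 0)
  yS[isContact] <- pmin(pmax(yS[isContact], 0), 1)
  yS[isAngle] <- pmin(pmax(yS[isAngle], 0), 180)
  ds <- schema
  ds$value <- unname(yS)
  ds
}

# walker initialization: with hundreds of observables the posterior peak
# occupies a tiny fraction of the prior box, so walkers start in a small
# ball around the posterior mode located by multi-start local optimization
# (Nelder-Mead from the best points of a random scan); the stretch move
# then expands the ensemble to the full posterior support
.initWalkers <- function(lp, nWalkers, seed, nScan = 512, nStarts = 5) {
  set.seed(seed)
  box <- attr(lp, "box")
  groups <- attr(lp, "groups")
  nS <- nrow(box)
  d <- nS + length(groups)
  draw <- function(n) {
    m <- matrix(NA_real_, n, d)
    for (j in seq_len(nS)) {
      span <- box$max[j] - box$min[j]
      m[, j] <- runif(n, box$min[j] + 0.02 * span, box$max[j] - 0.02 * span)
    }
    for (g in seq_along(groups))
      m[, nS + g] <- runif(n, 0.05, 0.5)
    m
  }
  clip <- function(th) {
    for (j in seq_len(nS)) {
      span <- box$max[j] - box$min[j]
      th[j] <- min(max(th[j], box$min[j] + 1e-6 * span),
                   box$max[j] - 1e-6 * span)
    }
    for (g in seq_along(groups)) th[nS + g] <- max(th[nS + g], 1e-4)
    th
  }
  scan <- draw(nScan)
  v <- lp(scan)
  starts <- order(v, decreasing = TRUE)[seq_len(nStarts)]
  neglp <- function(th) {
    val <- lp(matrix(clip(th), 1))
    if (!is.finite(val)) 1e12 else -val
  }
  best <- scan[starts[1], ]
  bestv <- -Inf
  for (s0 in starts) {
    o <- tryCatch(stats::optim(scan[s0, ], neglp, method = "Nelder-Mead",
                               control = list(maxit = 400)),
                  error = function(e) NULL)
    if (!is.null(o) && -o$value > bestv) {
      bestv <- -o$value
      best <- clip(o$par)
    }
  }
  init <- matrix(NA_real_, nWalkers, d,
                 dimnames = list(NULL, attr(lp, "paramNames")))
  for (w in seq_len(nWalkers)) {
    cand <- best
    for (j in seq_len(nS)) {
      span <- box$max[j] - box$min[j]
      cand[j] <- cand[j] + rnorm(1, 0, 0.005 * span)
    }
    for (g in seq_along(groups))
      cand[nS + g] <- cand[nS + g] * exp(rnorm(1, 0, 0.05))
    init[w, ] <- clip(cand)
  }
  init
}

# one inference pass: dataset -> posterior -> MAP and coverage
.inferOnce <- function(grid, dataset, mcmc, seed, params = NULL) {
  lp <- makeLogPosterior(grid, dataset)
  if (is.null(params)) params <- head(attr(lp, "paramNames"), 2)
  init <- .initWalkers(lp, mcmc$walkers, seed)
  ps <- runEnsembleMCMC(lp, init, nSteps = mcmc$steps, seed = seed + 1,
                        burnIn = mcmc$burnIn)
  map <- mapEstimate(ps, params)
  md <- marginalDensity(ps, params)
  r68 <- credibleRegion(md, 0.68)
  r95 <- credibleRegion(md, 0.95)
  list(posterior = ps, map = map$estimate, md = md, r68 = r68, r95 = r95)
}

#' Parameter-recovery experiment on synthetic data
#'
#' For each ground-truth point and repeat: generate a noisy synthetic
#' dataset, run the full inference (ensemble MCMC over structural and
#' nuisance parameters), record the MAP estimate of the structural
#' parameters of interest and whether the 68\%/95\% credible regions cover
#' the truth.  Reports per-truth RMS errors.
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param truthPoints data.frame of ground-truth parameter values (columns
#'   = the grid's varying parameters).
#' @param noise a \code{\link{noiseSpec}}.
#' @param nRepeats repeats per truth point.
#' @param mcmc list with walkers, steps, burnIn.
#' @param seed master seed.
#' @param params structural parameters summarized (default first two
#'   varying axes, i.e. (P, C)).
#' @return list of class \code{RecoveryResult}: \code{runs} (one row per
#'   repeat), \code{rms} (per truth x parameter), \code{coverage}, and the
#'   noise label.
#' @export
recoveryExperiment <- function(grid, truthPoints, noise = noiseSpec("low"),
                               nRepeats = 3,
                               mcmc = list(walkers = 24, steps = 600,
                                           burnIn = 0.4),
                               seed = 1, params = NULL) {
  ax <- gridAxes(grid)
  if (is.null(params)) params <- head(names(ax), 2)
  runs <- list()
  for (ti in seq_len(nrow(truthPoints))) {
    truth <- unlist(truthPoints[ti, names(ax), drop = TRUE])
    for (r in seq_len(nRepeats)) {
      s <- seed + 997 * ti + 13 * r
      ds <- generateSyntheticDataset(grid, truth, noise, seed = s)
      fit <- .inferOnce(grid, ds, mcmc, seed = s + 1, params = params)
      rec <- data.frame(truth_id = ti, rep = r)
      for (p in params) {
        rec[[paste0("truth_", p)]] <- truth[[p]]
        rec[[paste0("map_", p)]] <- fit$map[[p]]
      }
      rec$covered68 <- regionContains(fit$md, fit$r68, truth[params])
      rec$covered95 <- regionContains(fit$md, fit$r95, truth[params])
      runs[[length(runs) + 1]] <- rec
    }
  }
  runs <- do.call(rbind, runs)
  rms <- do.call(rbind, lapply(unique(runs$truth_id), function(ti) {
    sub <- runs[runs$truth_id == ti, ]
    out <- data.frame(truth_id = ti)
    for (p in params)
      out[[paste0("rms_", p)]] <-
        sqrt(mean((sub[[paste0("map_", p)]] - sub[[paste0("truth_", p)]])^2))
    out
  }))
  structure(list(runs = runs, rms = rms,
                 coverage = c(c68 = mean(runs$covered68),
                              c95 = mean(runs$covered95)),
                 noise = noise$label, params = params),
            class = "RecoveryResult")
}

#' @export
print.RecoveryResult <- function(x, ...) {
  cat(sprintf("RecoveryResult: %d runs at noise '%s'\n", nrow(x$runs), x$noise))
  print(x$rms, row.names = FALSE)
  cat(sprintf("coverage: 68%% = %.2f, 95%% = %.2f\n",
              x$coverage["c68"], x$coverage["c95"]))
  invisible(x)
}

#' rDNA-volume model-mismatch experiment
#'
#' Generates synthetic data from fresh simulations in which the rDNA bead
#' diameter is changed so the net nucleolar volume fraction V departs from
#' the value baked into the grid, then infers with the unmodified grid.
#' Quantifies robustness of the inference to model mismatch.
#'
#' @param grid a \linkS4class{ModelGrid} (its config supplies genome,
#'   geometry, force field and simulation settings).
#' @param vFractions vector of net nucleolar volume fractions in (0, 1).
#' @param truth ground-truth structural parameters (default: the grid node
#'   closest to the centre of the grid box).
#' @param noise a \code{\link{noiseSpec}}.
#' @param nReplicas mismatch simulations averaged per V.
#' @param mcmc,seed,params as in \code{\link{recoveryExperiment}}.
#' @return data.frame per V with MAP errors for each parameter.
#' @export
mismatchExperiment <- function(grid, vFractions = c(0.05, 0.10, 0.14, 0.16,
                                                    0.20, 0.30),
                               truth = NULL, noise = noiseSpec("none"),
                               nReplicas = 2,
                               mcmc = list(walkers = 24, steps = 600,
                                           burnIn = 0.4),
                               seed = 1, params = NULL) {
  if (any(vFractions <= 0 | vFractions >= 1)) stop("V must lie in (0, 1)")
  cfg <- grid@config
  ax <- gridAxes(grid)
  if (is.null(params)) params <- head(names(ax), 2)
  if (is.null(truth)) {
    ctr <- vapply(ax, function(v) v[ceiling(length(v) / 2)], 0)
    truth <- ctr
  }
  fullTruth <- c(P = grid@points$P[1], C = grid@points$C[1],
                 W = grid@points$W[1], L = grid@points$L[1])
  fullTruth[names(truth)] <- truth
  pp <- parameterPoint(fullTruth["P"], fullTruth["C"], fullTruth["W"],
                       fullTruth["L"])
  geom0 <- cfg$geometry
  out <- list()
  for (vi in seq_along(vFractions)) {
    V <- vFractions[vi]
    geomV <- nucleusGeometry(
      radius = geom0@radius,
      rdnaDiameter = rdnaDiameterFromVolumeFraction(V, geom0@radius,
                                                    geom0@nRdnaBeads),
      nRdnaBeads = geom0@nRdnaBeads,
      spbPosition = geom0@spbPosition)
    chains <- discretizeGenome(cfg$genome, pp, geomV)
    repMat <- matrix(NA_real_, nReplicas, nrow(grid@schema))
    for (r in seq_len(nReplicas)) {
      s <- seed + 131 * vi + r
      traj <- suppressWarnings(runSimulation(
        chains, cfg$ff, nSteps = cfg$simConfig$nSteps,
        sampleEvery = cfg$simConfig$sampleEvery,
        equilibrationSteps = cfg$simConfig$equilibrationSteps,
        seed = s, dt = cfg$simConfig$dt, checkEquilibration = FALSE))
      set.seed(s + 131)
      repMat[r, ] <- observableValues(computeObservables(traj, grid@schema))
    }
    y <- colMeans(repMat)
    ds <- grid@schema
    set.seed(seed + 917 * vi)
    yS <- y + rnorm(length(y), 0, noise$relSd * abs(y))
    ds$value <- pmax(yS, 0)
    isContact <- grepl("contact", ds$class)
    ds$value[isContact] <- pmin(ds$value[isContact], 1)
    fit <- .inferOnce(grid, ds, mcmc, seed = seed + 917 * vi + 1,
                      params = params)
    rec <- data.frame(V = V)
    for (p in params) {
      rec[[paste0("truth_", p)]] <- fullTruth[[p]]
      rec[[paste0("map_", p)]] <- fit$map[[p]]
      rec[[paste0("err_", p)]] <- abs(fit$map[[p]] - fullTruth[[p]])
    }
    out[[vi]] <- rec
  }
  do.call(rbind, out)
}

# ---- reduced-scale defaults -----------------------------------------------

#' Reduced-scale study geometry and grid defaults
#'
#' Desk-scale defaults for the validation harness: the three-chromosome
#' \code{\link{reducedGenome}} inside a 360 nm nucleus (preserving the
#' genome-bp per nuclear-volume ratio of the full yeast system), 30 rDNA
#' beads at the standard nucleolar volume fraction V = 14\%, fixed fiber
#' width W = 30 nm and tether length L = 130 nm, and a (P, C) lattice of
#' 4 x 3 nodes spanning P = 40-160 nm, C = 30-90 bp/nm.
#'
#' @return \code{reducedGeometry}: a \linkS4class{NucleusGeometry}.
#' @export
reducedGeometry <- function() {
  nucleusGeometry(radius = 360, nRdnaBeads = 30L, rdnaVolumeFraction = 0.14)
}

#' @rdname reducedGeometry
#' @export
reducedGridPoints <- function() {
  pts <- expand.grid(P = c(40, 80, 120, 160), C = c(30, 60, 90))
  pts$W <- 30
  pts$L <- 130
  pts
}

#' @rdname reducedGeometry
#' @param nSteps,sampleEvery,equilibrationSteps,dt simulation settings.
#' @export
reducedSimConfig <- function(nSteps = 3e5, sampleEvery = 1000,
                             equilibrationSteps = 1e5, dt = 0.5) {
  list(nSteps = nSteps, sampleEvery = sampleEvery,
       equilibrationSteps = equilibrationSteps, dt = dt)
}

#' @rdname reducedGeometry
#' @param seed master seed for the grid build.
#' @param nReplicas replicas per grid point.
#' @param simConfig simulation settings.
#' @param cacheDir optional cache directory.
#' @param verbose print progress.
#' @export
buildReducedGrid <- function(seed = 1, nReplicas = 2L,
                             simConfig = reducedSimConfig(), cacheDir = NULL,
                             verbose = FALSE) {
  genome <- reducedGenome()
  buildModelGrid(reducedGridPoints(), genome, reducedGeometry(),
                 schema = buildObservableSchema(genome),
                 simConfig = simConfig, nReplicas = nReplicas, seed = seed,
                 cacheDir = cacheDir, verbose = verbose)
}

#' @rdname reducedGeometry
#' @export
reducedTruthPoints <- function() {
  data.frame(P = c(80, 120), C = c(60, 60))
}
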