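# The simulation library over discrete parameter points and its
# multilinear interpolating surrogate.

#' Build a model grid of simulated parameter points
#'
#' Runs (or loads from cache) \code{nReplicas} independent simulations per
#' parameter point, differing only by seed, computes the observable schema
#' on each, and stores replica-averaged observables with their
#' between-replica standard errors.  A failed simulation marks its point
#' unusable rather than aborting the build.
#'
#' @param points data.frame with columns P, C, W, L (one row per point).
#' @param genome a \linkS4class{GenomeSpec}.
#' @param geometry a \linkS4class{NucleusGeometry} (fixed across points:
#'   the rDNA bead count and diameter do not vary with the structural
#'   parameters).
#' @param schema observable schema; default from
#'   \code{\link{buildObservableSchema}}.
#' @param ff force field.
#' @param simConfig list with nSteps, sampleEvery, equilibrationSteps, dt.
#' @param nReplicas replicas per point (>= 2).
#' @param seed master seed; replica seeds derive deterministically from it.
#' @param cacheDir optional directory for per-replica result caching
#'   (keyed by point, replica seed and simulation settings), making grid
#'   builds resumable.
#' @param verbose print progress.
#' @return a \linkS4class{ModelGrid}.
#' @export
buildModelGrid <- function(points, genome, geometry,
                           schema = buildObservableSchema(genome),
                           ff = forceField(),
                           simConfig = list(nSteps = 3e5, sampleEvery = 1000,
                                            equilibrationSteps = 1e5,
                                            dt = 0.5),
                           nReplicas = 2L, seed = 1, cacheDir = NULL,
                           verbose = FALSE) {
  stopifnot(nReplicas >= 2)
  points <- as.data.frame(points)[, c("P", "C", "W", "L")]
  K <- nrow(schema)
  npt <- nrow(points)
  obs <- se <- matrix(NA_real_, npt, K, dimnames = list(NULL, schema$id))
  reps <- vector("list", npt)
  status <- rep("ok", npt)
  cfgKey <- paste(simConfig$nSteps, simConfig$sampleEvery,
                  simConfig$equilibrationSteps, simConfig$dt, K, sep = "-")
  for (i in seq_len(npt)) {
    pp <- parameterPoint(points$P[i], points$C[i], points$W[i], points$L[i])
    repMat <- matrix(NA_real_, nReplicas, K)
    ok <- TRUE
    for (r in seq_len(nReplicas)) {
      repSeed <- seed + 7919 * i + r
      cf <- if (is.null(cacheDir)) NULL else
        file.path(cacheDir, sprintf("pt_%g_%g_%g_%g_rep%d_s%d_%s.rds",
                                    pp@P, pp@C, pp@W, pp@L, r, repSeed, cfgKey))
      if (!is.null(cf) && file.exists(cf)) {
        repMat[r, ] <- readRDS(cf)
        next
      }
      res <- tryCatch({
        chains <- discretizeGenome(genome, pp, geometry)
        traj <- suppressWarnings(runSimulation(
          chains, ff, nSteps = simConfig$nSteps,
          sampleEvery = simConfig$sampleEvery,
          equilibrationSteps = simConfig$equilibrationSteps,
          seed = repSeed, dt = simConfig$dt, checkEquilibration = FALSE))
        set.seed(repSeed + 131)
        observableValues(computeObservables(traj, schema))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        status[i] <- paste("failed:", conditionMessage(res))
        ok <- FALSE
        break
      }
      repMat[r, ] <- res
      if (!is.null(cf)) {
        dir.create(dirname(cf), recursive = TRUE, showWarnings = FALSE)
        saveRDS(res, cf)
      }
    }
    if (ok) {
      obs[i, ] <- colMeans(repMat)
      se[i, ] <- apply(repMat, 2, sd) / sqrt(nReplicas)
      reps[[i]] <- repMat
    }
    if (verbose)
      message(sprintf("point %d/%d (P=%g C=%g): %s", i, npt,
                      pp@P, pp@C, status[i]))
  }
  pts <- points
  pts$status <- status
  new("ModelGrid", points = pts, observables = obs, stderr = se,
      replicates = reps, schema = schema,
      config = list(genome = genome, geometry = geometry, ff = ff,
                    simConfig = simConfig, nReplicas = nReplicas, seed = seed))
}

# lattice bookkeeping: map grid rows onto the tensor-product index array
.gridLattice <- function(grid) {
  ax <- gridAxes(grid)
  if (!length(ax)) stop("grid has a single point; nothing to interpolate")
  dims <- lengths(ax)
  idx <- sapply(names(ax), function(p) match(grid@points[[p]], ax[[p]]))
  idx <- matrix(idx, ncol = length(ax))
  lin <- as.integer(1 + (idx - 1) %*% cumprod(c(1, dims[-length(dims)])))
  A <- rep(NA_integer_, prod(dims))
  A[lin] <- seq_len(nrow(grid@points))
  if (anyNA(A)) stop("grid points do not form a complete lattice")
  list(axes = ax, dims = dims, A = A)
}

#' Interpolate predicted observables at arbitrary parameter values
#'
#' Piecewise-multilinear interpolation on the lattice of simulated points:
#' exact at lattice nodes, continuous across cell boundaries.  Queries
#' outside the per-axis grid range are an error (the inference prior box
#' must lie within the grid).
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param query a \linkS4class{ParameterPoint}, a named numeric vector of
#'   the varying parameters, or a matrix with one query per row.
#' @return an \linkS4class{ObservableSet} for a single query, otherwise a
#'   matrix (queries x observables).
#' @export
predictObservables <- function(grid, query) {
  lat <- .gridLattice(grid)
  ax <- lat$axes
  single <- FALSE
  if (is(query, "ParameterPoint")) {
    query <- c(P = query@P, C = query@C, W = query@W, L = query@L)
  }
  if (is.null(dim(query))) {
    query <- matrix(query, 1, dimnames = list(NULL, names(query)))
    single <- TRUE
  }
  miss <- setdiff(names(ax), colnames(query))
  if (length(miss)) stop("query missing parameters: ", paste(miss, collapse = ", "))
  nq <- nrow(query)
  d <- length(ax)
  iLo <- w <- matrix(0, nq, d)
  for (j in seq_len(d)) {
    v <- query[, names(ax)[j]]
    axv <- ax[[j]]
    if (any(v < min(axv) - 1e-9) || any(v > max(axv) + 1e-9))
      stop(sprintf("query outside grid range for %s [%g, %g]",
                   names(ax)[j], min(axv), max(axv)))
    lo <- pmin(pmax(findInterval(v, axv), 1L), length(axv) - 1L)
    iLo[, j] <- lo
    w[, j] <- (v - axv[lo]) / (axv[lo + 1] - axv[lo])
  }
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  stride <- cumprod(c(1, lat$dims[-d]))
  out <- matrix(0, nq, ncol(grid@observables),
                dimnames = list(NULL, colnames(grid@observables)))
  for (cc in seq_len(nrow(corners))) {
    off <- corners[cc, ]
    lin <- 1 + (iLo - 1 + matrix(off, nq, d, byrow = TRUE)) %*% stride
    rows <- lat$A[as.integer(lin)]
    wt <- rep(1, nq)
    for (j in seq_len(d))
      wt <- wt * (if (off[j] == 1) w[, j] else 1 - w[, j])
    bad <- grid@points$status[rows] != "ok"
    if (any(bad & wt > 1e-12)) stop("interpolation touches a failed grid point")
    out <- out + wt * grid@observables[rows, , drop = FALSE]
  }
  if (single) {
    return(new("ObservableSet", values = setNames(out[1, ], colnames(out)),
               stderr = setNames(rep(NA_real_, ncol(out)), colnames(out)),
               schema = grid@schema))
  }
  out
}

#' Between-replica convergence diagnostics
#'
#' Per-point, per-observable coefficient of variation across replicas;
#' points whose median CV exceeds the threshold are flagged.
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param cvThreshold flagging threshold on the median CV.
#' @return data.frame: point parameters, median and maximum CV, flag.
#' @export
replicaConvergenceReport <- function(grid, cvThreshold = 0.5) {
  res <- lapply(seq_len(nrow(grid@points)), function(i) {
    rm_ <- grid@replicates[[i]]
    if (is.null(rm_)) {
      return(data.frame(grid@points[i, c("P", "C", "W", "L")],
                        median_cv = NA, max_cv = NA, flagged = TRUE))
    }
    mu <- colMeans(rm_)
    cv <- apply(rm_, 2, sd) / pmax(abs(mu), 1e-12)
    data.frame(grid@points[i, c("P", "C", "W", "L")],
               median_cv = median(cv, na.rm = TRUE),
               max_cv = max(cv, na.rm = TRUE),
               flagged = median(cv, na.rm = TRUE) > cvThreshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write / read a grid manifest as delimited text
#'
#' One row per point: parameters, replica count, status.  (Observable
#' values travel with the serialized grid; the manifest mirrors the run
#' bookkeeping.)
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param path output path.
#' @export
writeGridManifest <- function(grid, path) {
  df <- grid@points
  df$n_replicas <- grid@config$nReplicas
  df$seed <- grid@config$seed
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridManifest
#' @export
readGridManifest <- function(path) read.delim(path)
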