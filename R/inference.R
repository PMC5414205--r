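# Bayesian inference of structural parameters: Gaussian likelihood with
# per-group variance nuisance parameters, flat structural priors on the
# grid box, affine-invariant ensemble MCMC, KDE marginals, MAP and
# highest-density credible regions.

# per-observable noise scale: sigma_k = xi_group * scale_k with
# scale_k = max(|Y_k|, 0.1 * median |Y| of the observable's dataset)
.noiseScales <- function(dataset) {
  med <- stats::ave(abs(dataset$value), dataset$dataset,
                    FUN = function(v) median(v))
  pmax(abs(dataset$value), 0.1 * med, 1e-12)
}

#' Gaussian log-likelihood of a dataset under model predictions
#'
#' Sum over measurements k of
#' \eqn{-(Y_k^E - Y_k^M)^2 / (2 sigma_k^2) - log(2 pi sigma_k^2) / 2},
#' where the unknown variances are parameterized per data group g
#' (live_imaging, fixed_imaging, hic_A, hic_B) as
#' \eqn{sigma_k = xi_g s_k} with a per-observable scale \eqn{s_k}
#' proportional to the measured magnitude.
#'
#' @param dataset data.frame with columns id, value, group.
#' @param predictions named numeric vector covering all dataset ids.
#' @param nuisance named numeric vector of positive scales, one per group
#'   (names \code{xi_<group>}).
#' @return log-likelihood scalar.
#' @export
logLikelihood <- function(dataset, predictions, nuisance) {
  miss <- setdiff(dataset$id, names(predictions))
  if (length(miss)) stop("missing prediction ids: ", paste(miss, collapse = ", "))
  xi <- nuisance[paste0("xi_", dataset$group)]
  if (anyNA(xi)) stop("missing nuisance component for some group")
  if (any(xi <= 0)) stop("non-positive nuisance variance scale")
  s <- .noiseScales(dataset)
  sig2 <- (xi * s)^2
  r <- dataset$value - predictions[dataset$id]
  sum(-r^2 / (2 * sig2) - 0.5 * log(2 * pi * sig2))
}

#' Construct the log-posterior over (structural, nuisance) parameters
#'
#' Flat priors on the structural parameters inside \code{priorBox} (default
#' the grid's own per-axis range, the widest admissible box since the
#' surrogate cannot extrapolate), broad half-normal priors on the per-group
#' noise scales.  The returned function accepts a parameter vector or a
#' matrix (one point per row) and returns log-posterior values, -Inf
#' outside the support.
#'
#' @param grid a \linkS4class{ModelGrid}.
#' @param dataset data.frame with columns id, value, group.
#' @param priorBox data.frame (param, min, max) for the varying structural
#'   parameters; must lie within the grid ranges.
#' @param nuisanceScale scale of the half-normal prior on each xi.
#' @return log-posterior function with attributes \code{paramNames} and
#'   \code{box} (support bounds used for initialization).
#' @export
makeLogPosterior <- function(grid, dataset, priorBox = NULL,
                             nuisanceScale = 0.5) {
  ax <- gridAxes(grid)
  vn <- names(ax)
  if (is.null(priorBox))
    priorBox <- data.frame(param = vn,
                           min = vapply(ax, min, 0),
                           max = vapply(ax, max, 0))
  priorBox <- priorBox[match(vn, priorBox$param), ]
  for (j in seq_along(vn)) {
    if (priorBox$min[j] < min(ax[[j]]) - 1e-9 ||
        priorBox$max[j] > max(ax[[j]]) + 1e-9)
      stop("prior box exceeds grid range for ", vn[j])
  }
  groups <- sort(unique(dataset$group))
  xin <- paste0("xi_", groups)
  s <- .noiseScales(dataset)
  ids <- dataset$id
  miss <- setdiff(ids, colnames(grid@observables))
  if (length(miss)) stop("dataset ids absent from grid schema: ",
                         paste(miss, collapse = ", "))
  y <- dataset$value
  gidx <- match(dataset$group, groups)
  d <- length(vn) + length(groups)
  lp <- function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, 1)
    stopifnot(ncol(theta) == d)
    th <- theta[, seq_along(vn), drop = FALSE]
    colnames(th) <- vn
    xi <- theta[, length(vn) + seq_along(groups), drop = FALSE]
    out <- rep(-Inf, nrow(theta))
    inBox <- rep(TRUE, nrow(theta))
    for (j in seq_along(vn))
      inBox <- inBox & th[, j] >= priorBox$min[j] & th[, j] <= priorBox$max[j]
    inBox <- inBox & apply(xi > 0, 1, all)
    if (!any(inBox)) return(out)
    pred <- predictObservables(grid, th[inBox, , drop = FALSE])[, ids, drop = FALSE]
    xiIn <- xi[inBox, , drop = FALSE]
    res <- sweep(pred, 2, y)  # pred - y per row
    sigma <- xiIn[, gidx, drop = FALSE] * matrix(s, sum(inBox), length(s),
                                                 byrow = TRUE)
    ll <- rowSums(-res^2 / (2 * sigma^2) - 0.5 * log(2 * pi * sigma^2))
    lprior <- rowSums(-xiIn^2 / (2 * nuisanceScale^2))
    out[inBox] <- ll + lprior
    out
  }
  attr(lp, "paramNames") <- c(vn, xin)
  attr(lp, "box") <- priorBox
  attr(lp, "groups") <- groups
  lp
}

#' Log-posterior at a single structural/nuisance point
#'
#' Convenience evaluation of \code{\link{makeLogPosterior}} at one point.
#'
#' @param params named numeric of structural parameters (the grid's varying
#'   axes).
#' @param nuisance named numeric of per-group scales (xi_<group>).
#' @param dataset measurement data.frame.
#' @param grid a \linkS4class{ModelGrid}.
#' @param ... passed to \code{\link{makeLogPosterior}}.
#' @return log-posterior scalar (-Inf outside the prior support).
#' @export
logPosterior <- function(params, nuisance, dataset, grid, ...) {
  lp <- makeLogPosterior(grid, dataset, ...)
  pn <- attr(lp, "paramNames")
  theta <- c(params, nuisance)[pn]
  if (anyNA(theta)) {
    # points outside the grid box cannot be interpolated: treat structural
    # values beyond the axes as prior exclusions
    ax <- gridAxes(grid)
    vn <- names(ax)
    sv <- params[vn]
    if (any(sv < vapply(ax, min, 0) | sv > vapply(ax, max, 0))) return(-Inf)
    stop("parameter names do not match: need ", paste(pn, collapse = ", "))
  }
  as.numeric(lp(theta))
}

#' Affine-invariant ensemble MCMC (stretch move)
#'
#' Goodman-Weare ensemble sampler: walkers updated in two half-ensembles,
#' each walker proposing a stretch move along the line to a randomly chosen
#' partner from the other half, with scale z drawn from g(z) proportional
#' to 1/sqrt(z) on [1/a, a].  Reproducible given the seed.
#'
#' @param logPost vectorized log-posterior (matrix in, vector out), e.g.
#'   from \code{\link{makeLogPosterior}}.
#' @param init nWalkers x nParams matrix of starting positions with finite
#'   log-posterior; nWalkers must be at least twice the dimension.
#' @param nSteps ensemble steps.
#' @param seed RNG seed.
#' @param a stretch scale parameter.
#' @param burnIn fraction recorded in the metadata (used by downstream
#'   summaries as the default).
#' @return a \linkS4class{PosteriorSample}; an acceptance fraction below
#'   0.05 triggers a stuck-sampler warning.
#' @export
runEnsembleMCMC <- function(logPost, init, nSteps = 1000, seed = 1, a = 2,
                            burnIn = 0.25) {
  set.seed(seed)
  nw <- nrow(init)
  d <- ncol(init)
  if (nw < 2 * d) stop("need at least 2 x dimension walkers")
  pn <- attr(logPost, "paramNames")
  if (is.null(pn)) pn <- colnames(init)
  if (is.null(pn)) pn <- paste0("par", seq_len(d))
  x <- as.matrix(init)
  lpx <- logPost(x)
  if (any(!is.finite(lpx))) stop("initial walkers must have finite log-posterior")
  draws <- matrix(NA_real_, nw * nSteps, d, dimnames = list(NULL, pn))
  lps <- numeric(nw * nSteps)
  nAcc <- 0
  halves <- list(seq_len(floor(nw / 2)), (floor(nw / 2) + 1):nw)
  for (step in seq_len(nSteps)) {
    for (h in 1:2) {
      mv <- halves[[h]]
      ot <- halves[[3 - h]]
      partner <- ot[sample.int(length(ot), length(mv), replace = TRUE)]
      z <- ((a - 1) * runif(length(mv)) + 1)^2 / a
      prop <- x[partner, , drop = FALSE] +
        z * (x[mv, , drop = FALSE] - x[partner, , drop = FALSE])
      lpp <- logPost(prop)
      logr <- (d - 1) * log(z) + lpp - lpx[mv]
      acc <- log(runif(length(mv))) < logr
      x[mv[acc], ] <- prop[acc, , drop = FALSE]
      lpx[mv[acc]] <- lpp[acc]
      nAcc <- nAcc + sum(acc)
    }
    rows <- (step - 1) * nw + seq_len(nw)
    draws[rows, ] <- x
    lps[rows] <- lpx
  }
  accFrac <- nAcc / (nw * nSteps)
  if (accFrac < 0.05)
    warning(sprintf("ensemble appears stuck: acceptance fraction %.3f", accFrac))
  new("PosteriorSample", draws = draws, logProb = lps,
      meta = list(walkers = nw, steps = nSteps, burnIn = burnIn,
                  acceptance = accFrac, seed = seed,
                  box = attr(logPost, "box")))
}

#' Kernel-smoothed marginal posterior density
#'
#' Marginal of the posterior draws over a subset of one or two parameters,
#' normalized to integrate to 1 on its own grid.
#'
#' @param ps a \linkS4class{PosteriorSample}.
#' @param params character vector of 1 or 2 parameter names.
#' @param burnIn fraction of each walker chain dropped (default from the
#'   sampler metadata).
#' @param n grid points per axis.
#' @return list with \code{params}, axes (\code{x}, and \code{y} in 2D),
#'   density (\code{z}), cell area and bandwidths; class
#'   \code{"MarginalDensity"}.
#' @export
marginalDensity <- function(ps, params, burnIn = ps@meta$burnIn, n = 101) {
  dr <- posteriorDraws(ps, burnIn)
  if (nrow(dr) < 1000)
    stop("need >= 1000 draws after burn-in for a stable marginal")
  miss <- setdiff(params, colnames(dr))
  if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
  if (length(params) == 1) {
    v <- dr[, params]
    de <- density(v, n = n)
    dx <- diff(de$x[1:2])
    z <- de$y / sum(de$y * dx)
    out <- list(params = params, x = de$x, z = z, cell = dx, bw = de$bw)
  } else if (length(params) == 2) {
    vx <- dr[, params[1]]; vy <- dr[, params[2]]
    hx <- MASS::bandwidth.nrd(vx); hy <- MASS::bandwidth.nrd(vy)
    if (hx <= 0) hx <- max(diff(range(vx)) / 10, 1e-6)
    if (hy <= 0) hy <- max(diff(range(vy)) / 10, 1e-6)
    lims <- c(range(vx) + c(-1, 1) * hx, range(vy) + c(-1, 1) * hy)
    kd <- MASS::kde2d(vx, vy, h = c(hx, hy), n = n, lims = lims)
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    z <- kd$z / sum(kd$z * cell)
    out <- list(params = params, x = kd$x, y = kd$y, z = z, cell = cell,
                bw = c(hx, hy) / 4)  # kde2d's h is 4 x the Gaussian sd
  } else stop("params must have length 1 or 2")
  structure(out, class = "MarginalDensity")
}

#' Maximum a posteriori estimate
#'
#' Default: argmax of the kernel-smoothed joint marginal of the requested
#' parameters (matching the density-based presentation of posteriors).
#' Alternative \code{method = "draw"}: the draw with the highest sampled
#' log-posterior (joint argmax, no smoothing).
#'
#' @param ps a \linkS4class{PosteriorSample}.
#' @param params parameters of interest (1 or 2 for the marginal method).
#' @param method "marginal" or "draw".
#' @param burnIn burn-in fraction.
#' @return list with \code{estimate} (named numeric), \code{method} and
#'   \code{multimodal} flag (a second density peak within 20\% of the max).
#' @export
mapEstimate <- function(ps, params = c("P", "C"),
                        method = c("marginal", "draw"),
                        burnIn = ps@meta$burnIn) {
  method <- match.arg(method)
  if (method == "draw") {
    dr <- posteriorDraws(ps, burnIn)
    lp <- tail(ps@logProb, nrow(dr))
    best <- dr[which.max(lp), params]
    return(list(estimate = setNames(as.numeric(best), params),
                method = method, multimodal = NA))
  }
  md <- marginalDensity(ps, params, burnIn)
  if (length(params) == 1) {
    i <- which.max(md$z)
    est <- setNames(md$x[i], params)
    zz <- md$z
    loc <- which(diff(sign(diff(zz))) == -2) + 1
  } else {
    i <- which(md$z == max(md$z), arr.ind = TRUE)[1, ]
    est <- setNames(c(md$x[i[1]], md$y[i[2]]), params)
    zz <- md$z
    loc <- which(zz > 0.8 * max(zz))
  }
  # crude multimodality screen: any near-max density cell well outside the
  # central spread of the draws
  multimodal <- FALSE
  if (length(params) == 2) {
    dr <- posteriorDraws(ps, burnIn)
    sdx <- sd(dr[, params[1]])
    sdy <- sd(dr[, params[2]])
    cand <- which(md$z > 0.8 * max(md$z), arr.ind = TRUE)
    dx <- abs(md$x[cand[, 1]] - est[1]) > pmax(2 * sdx, 4 * md$bw[1])
    dy <- abs(md$y[cand[, 2]] - est[2]) > pmax(2 * sdy, 4 * md$bw[2])
    multimodal <- any(dx & dy)
  }
  list(estimate = est, method = method, multimodal = multimodal)
}

#' Highest-density credible region
#'
#' Iso-density region of a (1D or 2D) marginal enclosing the requested
#' probability mass.
#'
#' @param md a \code{MarginalDensity} from \code{\link{marginalDensity}}.
#' @param mass probability mass in (0, 1), typically 0.68 or 0.95.
#' @return list with the density \code{level}, achieved \code{mass}, and in
#'   2D the contour \code{polygons} (from \code{grDevices::contourLines}).
#' @export
credibleRegion <- function(md, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  z <- as.numeric(md$z)
  o <- order(z, decreasing = TRUE)
  cum <- cumsum(z[o] * md$cell)
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- length(z)
  level <- z[o][k]
  out <- list(level = level, mass = sum(z[z >= level] * md$cell),
              requested = mass)
  if (!is.null(md$y))
    out$polygons <- grDevices::contourLines(md$x, md$y, md$z, levels = level)
  out
}

#' Test whether a point lies inside a credible region
#'
#' @param md the \code{MarginalDensity} the region was derived from.
#' @param region a region from \code{\link{credibleRegion}}.
#' @param point named numeric matching \code{md$params}.
#' @return logical: density at the point is at or above the region level.
#' @export
regionContains <- function(md, region, point) {
  pt <- as.numeric(point[md$params])
  if (is.null(md$y)) {
    zi <- approx(md$x, md$z, xout = pt[1], rule = 2)$y
    return(zi >= region$level)
  }
  ix <- findInterval(pt[1], md$x)
  iy <- findInterval(pt[2], md$y)
  if (ix < 1 || ix >= length(md$x) || iy < 1 || iy >= length(md$y))
    return(FALSE)
  tx <- (pt[1] - md$x[ix]) / diff(md$x[ix + 0:1])
  ty <- (pt[2] - md$y[iy]) / diff(md$y[iy + 0:1])
  zi <- (1 - tx) * (1 - ty) * md$z[ix, iy] + tx * (1 - ty) * md$z[ix + 1, iy] +
    (1 - tx) * ty * md$z[ix, iy + 1] + tx * ty * md$z[ix + 1, iy + 1]
  zi >= region$level
}
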