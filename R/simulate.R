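# Overdamped Langevin dynamics driver.
#
# Units: lengths nm, energies kT, friction coefficient gamma = 1, so the
# free-bead diffusion coefficient is D = kT and one time unit corresponds
# to a mean-square free-bead displacement of 6 kT nm^2.

#' Initial configuration of all chains
#'
#' Free chains (no geometry) are drawn from the equilibrium ensemble of the
#' discrete worm-like chain: bond lengths at rest, consecutive-bond angles
#' sampled from the Boltzmann density of the bending potential, so static
#' chain statistics are equilibrated from the first step.  Confined chains
#' are grown as soft self-avoiding walks inside the nuclear sphere, each
#' chain starting from its centromeric bead placed within 2 L of the SPB to
#' shorten equilibration.
#'
#' @param chains a \linkS4class{BeadChainSet}.
#' @param geometry a \linkS4class{NucleusGeometry} or NULL (free chains);
#'   defaults to the geometry stored in \code{chains}.
#' @param seed RNG seed (deterministic placement).
#' @param ff force field (bending mapping and rest lengths).
#' @return a \linkS4class{SimulationState}.
#' @export
initConfiguration <- function(chains, geometry = chains@geometry, seed = 1,
                              ff = forceField()) {
  set.seed(seed)
  n <- nBeads(chains)
  diam <- chains@beadDiameter
  pos <- matrix(0, n, 3)
  if (is.null(geometry)) {
    pos <- .initFreeChains(chains, ff)
  } else {
    vol <- sum(pi / 6 * diam^3)
    sphere <- 4 / 3 * pi * geometry@radius^3
    if (vol > 0.6 * sphere)
      stop(sprintf("overcrowded system: bead volume is %.0f%% of the nucleus",
                   100 * vol / sphere))
    pos <- .initConfined(chains, geometry)
  }
  new("SimulationState", positions = pos, step = 0, seed = as.numeric(seed))
}

# equilibrium discrete-WLC sampling for unconfined chains
.initFreeChains <- function(chains, ff) {
  n <- nBeads(chains)
  pos <- matrix(0, n, 3)
  r0 <- .bondRestLengths(chains)
  angK <- .angleConstants(chains, ff)
  bondChain <- chains@beadChain[chains@bonds[, 1]]
  angChain <- if (nrow(chains@angles)) chains@beadChain[chains@angles[, 1]] else integer(0)
  randDir <- function() {
    z <- rnorm(3)
    z / sqrt(sum(z^2))
  }
  for (ci in seq_along(chains@chainNames)) {
    idx <- which(chains@beadChain == ci)
    nb <- length(idx)
    origin <- c((ci - 1) * 20 * max(chains@beadDiameter), 0, 0)
    pos[idx[1], ] <- origin
    if (nb == 1) next
    bIdx <- which(bondChain == ci)
    aIdx <- which(angChain == ci)
    t <- randDir()
    pos[idx[2], ] <- pos[idx[1], ] + r0[bIdx[1]] * t
    if (nb > 2) {
      for (j in 3:nb) {
        k <- angK[aIdx[j - 2]]
        # cos(theta) ~ exp(k cos theta): inverse-CDF, stable for large k
        u <- runif(1)
        ct <- 1 + log(u + (1 - u) * exp(-2 * k)) / k
        ct <- max(min(ct, 1), -1)
        st <- sqrt(1 - ct^2)
        phi <- runif(1, 0, 2 * pi)
        # orthonormal frame around t
        ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        n1 <- ref - sum(ref * t) * t
        n1 <- n1 / sqrt(sum(n1^2))
        n2 <- c(t[2] * n1[3] - t[3] * n1[2], t[3] * n1[1] - t[1] * n1[3],
                t[1] * n1[2] - t[2] * n1[1])
        t <- ct * t + st * (cos(phi) * n1 + sin(phi) * n2)
        t <- t / sqrt(sum(t^2))
        pos[idx[j], ] <- pos[idx[j - 1], ] + r0[bIdx[j - 1]] * t
      }
    }
  }
  pos
}

# soft self-avoiding growth inside the nucleus, centromere-anchored
.initConfined <- function(chains, geometry) {
  n <- nBeads(chains)
  diam <- chains@beadDiameter
  R <- geometry@radius
  spb <- geometry@spbPosition
  pos <- matrix(NA_real_, n, 3)
  cell <- max(min(diam), 1)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  placed <- logical(n)
  keyOf <- function(p) paste(floor(p / cell), collapse = ",")
  addBead <- function(i, p) {
    k <- keyOf(p)
    occ[[k]] <- c(occ[[k]], i)
    pos[i, ] <<- p
    placed[i] <<- TRUE
  }
  overlaps <- function(i, p, tol = 0.7) {
    base <- floor(p / cell)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(base + c(dx, dy, dz), collapse = ",")
      js <- occ[[k]]
      for (j in js) {
        lim <- tol * 0.5 * (diam[i] + diam[j])
        if (sum((p - pos[j, ])^2) < lim^2) return(TRUE)
      }
    }
    # enlarged beads can span several cells: check them directly
    big <- which(placed & diam > 2 * cell)
    for (j in big) {
      lim <- tol * 0.5 * (diam[i] + diam[j])
      if (sum((p - pos[j, ])^2) < lim^2) return(TRUE)
    }
    FALSE
  }
  randDir <- function() {
    z <- rnorm(3)
    z / sqrt(sum(z^2))
  }
  growStep <- function(i, from, step) {
    rmax <- R - 0.5 * diam[i]
    for (try in 1:30) {
      p <- from + step * randDir()
      if (sqrt(sum(p^2)) > rmax) next
      if (try <= 15 && overlaps(i, p)) next
      return(p)
    }
    # fall back: step inward, ignore overlaps
    inward <- -from / max(sqrt(sum(from^2)), 1e-9)
    p <- from + step * inward
    if (sqrt(sum(p^2)) > rmax) p <- p * rmax / sqrt(sum(p^2))
    p
  }
  L <- chains@params@L
  for (ci in seq_along(chains@chainNames)) {
    idx <- which(chains@beadChain == ci)
    cen <- chains@centromereBead[ci]
    # centromeric bead within 2L of the SPB (and inside the sphere)
    repeat {
      p <- spb + 2 * L * runif(1)^(1 / 3) * randDir()
      if (sqrt(sum(p^2)) <= R - 0.5 * diam[cen]) break
    }
    addBead(cen, p)
    for (dir in c(1L, -1L)) {
      ordered <- if (dir == 1L) idx[idx > cen] else rev(idx[idx < cen])
      prev <- cen
      for (i in ordered) {
        step <- 0.5 * (diam[prev] + diam[i])
        addBead(i, growStep(i, pos[prev, ], step))
        prev <- i
      }
    }
  }
  pos
}

# stability bound for the explicit overdamped integrator
.checkDt <- function(dt, ff, gamma = 1) {
  kmax <- max(ff$kBond / (1 - 0.999^2), ff$kExcludedVolume, ff$kWall, ff$kSpb)
  # the FENE divergence is handled by the displacement cap; use the central
  # stiffness for the soft bound
  kmax <- max(ff$kBond, ff$kExcludedVolume, ff$kWall, ff$kSpb)
  if (dt * kmax / gamma >= 2)
    stop(sprintf("dt = %g unstable for stiffness %g kT/nm^2 (need dt < %g)",
                 dt, kmax, 2 * gamma / kmax))
  invisible(TRUE)
}

.cppArgs <- function(chains, ff, geometry) {
  r0 <- .bondRestLengths(chains)
  angK <- .angleConstants(chains, ff)
  free <- is.null(geometry)
  list(bonds = chains@bonds - 1L, bond_r0 = r0, angles = chains@angles - 1L,
       angle_k = angK,
       r_nucleus = if (free) -1 else geometry@radius,
       spb = if (free) c(0, 0, 0) else geometry@spbPosition,
       cent = if (free) integer(0) else chains@centromereBead - 1L,
       telo = if (free) integer(0) else chains@telomereBeads - 1L)
}

#' Run a Langevin dynamics simulation
#'
#' Overdamped (first-order) integration: each step every bead moves by
#' (dt / gamma) times the total force plus an isotropic Gaussian kick of
#' per-axis variance 2 kT dt / gamma, with a per-step displacement cap that
#' tames the stiff core of the finitely extensible bonds.  Positions are
#' sampled every \code{sampleEvery} steps after \code{equilibrationSteps}.
#' A trend test on the sampled radius of gyration and potential energy
#' flags unequilibrated runs with a warning.
#'
#' @param chains a \linkS4class{BeadChainSet}.
#' @param ff a force field from \code{\link{forceField}}.
#' @param nSteps total number of steps (> equilibrationSteps).
#' @param sampleEvery sampling interval in steps.
#' @param equilibrationSteps steps discarded before sampling starts.
#' @param seed RNG seed; identical seeds and configurations give identical
#'   trajectories.
#' @param dt time step, simulation time units.
#' @param kT temperature in kT units (1 = thermal).
#' @param init optional \linkS4class{SimulationState} to start from.
#' @param maxDisplacement per-step displacement cap, nm; default W/10.
#' @param checkEquilibration run the trend diagnostic (warning only).
#' @return a \linkS4class{Trajectory}.
#' @examples
#' g <- reducedGenome()
#' chains <- discretizeGenome(g, parameterPoint(80, 60, 30, 130),
#'                            reducedGeometry())
#' tr <- runSimulation(chains, nSteps = 2000, sampleEvery = 500,
#'                     equilibrationSteps = 0, seed = 1)
#' @export
runSimulation <- function(chains, ff = forceField(), nSteps,
                          sampleEvery = 10000L, equilibrationSteps = 0L,
                          seed = 1, dt = 0.5, kT = 1, init = NULL,
                          maxDisplacement = NULL,
                          checkEquilibration = TRUE) {
  if (nSteps <= equilibrationSteps)
    stop("nSteps must exceed equilibrationSteps")
  .checkDt(dt, ff)
  geometry <- chains@geometry
  if (is.null(init)) init <- initConfiguration(chains, geometry, seed, ff)
  if (is.null(maxDisplacement)) maxDisplacement <- min(chains@beadDiameter) / 10
  a <- .cppArgs(chains, ff, geometry)
  skin <- 1.2 * min(chains@beadDiameter)
  res <- cpp_run_langevin(init@positions, chains@beadDiameter,
                          a$bonds, a$bond_r0, ff$kBond, ff$maxExtension,
                          a$angles, a$angle_k, ff$kExcludedVolume,
                          a$r_nucleus, ff$kWall, a$cent, a$spb,
                          chains@params@L, ff$kSpb, a$telo, ff$fTelomere,
                          ff$telomereShell, dt, kT, 1,
                          as.integer(nSteps), as.integer(sampleEvery),
                          as.integer(equilibrationSteps), maxDisplacement,
                          skin, 2 * min(chains@beadDiameter),
                          as.numeric(seed) * 2654435761 %% 2^31 + 7)
  traj <- new("Trajectory", frames = res$frames, steps = res$steps,
              chains = chains, dt = dt, sampleEvery = as.integer(sampleEvery),
              seed = as.numeric(seed), rg = res$rg, energy = res$energy)
  if (checkEquilibration && length(res$rg) >= 10) {
    d <- equilibrationDiagnostic(traj)
    if (!d$equilibrated)
      warning(sprintf("equilibration trend detected (rg rho = %.2f, p = %.3g)",
                      d$rho, d$p), call. = FALSE)
  }
  traj
}

#' Equilibration diagnostic of a trajectory
#'
#' Spearman trend test of the sampled radius of gyration against sample
#' index; a strong monotone trend indicates the sampling window started
#' before equilibrium.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return list with \code{rho}, \code{p}, \code{equilibrated}.
#' @export
equilibrationDiagnostic <- function(traj) {
  rg <- traj@rg
  ct <- suppressWarnings(cor.test(seq_along(rg), rg, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       equilibrated = !(abs(ct$estimate) > 0.5 && ct$p.value < 0.01))
}

#' Advance a simulation state by a number of Langevin steps
#'
#' Single-step access to the integrator (the update rule of
#' \code{\link{runSimulation}} without sampling machinery).
#'
#' @param state a \linkS4class{SimulationState}.
#' @param chains the \linkS4class{BeadChainSet} the state belongs to.
#' @param ff force field.
#' @param dt time step.
#' @param nSteps number of steps to advance.
#' @param kT temperature (0 disables the random kick).
#' @param seed RNG seed for the kicks.
#' @return the advanced \linkS4class{SimulationState}.
#' @export
langevinStep <- function(state, chains, ff = forceField(), dt = 0.5,
                         nSteps = 1L, kT = 1, seed = state@seed + 1) {
  .checkDt(dt, ff)
  geometry <- chains@geometry
  a <- .cppArgs(chains, ff, geometry)
  res <- cpp_run_langevin(state@positions, chains@beadDiameter,
                          a$bonds, a$bond_r0, ff$kBond, ff$maxExtension,
                          a$angles, a$angle_k, ff$kExcludedVolume,
                          a$r_nucleus, ff$kWall, a$cent, a$spb,
                          chains@params@L, ff$kSpb, a$telo, ff$fTelomere,
                          ff$telomereShell, dt, kT, 1,
                          as.integer(nSteps), as.integer(nSteps), 0L,
                          min(chains@beadDiameter) / 10,
                          0.4 * min(chains@beadDiameter),
                          2 * min(chains@beadDiameter), as.numeric(seed))
  new("SimulationState", positions = t(res$frames[, , 1]),
      step = state@step + nSteps, seed = state@seed)
}

#' Positions of one bead across frames
#' @param traj a \linkS4class{Trajectory}.
#' @param bead global bead index.
#' @return nFrames x 3 matrix, nm.
#' @export
beadPositions <- function(traj, bead) {
  t(traj@frames[, bead, , drop = TRUE])
}

#' Persist / restore a trajectory
#'
#' Native R serialization with full metadata (chains, parameters, seed,
#' sampling settings), sufficient to reproduce the run bit-for-bit with the
#' same backend.
#' @param traj a \linkS4class{Trajectory}.
#' @param path file path (.rds).
#' @export
writeTrajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  traj <- readRDS(path)
  if (!is(traj, "Trajectory")) stop("not a Trajectory file")
  traj
}

#' Export a trajectory as XYZ text (for visualization)
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param frames frame indices to export.
#' @export
exportXYZ <- function(traj, path, frames = seq_len(dim(traj@frames)[3])) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj@frames)[2]
  lab <- traj@chains@chainNames[traj@chains@beadChain]
  for (f in frames) {
    writeLines(c(as.character(n), sprintf("step %d", traj@steps[f])), con)
    xyz <- traj@frames[, , f]
    writeLines(sprintf("%s %.3f %.3f %.3f", lab, xyz[1, ], xyz[2, ], xyz[3, ]),
               con)
  }
  invisible(path)
}
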