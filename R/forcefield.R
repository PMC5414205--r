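# Force-field parameterization.  All energies in kT, lengths in nm.

#' Bending constant from the persistence length
#'
#' Constant k (kT units) of the discrete bending potential
#' U = k (1 - cos theta) applied to consecutive bond pairs.  Two mappings
#' are available:
#' \describe{
#'   \item{\code{"langevin"}}{(default) solves
#'     \eqn{coth(k) - 1/k = exp(-b/P)} so that the discrete-chain tangent
#'     correlation \eqn{<t_i . t_{i+s}> = <cos theta>^s} decays exactly as
#'     \eqn{exp(-s b / P)} at any bead size;}
#'   \item{\code{"continuum"}}{the continuum worm-like-chain limit
#'     k = P / b, accurate only for b << P.}
#' }
#'
#' @param P persistence length, nm (> 0).
#' @param bondLength bond rest length b, nm (> 0).
#' @param mapping "langevin" or "continuum".
#' @return bending constant, kT.
#' @examples
#' bendingConstantFromP(69, 30, mapping = "continuum")  # 2.3
#' bendingConstantFromP(69, 30)                         # discrete-corrected
#' @export
bendingConstantFromP <- function(P, bondLength,
                                 mapping = c("langevin", "continuum")) {
  if (P <= 0 || bondLength <= 0) stop("P and bondLength must be positive")
  mapping <- match.arg(mapping)
  if (mapping == "continuum") return(P / bondLength)
  target <- exp(-bondLength / P)
  lang <- function(k) 1 / tanh(k) - 1 / k
  # Langevin function is monotone on (0, Inf); bracket then solve
  uniroot(function(k) lang(k) - target, lower = 1e-8, upper = 1e8,
          tol = 1e-10)$root
}

#' Construct a simulation force field
#'
#' Potentials (all lengths nm, energies kT):
#' \itemize{
#'   \item bonds: finitely extensible spring symmetric about the rest length
#'     r0 (mean of the two bead diameters), diverging at
#'     |r - r0| = (maxExtension - 1) r0;
#'   \item bending: U = k (1 - cos theta), k from the persistence length via
#'     \code{\link{bendingConstantFromP}} (rDNA stretches use the same P
#'     over their larger bond length);
#'   \item excluded volume: harmonic overlap repulsion below the per-pair
#'     contact distance (mean of the two diameters), between all bead pairs;
#'   \item confinement: harmonic wall on the excess of the bead-center
#'     radius beyond R_N - W/2;
#'   \item SPB tether: harmonic spring of rest length L between each
#'     centromeric bead and the SPB;
#'   \item telomere attraction: constant radial outward force on telomeric
#'     beads, active only within a shell below the envelope.
#' }
#' Jointly the finite bond extensibility and the repulsive core prevent
#' chain crossing at the default energy scales.
#'
#' @param kBond bond stiffness, kT/nm^2.
#' @param maxExtension maximum bond length as a multiple of rest length.
#' @param kExcludedVolume overlap repulsion stiffness, kT/nm^2 (0 = phantom).
#' @param kWall confinement wall stiffness, kT/nm^2.
#' @param kSpb centromere-SPB tether stiffness, kT/nm^2.
#' @param fTelomere outward telomere force, kT/nm.
#' @param telomereShell active-shell thickness below the envelope, nm.
#' @param bendingMapping passed to \code{\link{bendingConstantFromP}}.
#' @return list of class \code{ForceField}.
#' @export
forceField <- function(kBond = 0.5, maxExtension = 1.5, kExcludedVolume = 1,
                       kWall = 1, kSpb = 0.1, fTelomere = 0.2,
                       telomereShell = 100,
                       bendingMapping = c("langevin", "continuum")) {
  stopifnot(kBond > 0, maxExtension > 1, kExcludedVolume >= 0, kWall >= 0,
            kSpb >= 0, fTelomere >= 0, telomereShell >= 0)
  structure(list(kBond = kBond, maxExtension = maxExtension,
                 kExcludedVolume = kExcludedVolume, kWall = kWall,
                 kSpb = kSpb, fTelomere = fTelomere,
                 telomereShell = telomereShell,
                 bendingMapping = match.arg(bendingMapping)),
            class = "ForceField")
}

# Per-angle bending constants for a chain set: bond length taken as the mean
# of the two adjacent bond rest lengths (relevant along the rDNA stretch).
.angleConstants <- function(chains, ff) {
  ang <- chains@angles
  if (nrow(ang) == 0) return(numeric(0))
  d <- chains@beadDiameter
  b1 <- (d[ang[, 1]] + d[ang[, 2]]) / 2
  b2 <- (d[ang[, 2]] + d[ang[, 3]]) / 2
  b <- (b1 + b2) / 2
  P <- chains@params@P
  vapply(unique(b), function(bb) bendingConstantFromP(P, bb, ff$bendingMapping),
         0)[match(b, unique(b))]
}

.bondRestLengths <- function(chains) {
  bd <- chains@bonds
  if (nrow(bd) == 0) return(numeric(0))
  (chains@beadDiameter[bd[, 1]] + chains@beadDiameter[bd[, 2]]) / 2
}
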