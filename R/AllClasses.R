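# S4 classes for the simulation / inference pipeline.

#' GenomeSpec: per-chromosome genomic lengths, centromeres and rDNA interval
#'
#' Holds the genome table used to discretize chromosomes into bead chains:
#' one row per chromosome with its genomic length and centromere position
#' (1-based bp), plus an optional rDNA interval assigned to one chromosome.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{length_bp},
#'   \code{centromere_bp}.
#' @slot rdna data.frame with zero or one row and columns \code{name},
#'   \code{start_bp}, \code{end_bp} (1-based inclusive).
#' @export
setClass("GenomeSpec",
  representation(chromosomes = "data.frame", rdna = "data.frame"))

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  msg <- character()
  need <- c("name", "length_bp", "centromere_bp")
  if (!all(need %in% names(ch))) return("chromosomes must have name, length_bp, centromere_bp")
  if (any(ch$length_bp <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  if (any(ch$centromere_bp <= 0 | ch$centromere_bp >= ch$length_bp))
    msg <- c(msg, "centromeres must lie strictly inside their chromosome")
  if (anyDuplicated(ch$name)) msg <- c(msg, "duplicate chromosome names")
  rd <- object@rdna
  if (nrow(rd) > 1) msg <- c(msg, "at most one rDNA interval")
  if (nrow(rd) == 1) {
    if (!rd$name %in% ch$name) msg <- c(msg, "rDNA chromosome not in genome")
    else {
      len <- ch$length_bp[match(rd$name, ch$name)]
      if (rd$start_bp < 1 || rd$end_bp > len || rd$start_bp >= rd$end_bp)
        msg <- c(msg, "rDNA interval must lie within its chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ParameterPoint: the structural parameter vector (P, C, W, L)
#'
#' @slot P persistence length, nm.
#' @slot C compaction, bp per nm of fiber contour.
#' @slot W fiber width (bead diameter), nm.
#' @slot L microtubule rest length (centromere-SPB tether), nm.
#' @export
setClass("ParameterPoint",
  representation(P = "numeric", C = "numeric", W = "numeric", L = "numeric"),
  prototype(P = 1, C = 1, W = 1, L = 1))

setValidity("ParameterPoint", function(object) {
  v <- c(P = object@P, C = object@C, W = object@W, L = object@L)
  if (length(v) != 4 || any(!is.finite(v))) return("P, C, W, L must be finite scalars")
  if (any(v <= 0)) return("P, C, W, L must be positive")
  TRUE
})

#' NucleusGeometry: nuclear sphere, SPB anchor and rDNA bead sizing
#'
#' @slot radius nuclear radius R_N, nm.
#' @slot rdnaDiameter rDNA bead diameter W_rDNA, nm.
#' @slot nRdnaBeads number of rDNA beads replacing the rDNA interval.
#' @slot spbPosition 3-vector on the nuclear envelope where the spindle pole
#'   body sits, nm.
#' @export
setClass("NucleusGeometry",
  representation(radius = "numeric", rdnaDiameter = "numeric",
                 nRdnaBeads = "integer", spbPosition = "numeric"))

setValidity("NucleusGeometry", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@rdnaDiameter <= 0) msg <- c(msg, "rdnaDiameter must be > 0")
  if (object@nRdnaBeads < 0L) msg <- c(msg, "nRdnaBeads must be >= 0")
  if (length(object@spbPosition) != 3) msg <- c(msg, "spbPosition must be a 3-vector")
  else if (abs(sqrt(sum(object@spbPosition^2)) - object@radius) > 1e-6 * object@radius)
    msg <- c(msg, "spbPosition must lie on the nuclear sphere")
  if (length(msg)) msg else TRUE
})

#' BeadChainSet: discretized bead chains for a whole genome
#'
#' Flattened representation of all chromosomes as bead chains: per-bead
#' chain membership, diameters and genomic tiles, plus centromere, telomere
#' and rDNA annotations and the bond/angle topology used by the simulator.
#'
#' @slot genome the \linkS4class{GenomeSpec} the chains were built from.
#' @slot params the \linkS4class{ParameterPoint} (sets bp per bead = C*W).
#' @slot geometry \linkS4class{NucleusGeometry} or NULL for free chains.
#' @slot chainNames chromosome name per chain.
#' @slot beadChain integer chain index per bead.
#' @slot beadDiameter per-bead diameter, nm.
#' @slot beadStartBp,beadEndBp 0-based half-open genomic tile per bead
#'   (rDNA beads share the rDNA interval).
#' @slot centromereBead global bead index of each chain's centromere.
#' @slot telomereBeads global bead indices of all chain ends.
#' @slot rdnaBeads global bead indices of the rDNA beads (may be empty).
#' @slot bonds two-column matrix of bonded bead pairs (1-based).
#' @slot angles three-column matrix of consecutive bead triplets.
#' @export
setClass("BeadChainSet",
  representation(genome = "GenomeSpec", params = "ParameterPoint",
                 geometry = "ANY", chainNames = "character",
                 beadChain = "integer", beadDiameter = "numeric",
                 beadStartBp = "numeric", beadEndBp = "numeric",
                 centromereBead = "integer", telomereBeads = "integer",
                 rdnaBeads = "integer", bonds = "matrix", angles = "matrix"))

#' SimulationState: bead positions at one instant
#'
#' @slot positions n x 3 matrix of bead coordinates, nm.
#' @slot step step counter.
#' @slot seed RNG seed the state was generated from.
#' @export
setClass("SimulationState",
  representation(positions = "matrix", step = "numeric", seed = "numeric"))

#' Trajectory: time-sampled bead coordinates
#'
#' @slot frames numeric array with dim (3, nBeads, nFrames), nm.
#' @slot steps step index of each sample.
#' @slot chains the \linkS4class{BeadChainSet} simulated.
#' @slot dt integration time step (simulation time units).
#' @slot sampleEvery steps between samples.
#' @slot seed RNG seed.
#' @slot rg radius of gyration per sample (equilibration diagnostic).
#' @slot energy potential energy per sample, kT.
#' @export
setClass("Trajectory",
  representation(frames = "array", steps = "integer", chains = "BeadChainSet",
                 dt = "numeric", sampleEvery = "integer", seed = "numeric",
                 rg = "numeric", energy = "numeric"))

#' ObservableSet: named summary statistics computed from a trajectory
#'
#' @slot values named numeric vector of observable values.
#' @slot stderr per-value sampling standard error.
#' @slot schema the observable schema data.frame the values follow.
#' @export
setClass("ObservableSet",
  representation(values = "numeric", stderr = "numeric", schema = "data.frame"))

#' ContactMap: symmetric binned contact-frequency matrix
#'
#' @slot matrix symmetric matrix of contact frequencies in [0, 1].
#' @slot binSize genomic bin size, bp.
#' @slot bins data.frame with columns \code{chrom}, \code{start_bp} per bin.
#' @export
setClass("ContactMap",
  representation(matrix = "matrix", binSize = "numeric", bins = "data.frame"))

#' ModelGrid: simulated parameter points with observable predictions
#'
#' @slot points data.frame with columns P, C, W, L (one row per point) and
#'   a \code{status} column.
#' @slot observables nPoints x nObservables matrix of replica-averaged values.
#' @slot stderr matching matrix of between-replica standard errors.
#' @slot replicates list (per point) of nReplica x nObservables matrices.
#' @slot schema observable schema shared by all points.
#' @slot config list: genome, geometry, simulation settings, seeds.
#' @export
setClass("ModelGrid",
  representation(points = "data.frame", observables = "matrix",
                 stderr = "matrix", replicates = "list",
                 schema = "data.frame", config = "list"))

#' PosteriorSample: ensemble MCMC draws over (structural, nuisance) space
#'
#' @slot draws nDraws x nParams matrix (named columns), all walkers stacked
#'   after burn-in.
#' @slot logProb log-posterior per draw.
#' @slot meta list: walkers, steps, burn-in, thinning, acceptance, seed,
#'   parameter box.
#' @export
setClass("PosteriorSample",
  representation(draws = "matrix", logProb = "numeric", meta = "list"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d chromosomes, %.1f Mb total%s\n",
              nrow(object@chromosomes), sum(object@chromosomes$length_bp) / 1e6,
              if (nrow(object@rdna)) sprintf(", rDNA on %s", object@rdna$name) else ""))
})

setMethod("show", "ParameterPoint", function(object) {
  cat(sprintf("ParameterPoint: P = %g nm, C = %g bp/nm, W = %g nm, L = %g nm\n",
              object@P, object@C, object@W, object@L))
})

setMethod("show", "NucleusGeometry", function(object) {
  cat(sprintf("NucleusGeometry: R_N = %g nm, %d rDNA beads of %.1f nm\n",
              object@radius, object@nRdnaBeads, object@rdnaDiameter))
})

setMethod("show", "BeadChainSet", function(object) {
  cat(sprintf("BeadChainSet: %d chains, %d beads (%.0f bp/bead), %d rDNA beads\n",
              length(object@chainNames), length(object@beadChain),
              bpPerBead(object), length(object@rdnaBeads)))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Trajectory: %d beads, %d frames (every %d steps, dt = %g)\n",
              d[2], d[3], object@sampleEvery, object@dt))
})

setMethod("show", "ObservableSet", function(object) {
  cat(sprintf("ObservableSet: %d observables (%s)\n", length(object@values),
              paste(unique(object@schema$dataset), collapse = ", ")))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d bins of %g Kb\n", nrow(object@matrix),
              object@binSize / 1000))
})

setMethod("show", "ModelGrid", function(object) {
  ax <- gridAxes(object)
  cat(sprintf("ModelGrid: %d points (%s), %d observables, %d replicas/point\n",
              nrow(object@points),
              paste(sprintf("%s:%d", names(ax), lengths(ax)), collapse = " "),
              ncol(object@observables),
              if (length(object@replicates)) nrow(object@replicates[[1]]) else 0L))
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf("PosteriorSample: %d draws over (%s), acceptance %.2f\n",
              nrow(object@draws), paste(colnames(object@draws), collapse = ", "),
              object@meta$acceptance))
})

# ---- constructors / accessors ---------------------------------------------

#' Construct a structural parameter point
#'
#' @param P persistence length, nm.
#' @param C compaction, bp/nm.
#' @param W fiber width, nm.
#' @param L microtubule rest length, nm.
#' @return a \linkS4class{ParameterPoint}.
#' @examples
#' parameterPoint(69, 50, 30, 400)
#' @export
parameterPoint <- function(P, C, W, L) {
  # note: the C slot is assigned directly because a named `C` argument to
  # new() would partially match its `Class` parameter
  x <- new("ParameterPoint", P = as.numeric(P), W = as.numeric(W),
           L = as.numeric(L))
  x@C <- as.numeric(C)
  validObject(x)
  x
}

#' @rdname parameterPoint
#' @param x a ParameterPoint.
#' @export
persistenceLength <- function(x) x@P

#' @rdname parameterPoint
#' @export
compaction <- function(x) x@C

#' @rdname parameterPoint
#' @export
fiberWidth <- function(x) x@W

#' @rdname parameterPoint
#' @export
microtubuleLength <- function(x) x@L

#' Prior box for the structural parameters
#'
#' The flat-prior support used for inference: P in [27, 252] nm, C in
#' [25, 110] bp/nm, W in [30, 60] nm, L in [200, 400] nm.
#'
#' @return data.frame with columns \code{param}, \code{min}, \code{max}.
#' @export
structuralPriorBox <- function() {
  data.frame(param = c("P", "C", "W", "L"),
             min = c(27, 25, 30, 200),
             max = c(252, 110, 60, 400))
}

#' Check a parameter point against the structural prior box
#' @param x a \linkS4class{ParameterPoint}.
#' @param box prior box as from \code{structuralPriorBox()}.
#' @return logical.
#' @export
inPriorBox <- function(x, box = structuralPriorBox()) {
  v <- c(P = x@P, C = x@C, W = x@W, L = x@L)[box$param]
  all(v >= box$min & v <= box$max)
}

#' Construct a nuclear geometry
#'
#' @param radius nuclear radius, nm.
#' @param rdnaDiameter rDNA bead diameter, nm; defaults to the diameter at
#'   which \code{nRdnaBeads} beads occupy \code{rdnaVolumeFraction} of the
#'   nuclear volume.
#' @param nRdnaBeads number of rDNA beads.
#' @param rdnaVolumeFraction net nucleolar volume fraction V used when
#'   \code{rdnaDiameter} is not given.
#' @param spbPosition SPB anchor on the envelope; default (0, 0, -radius).
#' @return a \linkS4class{NucleusGeometry}.
#' @examples
#' nucleusGeometry()  # yeast defaults: R_N = 1000 nm, 150 rDNA beads, V = 14%
#' @export
nucleusGeometry <- function(radius = 1000, rdnaDiameter = NULL,
                            nRdnaBeads = 150L, rdnaVolumeFraction = 0.14,
                            spbPosition = c(0, 0, -radius)) {
  if (is.null(rdnaDiameter))
    rdnaDiameter <- rdnaDiameterFromVolumeFraction(rdnaVolumeFraction, radius,
                                                   nRdnaBeads)
  new("NucleusGeometry", radius = as.numeric(radius),
      rdnaDiameter = as.numeric(rdnaDiameter),
      nRdnaBeads = as.integer(nRdnaBeads),
      spbPosition = as.numeric(spbPosition))
}

#' @rdname nucleusGeometry
#' @param x a NucleusGeometry.
#' @export
nuclearRadius <- function(x) x@radius

#' Base pairs per bead of a chain set
#' @param x a \linkS4class{BeadChainSet}.
#' @return C * W in bp.
#' @export
bpPerBead <- function(x) x@params@C * x@params@W

#' Number of beads in a chain set
#' @param x a \linkS4class{BeadChainSet}.
#' @export
nBeads <- function(x) length(x@beadChain)

#' Observable values of an ObservableSet
#' @param x an \linkS4class{ObservableSet}.
#' @export
observableValues <- function(x) x@values

#' Posterior draws, optionally burned-in and thinned
#' @param x a \linkS4class{PosteriorSample}.
#' @param burnIn fraction of each walker's chain to drop (default: as run).
#' @export
posteriorDraws <- function(x, burnIn = NULL) {
  if (is.null(burnIn)) return(x@draws)
  nw <- x@meta$walkers
  ns <- nrow(x@draws) / nw
  keep <- rep(seq_len(ns) > burnIn * ns, each = nw)
  x@draws[keep, , drop = FALSE]
}

#' Axes of a model grid (sorted unique values per varying parameter)
#' @param grid a \linkS4class{ModelGrid}.
#' @export
gridAxes <- function(grid) {
  ax <- lapply(c("P", "C", "W", "L"), function(p) sort(unique(grid@points[[p]])))
  names(ax) <- c("P", "C", "W", "L")
  ax[lengths(ax) > 1]
}
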