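# Discretization of chromosomes into bead chains.
#
# Genomic coordinates are 1-based inclusive in all input tables and are
# converted to 0-based half-open internally.  Bead counts use a ceiling so
# no sequence is dropped; the terminal partial bead keeps full diameter W.

#' rDNA bead diameter from a target nucleolar volume fraction
#'
#' Diameter d such that \code{nBeads} spheres of diameter d have a net
#' volume equal to fraction \code{V} of the nuclear sphere:
#' d = 2 R_N (V / nBeads)^(1/3).  With the yeast defaults (V = 14\%,
#' R_N = 1000 nm, 150 beads) this gives approximately 195 nm.
#'
#' @param V net volume fraction in (0, 1).
#' @param radius nuclear radius, nm.
#' @param nBeads number of rDNA beads.
#' @return bead diameter, nm.
#' @examples
#' rdnaDiameterFromVolumeFraction(0.14, 1000, 150)
#' @export
rdnaDiameterFromVolumeFraction <- function(V, radius = 1000, nBeads = 150L) {
  if (!is.finite(V) || V <= 0 || V >= 1) stop("V must lie in (0, 1)")
  if (radius <= 0 || nBeads < 1) stop("radius and nBeads must be positive")
  2 * radius * (V / nBeads)^(1 / 3)
}

# Single-chromosome tiling.  Returns per-bead diameters and tiles in
# non-rDNA ("nr") coordinates together with annotation indices.
.discretizeOne <- function(lengthBp, params, rdna0 = NULL, centromereBp = NULL,
                           geometry = NULL) {
  if (lengthBp <= 0) stop("chromosome length must be positive")
  bpb <- params@C * params@W
  W <- params@W
  if (is.null(rdna0)) {
    nt <- ceiling(lengthBp / bpb)
    nrdna <- 0L
    p <- nt
    rdlen <- 0
    rdstart <- NA_real_
  } else {
    rdstart <- rdna0[1]
    rdlen <- rdna0[2] - rdna0[1]
    if (rdstart < 0 || rdna0[2] > lengthBp || rdlen <= 0)
      stop("rDNA interval outside chromosome")
    if (is.null(geometry)) stop("rDNA chain requires a NucleusGeometry")
    nrdna <- geometry@nRdnaBeads
    nt <- ceiling((lengthBp - rdlen) / bpb)
    p <- min(ceiling(rdstart / bpb), nt)
  }
  nb <- nt + nrdna
  diam <- rep(W, nb)
  isRdna <- rep(FALSE, nb)
  if (nrdna > 0) {
    idx <- p + seq_len(nrdna)
    diam[idx] <- geometry@rdnaDiameter
    isRdna[idx] <- TRUE
  }
  # genomic tile per bead (approximate across the rDNA junction)
  shift <- function(x, strict) {
    if (is.null(rdna0)) return(x)
    ifelse(if (strict) x > rdstart else x >= rdstart, x + rdlen, x)
  }
  tileIdx <- integer(nb)
  tileIdx[!isRdna] <- seq_len(nt)
  startBp <- endBp <- numeric(nb)
  nrlen <- lengthBp - rdlen
  startBp[!isRdna] <- shift(pmin((tileIdx[!isRdna] - 1) * bpb, nrlen), FALSE)
  endBp[!isRdna] <- shift(pmin(tileIdx[!isRdna] * bpb, nrlen), TRUE)
  if (nrdna > 0) {
    sub <- rdstart + (seq_len(nrdna) - 1) * rdlen / nrdna
    startBp[isRdna] <- sub
    endBp[isRdna] <- sub + rdlen / nrdna
  }
  cenBead <- NA_integer_
  if (!is.null(centromereBp)) {
    cen0 <- centromereBp - 1
    cenBead <- .bpToBead(cen0, bpb, nt, p, nrdna, rdstart, rdlen)
  }
  list(n = nb, diam = diam, isRdna = isRdna, startBp = startBp, endBp = endBp,
       cenBead = cenBead, nt = nt, p = p, nrdna = nrdna,
       rdstart = rdstart, rdlen = rdlen, bpb = bpb, lengthBp = lengthBp)
}

# 0-based position -> 1-based bead index within one chain
.bpToBead <- function(pos0, bpb, nt, p, nrdna, rdstart, rdlen) {
  if (nrdna > 0 && pos0 >= rdstart && pos0 < rdstart + rdlen) {
    return(p + 1L + min(floor((pos0 - rdstart) / (rdlen / nrdna)), nrdna - 1L))
  }
  nrpos <- if (nrdna > 0 && pos0 >= rdstart + rdlen) pos0 - rdlen else pos0
  t <- min(floor(nrpos / bpb), nt - 1) + 1L
  as.integer(if (t > p) t + nrdna else t)
}

#' Discretize one chromosome into a bead chain
#'
#' Beads tile the chromosome at C*W bp per bead (ceiling: the terminal
#' partial bead keeps full diameter).  If an rDNA interval is given, it is
#' excised and replaced by exactly \code{geometry@nRdnaBeads} beads of
#' diameter \code{geometry@rdnaDiameter}, inserted at the interval position.
#'
#' @param lengthBp chromosome length, bp (> 0).
#' @param params a \linkS4class{ParameterPoint}.
#' @param rdnaInterval optional c(start_bp, end_bp), 1-based inclusive.
#' @param centromereBp optional centromere position, 1-based bp.
#' @param geometry \linkS4class{NucleusGeometry}; required with rDNA.
#' @return list with bead count \code{n}, per-bead \code{diam},
#'   \code{isRdna}, genomic tiles, and the centromere bead index.
#' @examples
#' pp <- parameterPoint(69, 50, 30, 400)
#' discretizeChromosome(230218, pp)$n  # ceil(230218 / 1500)
#' @export
discretizeChromosome <- function(lengthBp, params, rdnaInterval = NULL,
                                 centromereBp = NULL, geometry = NULL) {
  rdna0 <- if (!is.null(rdnaInterval))
    c(rdnaInterval[1] - 1, rdnaInterval[2]) else NULL
  .discretizeOne(lengthBp, params, rdna0, centromereBp, geometry)
}

#' Discretize a whole genome into a bead chain set
#'
#' @param genome a \linkS4class{GenomeSpec}.
#' @param params a \linkS4class{ParameterPoint}.
#' @param geometry a \linkS4class{NucleusGeometry}, or NULL for free
#'   (unconfined, untethered) chains.
#' @return a \linkS4class{BeadChainSet} with bond and angle topology.
#' @examples
#' chains <- discretizeGenome(yeastGenome(), parameterPoint(69, 50, 30, 400),
#'                            nucleusGeometry())
#' nBeads(chains)
#' @export
discretizeGenome <- function(genome, params, geometry = NULL) {
  validObject(params)
  ch <- genome@chromosomes
  rd <- genome@rdna
  chains <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    rdna0 <- NULL
    if (nrow(rd) == 1 && rd$name == ch$name[i])
      rdna0 <- c(rd$start_bp - 1, rd$end_bp)
    chains[[i]] <- .discretizeOne(ch$length_bp[i], params, rdna0,
                                  ch$centromere_bp[i], geometry)
  }
  ns <- vapply(chains, `[[`, 0, "n")
  off <- cumsum(c(0, ns[-length(ns)]))
  beadChain <- rep(seq_along(chains), ns)
  diam <- unlist(lapply(chains, `[[`, "diam"))
  startBp <- unlist(lapply(chains, `[[`, "startBp"))
  endBp <- unlist(lapply(chains, `[[`, "endBp"))
  cen <- as.integer(vapply(chains, `[[`, 0L, "cenBead") + off)
  telo <- as.integer(c(off + 1, off + ns))
  rdnaBeads <- integer(0)
  for (i in seq_along(chains)) {
    if (chains[[i]]$nrdna > 0)
      rdnaBeads <- c(rdnaBeads, off[i] + chains[[i]]$p + seq_len(chains[[i]]$nrdna))
  }
  bonds <- do.call(rbind, lapply(seq_along(chains), function(i) {
    n <- ns[i]
    if (n < 2) return(matrix(integer(), 0, 2))
    cbind(off[i] + seq_len(n - 1), off[i] + seq_len(n - 1) + 1)
  }))
  angles <- do.call(rbind, lapply(seq_along(chains), function(i) {
    n <- ns[i]
    if (n < 3) return(matrix(integer(), 0, 3))
    cbind(off[i] + seq_len(n - 2), off[i] + seq_len(n - 2) + 1,
          off[i] + seq_len(n - 2) + 2)
  }))
  storage.mode(bonds) <- "integer"
  storage.mode(angles) <- "integer"
  new("BeadChainSet", genome = genome, params = params,
      geometry = if (is.null(geometry)) NULL else geometry,
      chainNames = ch$name, beadChain = as.integer(beadChain),
      beadDiameter = diam, beadStartBp = startBp, beadEndBp = endBp,
      centromereBead = cen, telomereBeads = telo,
      rdnaBeads = as.integer(rdnaBeads), bonds = bonds, angles = angles)
}

#' Map a genomic locus to its bead
#'
#' Nearest-bead mapping under the C*W bp/bead tiling (the bead whose tile
#' contains the position).  Deterministic.
#'
#' @param chains a \linkS4class{BeadChainSet}.
#' @param chrom chromosome name.
#' @param positionBp 1-based position in bp.
#' @return list with \code{chain} (name), \code{bead} (1-based index within
#'   the chain) and \code{globalBead} (index into the chain set).
#' @examples
#' chains <- discretizeGenome(yeastGenome(), parameterPoint(69, 50, 30, 400),
#'                            nucleusGeometry())
#' locusToBead(chains, "chr1", 150000)$bead  # tile floor(149999/1500) + 1
#' @export
locusToBead <- function(chains, chrom, positionBp) {
  ci <- match(chrom, chains@chainNames)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  len <- chains@genome@chromosomes$length_bp[ci]
  if (positionBp < 1 || positionBp > len)
    stop(sprintf("position %d outside %s (1-%d)", as.integer(positionBp),
                 chrom, as.integer(len)))
  info <- .chainInfo(chains, ci)
  bead <- .bpToBead(positionBp - 1, info$bpb, info$nt, info$p, info$nrdna,
                    info$rdstart, info$rdlen)
  off <- sum(tabulate(chains@beadChain, length(chains@chainNames))[seq_len(ci - 1)])
  list(chain = chrom, bead = bead, globalBead = as.integer(off + bead))
}

# recover per-chain tiling parameters from a chain set
.chainInfo <- function(chains, ci) {
  sel <- chains@beadChain == ci
  n <- sum(sel)
  isRd <- seq_len(length(chains@beadChain))[sel] %in% chains@rdnaBeads
  nrdna <- sum(isRd)
  p <- if (nrdna > 0) which(isRd)[1] - 1L else n
  rd <- chains@genome@rdna
  list(bpb = bpPerBead(chains), nt = n - nrdna, p = p, nrdna = nrdna,
       rdstart = if (nrdna > 0) rd$start_bp - 1 else NA_real_,
       rdlen = if (nrdna > 0) rd$end_bp - rd$start_bp + 1 else 0)
}

#' Per-chromosome chain summary
#'
#' @param chains a \linkS4class{BeadChainSet}.
#' @return data.frame: name, bead count, centromere/telomere bead indices
#'   (within chain), rDNA bead range.
#' @export
chainTable <- function(chains) {
  ns <- tabulate(chains@beadChain, length(chains@chainNames))
  off <- cumsum(c(0, ns[-length(ns)]))
  rdFirst <- rdLast <- rep(NA_integer_, length(ns))
  if (length(chains@rdnaBeads)) {
    ci <- chains@beadChain[chains@rdnaBeads[1]]
    rdFirst[ci] <- min(chains@rdnaBeads) - off[ci]
    rdLast[ci] <- max(chains@rdnaBeads) - off[ci]
  }
  data.frame(name = chains@chainNames, beads = ns,
             centromere_bead = chains@centromereBead - off,
             telomere_left = 1L, telomere_right = ns,
             rdna_first = rdFirst, rdna_last = rdLast)
}

#' Export chain annotations as genomic ranges
#'
#' BED-like intervals for centromere, telomere and rDNA beads, as a
#' \code{GRanges} (0-based tile boundaries become 1-based ranges).
#'
#' @param chains a \linkS4class{BeadChainSet}.
#' @param teloBp extent reported for telomeric beads, bp.
#' @return a \code{GenomicRanges::GRanges} with a \code{role} column.
#' @export
chainAnnotations <- function(chains, teloBp = NULL) {
  idx <- c(chains@centromereBead, chains@telomereBeads, chains@rdnaBeads)
  role <- c(rep("centromere", length(chains@centromereBead)),
            rep("telomere", length(chains@telomereBeads)),
            rep("rdna", length(chains@rdnaBeads)))
  keep <- !is.na(idx)
  idx <- idx[keep]; role <- role[keep]
  GenomicRanges::GRanges(
    seqnames = chains@chainNames[chains@beadChain[idx]],
    ranges = IRanges::IRanges(start = floor(chains@beadStartBp[idx]) + 1,
                              end = pmax(floor(chains@beadEndBp[idx]),
                                         floor(chains@beadStartBp[idx]) + 1)),
    role = role)
}

#' Write chain annotations as BED-like text
#' @param chains a \linkS4class{BeadChainSet}.
#' @param path output file.
#' @export
writeChainAnnotations <- function(chains, path) {
  gr <- chainAnnotations(chains)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   role = gr$role)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
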