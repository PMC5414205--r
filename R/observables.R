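# Summary observables computed from trajectories: distance statistics,
# angles to the nucleolar axis, contact frequencies and MSD.

OBS_CLASSES <- c("median_3d_distance", "median_2d_distance",
                 "mean_3d_distance", "mode_3d_distance", "median_angle",
                 "contact_summary_intra", "contact_summary_inter",
                 "contact_vs_s_genomewide", "contact_vs_s_centromeric")

#' Build the default observable schema for a genome
#'
#' Emits the nine-dataset schema used for inference: O1 median 3D distances
#' between subtelomeric locus pairs (live imaging), O2 median angles between
#' loci and the nuclear-nucleolar axis, O3 median distances between loci on
#' the rDNA chromosome and the nucleolar centroid, O4 median 2D distances
#' between pairs on the longest chromosome, O5 mean 3D intrachromosomal
#' distances, O6 modes of 3D intrachromosomal distances, O7 modes of
#' SPB-telomere distances, O8/O9 Hi-C summaries (per-chromosome intra and
#' inter contact frequencies plus intrachromosomal contact frequency at
#' genomic separations 25-85 Kb in 5 Kb bins, genome-wide and
#' centromere-anchored).  For the 16-chromosome yeast genome the default
#' counts give 62/37/15/12/13/8/7/56/56 = 266 observables.
#'
#' Locus placement is deterministic (no RNG): subtelomeric loci at fixed
#' offsets from chromosome ends, other loci evenly spaced.
#'
#' @param genome a \linkS4class{GenomeSpec} (rDNA interval required for
#'   O2/O3).
#' @param counts named integer vector of per-dataset sizes for O1-O7.
#' @param hicBins genomic-separation bin centers for O8/O9, bp: the 12
#'   5-Kb bins tiling 25-85 Kb.
#' @return data.frame with columns id, dataset, class, chrom_a, pos_a,
#'   chrom_b, pos_b, sep_bp, group.
#' @examples
#' nrow(buildObservableSchema(yeastGenome()))  # 266
#' @export
buildObservableSchema <- function(genome,
                                  counts = c(O1 = 62, O2 = 37, O3 = 15,
                                             O4 = 12, O5 = 13, O6 = 8, O7 = 7),
                                  hicBins = seq(25000, 80000, by = 5000)) {
  ch <- genome@chromosomes
  if (nrow(genome@rdna) == 0) stop("schema requires an rDNA interval (O2/O3)")
  rdChrom <- genome@rdna$name
  longest <- ch$name[which.max(ch$length_bp)]
  rows <- list()
  addRow <- function(dataset, class, ca, pa, cb = NA, pb = NA, sep = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      dataset = dataset, class = class, chrom_a = ca, pos_a = pa,
      chrom_b = cb, pos_b = pb, sep_bp = sep)
  }

  # O1: subtelomeric locus pairs.  Pool: per chromosome end, loci at fixed
  # offsets; depth grows until enough cross-end pairs exist.
  minLen <- min(ch$length_bp)
  for (depth in 1:8) {
    offs <- seq_len(depth) * min(5000, floor(minLen / (2 * (depth + 1))))
    pool <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
      rbind(data.frame(chrom = ch$name[i], pos = offs, end = "L"),
            data.frame(chrom = ch$name[i], pos = ch$length_bp[i] - offs + 1,
                       end = "R"))
    }))
    pool$endId <- paste(pool$chrom, pool$end)
    prs <- combn(nrow(pool), 2)
    keep <- pool$endId[prs[1, ]] != pool$endId[prs[2, ]]
    prs <- prs[, keep, drop = FALSE]
    if (ncol(prs) >= counts["O1"]) break
  }
  sel <- round(seq(1, ncol(prs), length.out = counts["O1"]))
  for (k in sel)
    addRow("O1", "median_3d_distance", pool$chrom[prs[1, k]],
           pool$pos[prs[1, k]], pool$chrom[prs[2, k]], pool$pos[prs[2, k]])

  # O2: angles for loci spread evenly along the concatenated genome
  tot <- sum(ch$length_bp)
  bnd <- cumsum(c(0, ch$length_bp))
  for (k in seq_len(counts["O2"])) {
    g <- (k - 0.5) / counts["O2"] * tot
    ci <- findInterval(g, bnd, rightmost.closed = TRUE)
    ci <- min(ci, nrow(ch))
    addRow("O2", "median_angle", ch$name[ci],
           max(1, min(round(g - bnd[ci]), ch$length_bp[ci])))
  }

  # O3: loci on the rDNA chromosome (outside the interval) vs nucleolus
  rdLen <- ch$length_bp[match(rdChrom, ch$name)]
  rd <- genome@rdna
  nrLen <- rdLen - (rd$end_bp - rd$start_bp + 1)
  for (k in seq_len(counts["O3"])) {
    p <- round((k - 0.5) / counts["O3"] * nrLen)
    if (p >= rd$start_bp) p <- p + (rd$end_bp - rd$start_bp + 1)
    addRow("O3", "median_3d_distance", rdChrom, max(1, min(p, rdLen)),
           "NUCLEOLUS", NA)
  }

  # O4: 2D distances on the longest chromosome's right arm: one
  # pericentromeric and two internal anchors paired with loci along the arm
  li <- match(longest, ch$name)
  cen <- ch$centromere_bp[li]
  armLen <- ch$length_bp[li] - cen
  anchors <- c(cen + 5000, cen + round(0.55 * armLen), cen + round(0.8 * armLen))
  nPer <- diff(round(seq(0, counts["O4"], length.out = 4)))
  for (a in seq_along(anchors)) {
    for (k in seq_len(nPer[a])) {
      sep <- round(k / (nPer[a] + 1) * 0.5 * armLen)
      pb <- min(anchors[a] + sep, ch$length_bp[li] - 1000)
      addRow("O4", "median_2d_distance", longest, anchors[a], longest, pb)
    }
  }

  # O5: mean 3D intrachromosomal distances on the three longest chromosomes
  ord <- order(ch$length_bp, decreasing = TRUE)
  useCh <- ch$name[ord[seq_len(min(3, nrow(ch)))]]
  nPer <- diff(round(seq(0, counts["O5"], length.out = length(useCh) + 1)))
  for (a in seq_along(useCh)) {
    len <- ch$length_bp[match(useCh[a], ch$name)]
    for (k in seq_len(nPer[a])) {
      sep <- round(k / (nPer[a] + 1) * 0.6 * len)
      addRow("O5", "mean_3d_distance", useCh[a], round(0.15 * len),
             useCh[a], min(round(0.15 * len) + sep, len - 1000))
    }
  }

  # O6: distance modes on a mid-length chromosome
  modeCh <- if ("chr14" %in% ch$name) "chr14" else
    ch$name[ord[ceiling(length(ord) / 2)]]
  len <- ch$length_bp[match(modeCh, ch$name)]
  for (k in seq_len(counts["O6"])) {
    sep <- round(k / (counts["O6"] + 1) * 0.7 * len)
    addRow("O6", "mode_3d_distance", modeCh, round(0.1 * len),
           modeCh, min(round(0.1 * len) + sep, len - 1000))
  }

  # O7: SPB-telomere distance modes
  tel <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i)
    data.frame(chrom = ch$name[i], pos = c(2500, ch$length_bp[i] - 2500))))
  sel <- round(seq(1, nrow(tel), length.out = counts["O7"]))
  for (k in sel)
    addRow("O7", "mode_3d_distance", tel$chrom[k], tel$pos[k], "SPB", NA)

  # O8/O9: Hi-C summaries
  for (ds in c("O8", "O9")) {
    for (nm in ch$name) addRow(ds, "contact_summary_intra", nm, NA)
    for (nm in ch$name) addRow(ds, "contact_summary_inter", nm, NA)
    for (s in hicBins) addRow(ds, "contact_vs_s_genomewide", NA, NA, sep = s)
    for (s in hicBins) addRow(ds, "contact_vs_s_centromeric", NA, NA, sep = s)
  }

  schema <- do.call(rbind, rows)
  grp <- c(O1 = "live_imaging", O2 = "live_imaging", O3 = "live_imaging",
           O4 = "live_imaging", O5 = "fixed_imaging", O6 = "fixed_imaging",
           O7 = "fixed_imaging", O8 = "hic_A", O9 = "hic_B")
  schema$group <- unname(grp[schema$dataset])
  schema$id <- paste0(schema$dataset, "_",
                      formatC(stats::ave(seq_len(nrow(schema)), schema$dataset,
                                         FUN = seq_along),
                              width = 3, flag = "0"))
  rownames(schema) <- NULL
  schema[, c("id", "dataset", "class", "chrom_a", "pos_a", "chrom_b", "pos_b",
             "sep_bp", "group")]
}

# ---- internal helpers ------------------------------------------------------

# 3 x nFrames positions of a locus; special loci: "SPB", "NUCLEOLUS"
.locusSeries <- function(traj, chrom, posBp) {
  ch <- traj@chains
  nf <- dim(traj@frames)[3]
  if (is.na(chrom)) stop("locus chromosome is NA")
  if (chrom == "SPB") {
    if (is.null(ch@geometry)) stop("SPB locus needs a geometry")
    return(matrix(ch@geometry@spbPosition, 3, nf))
  }
  if (chrom == "NUCLEOLUS") {
    rd <- ch@rdnaBeads
    if (!length(rd)) stop("nucleolar locus needs rDNA beads")
    return(apply(traj@frames[, rd, , drop = FALSE], c(1, 3), mean))
  }
  b <- locusToBead(ch, chrom, posBp)$globalBead
  traj@frames[, b, ]
}

# per-frame random rotation matrices (imaging-axis isotropy for 2D stats)
.frameRotations <- function(nf) {
  lapply(seq_len(nf), function(i) {
    # uniform random rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    d <- diag(qr.R(qr_))
    q <- q %*% diag(sign(d))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

.distSeries <- function(a, b, projection = "3d", rotations = NULL) {
  d <- a - b
  if (projection == "2d") {
    nf <- ncol(d)
    if (is.null(rotations)) rotations <- .frameRotations(nf)
    d <- vapply(seq_len(nf), function(i) {
      v <- rotations[[i]] %*% d[, i]
      sqrt(v[1]^2 + v[2]^2)
    }, 0)
    return(d)
  }
  sqrt(colSums(d^2))
}

.modeEstimate <- function(x) {
  de <- density(x, bw = "nrd0")
  de$x[which.max(de$y)]
}

.applyStat <- function(x, statistic) {
  switch(statistic, mean = mean(x), median = median(x),
         mode = .modeEstimate(x), stop("unknown statistic: ", statistic))
}

#' Distance statistic between two loci
#'
#' Per-frame Euclidean distances summarized by mean, median or mode
#' (Gaussian kernel density peak, Silverman bandwidth).  2D projection
#' applies a fresh uniform random rotation per frame before dropping one
#' axis, making projected statistics rotation invariant despite the SPB
#' anisotropy; a fixed laboratory axis is available via
#' \code{projectionAxis = "fixed"}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param locusA,locusB loci as list(chrom =, pos =) with 1-based bp, or the
#'   special strings "SPB" / "NUCLEOLUS" (nucleolar = rDNA bead centroid).
#' @param statistic "mean", "median" or "mode".
#' @param projection "3d" or "2d".
#' @param projectionAxis "random" (default) or "fixed" (drop the z axis).
#' @return distance statistic, nm.
#' @export
pairwiseDistanceStats <- function(traj, locusA, locusB,
                                  statistic = c("median", "mean", "mode"),
                                  projection = c("3d", "2d"),
                                  projectionAxis = c("random", "fixed")) {
  statistic <- match.arg(statistic)
  projection <- match.arg(projection)
  projectionAxis <- match.arg(projectionAxis)
  nf <- dim(traj@frames)[3]
  minN <- if (statistic == "mode") 200 else 30
  if (nf < minN)
    stop(sprintf("need >= %d samples for the %s statistic, have %d",
                 minN, statistic, nf))
  asLoc <- function(l) if (is.character(l)) list(chrom = l, pos = NA) else l
  a <- asLoc(locusA); b <- asLoc(locusB)
  sa <- .locusSeries(traj, a$chrom, a$pos)
  sb <- .locusSeries(traj, b$chrom, b$pos)
  rot <- if (projection == "2d" && projectionAxis == "fixed")
    rep(list(diag(3)), nf) else NULL
  .applyStat(.distSeries(sa, sb, projection, rot), statistic)
}

#' Median angle between a locus and the nuclear-nucleolar axis
#'
#' Per-frame angle at the nuclear center between the locus position vector
#' and the vector to the nucleolar centroid (centroid of the rDNA beads),
#' summarized by the median, in degrees.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param locus list(chrom =, pos =).
#' @return median angle in [0, 180] degrees.
#' @export
angleToNucleolarAxis <- function(traj, locus) {
  sa <- .locusSeries(traj, locus$chrom, locus$pos)
  sn <- .locusSeries(traj, "NUCLEOLUS", NA)
  na <- sqrt(colSums(sa^2)); nn <- sqrt(colSums(sn^2))
  if (any(na < 1e-9) || any(nn < 1e-9)) stop("degenerate zero-length vector")
  ct <- colSums(sa * sn) / (na * nn)
  median(acos(pmax(pmin(ct, 1), -1)) * 180 / pi)
}

# contact statistics at bead resolution (shared by computeObservables)
.beadContacts <- function(traj, cutoff, maxSepBp = 100000) {
  ch <- traj@chains
  bpb <- bpPerBead(ch)
  maxSep <- max(1L, min(as.integer(ceiling(maxSepBp / bpb)),
                        max(tabulate(ch@beadChain)) - 1L))
  cpp_contact_stats(traj@frames, ch@beadChain - 1L,
                    integer(nBeads(ch)), ch@centromereBead - 1L,
                    cutoff, maxSep, length(ch@chainNames), 1L)
}

.chainPairFreq <- function(stats, chains) {
  nf <- stats$n_frames
  ns <- tabulate(chains@beadChain, length(chains@chainNames))
  cc <- stats$chain_counts + t(stats$chain_counts)
  diag(cc) <- diag(stats$chain_counts)
  npair <- outer(ns, ns)
  diag(npair) <- ns * (ns - 1) / 2
  cc / (npair * nf)
}

.sepFreqCurves <- function(stats, chains, bins) {
  nf <- stats$n_frames
  ns <- tabulate(chains@beadChain, length(chains@chainNames))
  bpb <- bpPerBead(chains)
  maxSep <- length(stats$sep_counts)
  pairsAt <- vapply(seq_len(maxSep), function(s) sum(pmax(ns - s, 0)), 0)
  fGw <- stats$sep_counts / (pairsAt * nf)
  sBp <- seq_len(maxSep) * bpb
  gw <- approx(sBp, fGw, xout = bins, rule = 2)$y
  fCen <- ifelse(stats$cen_pairs > 0, stats$cen_counts / stats$cen_pairs, NA)
  ok <- !is.na(fCen)
  cen <- approx(sBp[ok], fCen[ok], xout = bins, rule = 2)$y
  list(genomewide = gw, centromeric = cen)
}

#' Compute an observable set from a trajectory
#'
#' Evaluates every row of an observable schema (see
#' \code{\link{buildObservableSchema}}) on a trajectory.  Contact
#' frequencies use a per-frame distance cutoff (default twice the fiber
#' width, i.e. surface proximity).  Unresolvable loci are reported
#' exhaustively.  2D projections consume the current RNG stream; set the
#' seed beforehand for reproducible values.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param schema observable schema data.frame.
#' @param contactCutoff contact distance cutoff, nm.
#' @return an \linkS4class{ObservableSet} (values ordered as the schema).
#' @export
computeObservables <- function(traj, schema,
                               contactCutoff = 2 * traj@chains@params@W) {
  ch <- traj@chains
  nf <- dim(traj@frames)[3]
  # resolve loci up-front, exhaustively
  errs <- character()
  for (i in seq_len(nrow(schema))) {
    for (side in c("a", "b")) {
      cr <- schema[[paste0("chrom_", side)]][i]
      ps <- schema[[paste0("pos_", side)]][i]
      if (is.na(cr) || is.na(ps) || cr %in% c("SPB", "NUCLEOLUS")) next
      ok <- tryCatch({ locusToBead(ch, cr, ps); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) errs <- c(errs, sprintf("%s: %s", schema$id[i], ok))
    }
  }
  if (length(errs))
    stop("unresolvable loci:\n", paste(errs, collapse = "\n"))

  rot <- .frameRotations(nf)
  needHic <- any(schema$class %in% c("contact_summary_intra",
                                     "contact_summary_inter",
                                     "contact_vs_s_genomewide",
                                     "contact_vs_s_centromeric"))
  if (needHic) {
    cs <- .beadContacts(traj, contactCutoff)
    pairFreq <- .chainPairFreq(cs, ch)
    bins <- sort(unique(schema$sep_bp[!is.na(schema$sep_bp)]))
    curves <- if (length(bins)) .sepFreqCurves(cs, ch, bins) else NULL
    ns <- tabulate(ch@beadChain, length(ch@chainNames))
    nOther <- sapply(seq_along(ns), function(i) sum(ns[-i] * ns[i]))
    interFreq <- sapply(seq_along(ns), function(i) {
      cnt <- sum(cs$chain_counts[i, -i]) + sum(cs$chain_counts[-i, i])
      cnt / (nOther[i] * cs$n_frames)
    })
  }

  vals <- se <- numeric(nrow(schema))
  cache <- new.env(parent = emptyenv())
  series <- function(cr, ps) {
    key <- paste(cr, ps)
    if (is.null(cache[[key]])) cache[[key]] <- .locusSeries(traj, cr, ps)
    cache[[key]]
  }
  for (i in seq_len(nrow(schema))) {
    cl <- schema$class[i]
    if (cl %in% c("median_3d_distance", "median_2d_distance",
                  "mean_3d_distance", "mode_3d_distance")) {
      sa <- series(schema$chrom_a[i], schema$pos_a[i])
      sb <- series(schema$chrom_b[i], schema$pos_b[i])
      proj <- if (cl == "median_2d_distance") "2d" else "3d"
      d <- .distSeries(sa, sb, proj, rot)
      stat <- c(median_3d_distance = "median", median_2d_distance = "median",
                mean_3d_distance = "mean", mode_3d_distance = "mode")[cl]
      vals[i] <- .applyStat(d, stat)
      se[i] <- sd(d) / sqrt(nf)
    } else if (cl == "median_angle") {
      vals[i] <- angleToNucleolarAxis(traj, list(chrom = schema$chrom_a[i],
                                                 pos = schema$pos_a[i]))
      se[i] <- 90 / sqrt(nf)
    } else if (cl == "contact_summary_intra") {
      k <- match(schema$chrom_a[i], ch@chainNames)
      vals[i] <- pairFreq[k, k]
      se[i] <- sqrt(max(vals[i] * (1 - vals[i]), 1e-12) / nf)
    } else if (cl == "contact_summary_inter") {
      k <- match(schema$chrom_a[i], ch@chainNames)
      vals[i] <- interFreq[k]
      se[i] <- sqrt(max(vals[i] * (1 - vals[i]), 1e-12) / nf)
    } else if (cl == "contact_vs_s_genomewide") {
      vals[i] <- curves$genomewide[match(schema$sep_bp[i], bins)]
      se[i] <- sqrt(max(vals[i] * (1 - vals[i]), 1e-12) / nf)
    } else if (cl == "contact_vs_s_centromeric") {
      vals[i] <- curves$centromeric[match(schema$sep_bp[i], bins)]
      se[i] <- sqrt(max(vals[i] * (1 - vals[i]), 1e-12) / nf)
    } else stop("unknown observable class: ", cl)
  }
  new("ObservableSet", values = setNames(vals, schema$id),
      stderr = setNames(se, schema$id), schema = schema)
}

#' Binned genome-wide contact map
#'
#' Per-frame binary bead-pair contacts (distance below cutoff) averaged
#' over frames, aggregated to genomic bins as the mean contact frequency
#' over the bead pairs of each bin pair.  Symmetric by construction.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param binSizeBp genomic bin size, bp (must be >= bp per bead).
#' @param contactCutoff contact cutoff, nm.
#' @return a \linkS4class{ContactMap}.
#' @export
contactMap <- function(traj, binSizeBp = 30000,
                       contactCutoff = 2 * traj@chains@params@W) {
  ch <- traj@chains
  bpb <- bpPerBead(ch)
  if (binSizeBp < bpb)
    stop(sprintf("bin size %g bp below bp-per-bead %g", binSizeBp, bpb))
  gch <- ch@genome@chromosomes
  nBinsPer <- ceiling(gch$length_bp / binSizeBp)
  binOff <- cumsum(c(0, nBinsPer[-length(nBinsPer)]))
  mid <- (ch@beadStartBp + ch@beadEndBp) / 2
  localBin <- pmin(floor(mid / binSizeBp), nBinsPer[ch@beadChain] - 1)
  beadBin <- as.integer(binOff[ch@beadChain] + localBin)
  nBin <- sum(nBinsPer)
  st <- cpp_contact_stats(traj@frames, ch@beadChain - 1L, beadBin,
                          ch@centromereBead - 1L, contactCutoff, 1L,
                          length(ch@chainNames), nBin)
  counts <- st$bin_counts + t(st$bin_counts)
  diag(counts) <- diag(st$bin_counts)
  nPerBin <- tabulate(beadBin + 1L, nBin)
  npair <- outer(nPerBin, nPerBin)
  diag(npair) <- nPerBin * (nPerBin - 1) / 2
  freq <- counts / (npair * st$n_frames)
  freq[npair == 0] <- 0
  diag(freq)[nPerBin == 1] <- 1  # single-bead bin: self-contact
  bins <- data.frame(chrom = rep(gch$name, nBinsPer),
                     start_bp = unlist(lapply(nBinsPer, function(k)
                       (seq_len(k) - 1) * binSizeBp)))
  new("ContactMap", matrix = freq, binSize = binSizeBp, bins = bins)
}

#' Hi-C style summaries of a contact map
#'
#' Per-chromosome mean intrachromosomal and interchromosomal contact
#' frequencies plus intrachromosomal contact frequency versus genomic
#' separation (genome-wide and centromere-anchored), interpolated onto the
#' requested separation bins.  For the yeast genome and the default 12 bins
#' this yields 16 + 16 + 12 + 12 = 56 values.
#'
#' @param cmap a \linkS4class{ContactMap} covering all chromosomes.
#' @param genome the matching \linkS4class{GenomeSpec}.
#' @param sepBins separation bin centers, bp.
#' @return an \linkS4class{ObservableSet} with 2 nChrom + 2 nBins values.
#' @export
hicSummaries <- function(cmap, genome, sepBins = seq(25000, 80000, by = 5000)) {
  gch <- genome@chromosomes
  miss <- setdiff(gch$name, unique(cmap@bins$chrom))
  if (length(miss)) stop("contact map missing chromosomes: ",
                         paste(miss, collapse = ", "))
  M <- cmap@matrix
  chromOf <- cmap@bins$chrom
  intra <- vapply(gch$name, function(nm) {
    k <- which(chromOf == nm)
    mean(M[k, k])
  }, 0)
  inter <- vapply(gch$name, function(nm) {
    k <- which(chromOf == nm)
    mean(M[k, -k, drop = FALSE])
  }, 0)
  # contact frequency vs bin separation, averaged over chromosomes
  maxd <- ceiling(max(sepBins) / cmap@binSize) + 1
  acc <- n <- numeric(maxd)
  accC <- nC <- numeric(maxd)
  for (ci in seq_len(nrow(gch))) {
    k <- which(chromOf == gch$name[ci])
    nb <- length(k)
    cenBin <- min(floor(gch$centromere_bp[ci] / cmap@binSize) + 1, nb)
    for (d in seq_len(min(maxd, nb - 1))) {
      v <- M[cbind(k[seq_len(nb - d)], k[seq_len(nb - d) + d])]
      acc[d] <- acc[d] + sum(v)
      n[d] <- n[d] + length(v)
      for (sgn in c(-1, 1)) {
        j <- cenBin + sgn * d
        if (j >= 1 && j <= nb) {
          accC[d] <- accC[d] + M[k[cenBin], k[j]]
          nC[d] <- nC[d] + 1
        }
      }
    }
  }
  sBp <- seq_len(maxd) * cmap@binSize
  ok <- n > 0
  gw <- approx(sBp[ok], (acc / n)[ok], xout = sepBins, rule = 2)$y
  okC <- nC > 0
  cen <- approx(sBp[okC], (accC / nC)[okC], xout = sepBins, rule = 2)$y
  ids <- c(paste0("intra_", gch$name), paste0("inter_", gch$name),
           paste0("vs_s_gw_", sepBins), paste0("vs_s_cen_", sepBins))
  schema <- data.frame(
    id = ids,
    dataset = "HiC",
    class = rep(c("contact_summary_intra", "contact_summary_inter",
                  "contact_vs_s_genomewide", "contact_vs_s_centromeric"),
                c(nrow(gch), nrow(gch), length(sepBins), length(sepBins))),
    chrom_a = c(gch$name, gch$name, rep(NA, 2 * length(sepBins))),
    pos_a = NA, chrom_b = NA, pos_b = NA,
    sep_bp = c(rep(NA, 2 * nrow(gch)), sepBins, sepBins),
    group = "hic_A")
  vals <- c(intra, inter, gw, cen)
  new("ObservableSet", values = setNames(vals, ids),
      stderr = setNames(rep(NA_real_, length(vals)), ids), schema = schema)
}

#' Mean-squared displacement of a locus
#'
#' Time-and-ensemble averaged squared displacement of the locus bead over
#' frame lags.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param locus list(chrom =, pos =) or a vector of global bead indices
#'   (averaged).
#' @param lags frame lags (integers); default a log-spaced set.
#' @return data.frame with \code{lag_frames}, \code{lag_time} (simulation
#'   time units) and \code{msd} (nm^2).
#' @export
msd <- function(traj, locus, lags = NULL) {
  nf <- dim(traj@frames)[3]
  if (is.null(lags))
    lags <- unique(round(exp(seq(log(1), log(nf - 1), length.out = 30))))
  if (any(lags >= nf)) stop("lag exceeds trajectory span")
  beads <- if (is.list(locus))
    locusToBead(traj@chains, locus$chrom, locus$pos)$globalBead
  else as.integer(locus)
  out <- vapply(lags, function(l) {
    tot <- 0
    for (b in beads) {
      x <- traj@frames[, b, ]
      d <- x[, (l + 1):nf, drop = FALSE] - x[, 1:(nf - l), drop = FALSE]
      tot <- tot + mean(colSums(d^2))
    }
    tot / length(beads)
  }, 0)
  data.frame(lag_frames = lags,
             lag_time = lags * traj@sampleEvery * traj@dt,
             msd = out)
}

#' Fit the time-axis scale between simulated and measured MSD curves
#'
#' Least-squares fit (on log MSD) of a single multiplicative scale alpha
#' mapping simulation time to experimental time (experimental t corresponds
#' to simulation t / alpha), shared across loci of a dataset.
#'
#' @param msdSim data.frame with columns \code{time}, \code{msd} (simulated).
#' @param msdExp data.frame with columns \code{time}, \code{msd} (measured).
#' @return fitted scale alpha (experimental time units per simulation time
#'   unit).
#' @export
fitTimeScale <- function(msdSim, msdExp) {
  fs <- function(tq) approx(log(msdSim$time), log(msdSim$msd), xout = log(tq),
                            rule = 1)$y
  obj <- function(logA) {
    a <- exp(logA)
    pred <- fs(msdExp$time / a)
    ok <- !is.na(pred)
    if (sum(ok) < 2) return(1e10)
    sum((log(msdExp$msd[ok]) - pred[ok])^2) + 1e-3 * (sum(!ok))
  }
  lo <- log(min(msdExp$time) / max(msdSim$time))
  hi <- log(max(msdExp$time) / min(msdSim$time))
  if (lo >= hi) stop("non-overlapping time ranges")
  opt <- optimize(obj, c(lo, hi))
  if (opt$objective >= 1e10) stop("non-overlapping time ranges after scaling")
  exp(opt$minimum)
}
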