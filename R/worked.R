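# Fiber-structure arithmetic relating inferred compaction to nucleosome
# packing density.

#' Nucleosomes per 11 nm of fiber from a compaction value
#'
#' With a nucleosome repeat length of 167 bp in yeast, a compaction C in
#' bp/nm corresponds to C * 11 / 167 nucleosomes per 11 nm turn.  The
#' inferred compaction of ~61 bp/nm gives about 4 nucleosomes per 11 nm,
#' between the classical 30 nm fiber (~11 per 11 nm) and the stretched
#' beads-on-a-string fiber (~1 per 11 nm).
#'
#' @param compaction compaction, bp/nm.
#' @param repeatBp nucleosome repeat length, bp.
#' @param turnNm reference fiber length, nm.
#' @return nucleosomes per \code{turnNm} of fiber.
#' @examples
#' nucleosomeDensity(61)  # ~4 per 11 nm
#' @export
nucleosomeDensity <- function(compaction, repeatBp = 167, turnNm = 11) {
  if (compaction <= 0 || repeatBp <= 0 || turnNm <= 0)
    stop("all arguments must be positive")
  compaction * turnNm / repeatBp
}

#' Genome fractions of a two-state fiber mixture
#'
#' If the fiber alternates between two structures with different linear
#' nucleosome densities and each occupies a given fraction of the fiber's
#' linear (contour) length, the corresponding fractions of the genome are
#' proportional to density times length.  Equal linear lengths of a
#' 6-per-11 nm fiber and a 1-per-11 nm fiber hold 6/7 (~86\%) and 1/7
#' (~14\%) of the genome.
#'
#' @param densities linear packing densities of the states (e.g.
#'   nucleosomes per 11 nm, or bp/nm).
#' @param lengthFractions fractions of linear fiber length per state
#'   (summing to 1); default equal.
#' @return genome fraction per state (sums to 1).
#' @examples
#' fiberMixtureGenomeFractions(c(6, 1))  # 0.857, 0.143
#' @export
fiberMixtureGenomeFractions <- function(densities,
                                        lengthFractions =
                                          rep(1 / length(densities),
                                              length(densities))) {
  if (any(densities <= 0)) stop("densities must be positive")
  if (abs(sum(lengthFractions) - 1) > 1e-9)
    stop("lengthFractions must sum to 1")
  w <- densities * lengthFractions
  w / sum(w)
}
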