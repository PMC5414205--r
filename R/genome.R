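# Genome specifications and their text representation.

#' Construct a genome specification
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length_bp},
#'   \code{centromere_bp} (1-based bp).
#' @param rdna optional list/data.frame with \code{name}, \code{start_bp},
#'   \code{end_bp} (1-based inclusive) marking the rDNA interval.
#' @return a \linkS4class{GenomeSpec}.
#' @export
genomeSpec <- function(chromosomes, rdna = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  chromosomes$name <- as.character(chromosomes$name)
  if (is.null(rdna)) {
    rdna <- data.frame(name = character(), start_bp = numeric(),
                       end_bp = numeric())
  } else {
    rdna <- as.data.frame(as.list(rdna))
    rdna$name <- as.character(rdna$name)
  }
  new("GenomeSpec", chromosomes = chromosomes, rdna = rdna)
}

#' The packaged S. cerevisiae genome specification
#'
#' Sixteen chromosomes with sacCer3 reference lengths and centromere
#' midpoints (chromosome 1 at 230 Kb, chromosome 4 at 1531 Kb), and the
#' rDNA interval on chromosome 12.  The in-vivo rDNA repeat array spans
#' roughly 1-2 Mb; in the model the configured interval is excised and
#' replaced by a fixed number of enlarged beads (see
#' \code{\link{nucleusGeometry}}), so only its location matters.
#'
#' @return a \linkS4class{GenomeSpec} with 16 chromosomes.
#' @examples
#' yeastGenome()
#' @export
yeastGenome <- function() {
  dir <- system.file("extdata", package = "chromInfer")
  ch <- read.delim(file.path(dir, "sc_genome.tsv"))
  rd <- read.delim(file.path(dir, "sc_rdna.tsv"))
  genomeSpec(ch, rd)
}

#' A reduced three-chromosome genome for desk-scale validation
#'
#' Chromosomes 1, 4 and 12 of the yeast spec at one fifth of their genomic
#' lengths (centromeres and the rDNA interval scaled likewise).  Used with
#' \code{\link{reducedGeometry}}, which shrinks the nucleus to preserve the
#' genome-bp per nuclear-volume ratio of the full system.
#'
#' @return a \linkS4class{GenomeSpec} with 3 chromosomes.
#' @export
reducedGenome <- function() {
  genomeSpec(
    data.frame(name = c("chrA", "chrB", "chrC"),
               length_bp = c(46044, 306387, 215635),
               centromere_bp = c(30293, 89942, 30166)),
    list(name = "chrC", start_bp = 90200, end_bp = 93780))
}

#' Read / write a genome specification as delimited text
#'
#' Format: a tab-separated chromosome table (name, length_bp, centromere_bp)
#' with an optional rDNA line of the form
#' \code{#rdna<TAB>name<TAB>start_bp<TAB>end_bp} at the top.
#'
#' @param path file path.
#' @return \code{readGenomeSpec}: a \linkS4class{GenomeSpec}.
#' @export
readGenomeSpec <- function(path) {
  lines <- readLines(path)
  rdna <- NULL
  rl <- grep("^#rdna\t", lines, value = TRUE)
  if (length(rl)) {
    f <- strsplit(rl[1], "\t")[[1]]
    rdna <- list(name = f[2], start_bp = as.numeric(f[3]),
                 end_bp = as.numeric(f[4]))
  }
  body <- lines[!startsWith(lines, "#")]
  ch <- read.delim(text = paste(body, collapse = "\n"))
  genomeSpec(ch, rdna)
}

#' @rdname readGenomeSpec
#' @param genome a \linkS4class{GenomeSpec}.
#' @export
writeGenomeSpec <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rd <- genome@rdna
  if (nrow(rd))
    writeLines(sprintf("#rdna\t%s\t%d\t%d", rd$name, as.integer(rd$start_bp),
                       as.integer(rd$end_bp)), con)
  write.table(genome@chromosomes, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Chromosome names of a genome specification
#' @param genome a \linkS4class{GenomeSpec}.
#' @export
chromosomeNames <- function(genome) genome@chromosomes$name

#' Chromosome length lookup
#' @param genome a \linkS4class{GenomeSpec}.
#' @param chrom chromosome name.
#' @export
chromosomeLength <- function(genome, chrom) {
  i <- match(chrom, genome@chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome@chromosomes$length_bp[i]
}
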