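# Plain-text file formats: observable sets / measurement datasets,
# contact maps (dense and sparse triplet) and run configuration.

#' Write / read an observable set or measurement dataset as delimited text
#'
#' Tab-separated with columns id, dataset, class, chrom_a, pos_a, chrom_b,
#' pos_b, sep_bp, group, value, stderr — the same schema for model
#' predictions and experimental measurement tables.
#'
#' @param x an \linkS4class{ObservableSet} or a dataset data.frame with a
#'   \code{value} column.
#' @param path file path.
#' @export
writeObservableSet <- function(x, path) {
  if (is(x, "ObservableSet")) {
    df <- x@schema
    df$value <- unname(x@values[df$id])
    df$stderr <- unname(x@stderr[df$id])
  } else {
    df <- x
    if (is.null(df$stderr)) df$stderr <- NA_real_
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeObservableSet
#' @return \code{readDataset}: data.frame; \code{readObservableSet}: an
#'   \linkS4class{ObservableSet}.
#' @export
readDataset <- function(path) {
  df <- read.delim(path)
  need <- c("id", "class", "value", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname writeObservableSet
#' @export
readObservableSet <- function(path) {
  df <- readDataset(path)
  schema <- df[, setdiff(names(df), c("value", "stderr"))]
  new("ObservableSet", values = setNames(as.numeric(df$value), df$id),
      stderr = setNames(if (is.null(df$stderr)) rep(NA_real_, nrow(df))
                        else as.numeric(df$stderr), df$id),
      schema = schema)
}

#' Write / read contact maps as text
#'
#' Dense format: whitespace-delimited matrix preceded by two header lines
#' (bin size; bin coordinates as chrom:start).  Triplet format:
#' tab-separated \code{bin_i}, \code{bin_j}, \code{frequency} for the upper
#' triangle of non-zero entries.
#'
#' @param cmap a \linkS4class{ContactMap}.
#' @param path file path.
#' @export
writeContactMapDense <- function(cmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#binsize\t%d", as.integer(cmap@binSize)), con)
  writeLines(paste0("#bins\t", paste(cmap@bins$chrom, cmap@bins$start_bp,
                                     sep = ":", collapse = "\t")), con)
  write.table(cmap@matrix, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeContactMapDense
#' @export
readContactMapDense <- function(path) {
  lines <- readLines(path, n = 2)
  binSize <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
  binsRaw <- strsplit(lines[2], "\t")[[1]][-1]
  parts <- strsplit(binsRaw, ":")
  bins <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     start_bp = as.numeric(vapply(parts, `[`, "", 2)))
  m <- as.matrix(read.table(path, skip = 2))
  dimnames(m) <- NULL
  new("ContactMap", matrix = m, binSize = binSize, bins = bins)
}

#' @rdname writeContactMapDense
#' @export
writeContactMapTriplet <- function(cmap, path) {
  m <- cmap@matrix
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2], frequency = m[idx])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#binsize\t%d\t#nbins\t%d", as.integer(cmap@binSize),
                     nrow(m)), con)
  writeLines(paste0("#bins\t", paste(cmap@bins$chrom, cmap@bins$start_bp,
                                     sep = ":", collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContactMapTriplet
#' @export
readContactMapTriplet <- function(path) {
  lines <- readLines(path, n = 2)
  hdr <- strsplit(lines[1], "\t")[[1]]
  binSize <- as.numeric(hdr[2])
  nb <- as.integer(hdr[4])
  binsRaw <- strsplit(lines[2], "\t")[[1]][-1]
  parts <- strsplit(binsRaw, ":")
  bins <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     start_bp = as.numeric(vapply(parts, `[`, "", 2)))
  df <- read.delim(path, skip = 2)
  m <- matrix(0, nb, nb)
  m[cbind(df$bin_i, df$bin_j)] <- df$frequency
  m[cbind(df$bin_j, df$bin_i)] <- df$frequency
  new("ContactMap", matrix = m, binSize = binSize, bins = bins)
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections \code{genome} (path or "yeast" /
#' "reduced"), \code{geometry}, \code{parameters} (P, C, W, L),
#' \code{simulation} (steps, dt, sample_every, equilibration_steps, seed),
#' \code{observables}, \code{inference} and \code{output}.  Validation
#' errors name the offending field.
#'
#' @param path YAML file path.
#' @return named list with a \code{configHash} attribute.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validateConfig(cfg)
  attr(cfg, "configHash") <- .configHash(cfg)
  cfg
}

.configHash <- function(cfg) {
  raw <- as.integer(serialize(cfg, NULL, version = 2))
  # small rolling hash; stable across sessions for identical configs
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2^28
  sprintf("%08x", h)
}

.validateConfig <- function(cfg) {
  err <- function(field, why) stop(sprintf("config field '%s': %s", field, why),
                                   call. = FALSE)
  p <- cfg$parameters
  if (!is.null(p)) {
    for (nm in c("P", "C", "W", "L")) {
      if (is.null(p[[nm]])) err(paste0("parameters.", nm), "missing")
      if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
        err(paste0("parameters.", nm), "must be a positive number")
    }
  }
  s <- cfg$simulation
  if (!is.null(s)) {
    for (nm in c("steps", "sample_every")) {
      if (!is.null(s[[nm]]) && (!is.numeric(s[[nm]]) || s[[nm]] <= 0))
        err(paste0("simulation.", nm), "must be a positive number")
    }
  }
  invisible(TRUE)
}

.resolveGenome <- function(spec) {
  if (is.null(spec) || identical(spec, "yeast")) return(yeastGenome())
  if (identical(spec, "reduced")) return(reducedGenome())
  readGenomeSpec(spec)
}

.resolveGeometry <- function(g) {
  if (is.null(g)) return(nucleusGeometry())
  if (identical(g, "reduced")) return(reducedGeometry())
  do.call(nucleusGeometry, g)
}
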