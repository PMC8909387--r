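#' Genome coordinate model
#'
#' A genome model is the coordinate frame for all copy-number scoring: an
#' ordered set of chromosomes, each with a total length and a single
#' centromere breakpoint splitting it into a p arm `[0, centromere)` and a
#' q arm `[centromere, length)`. All coordinates in the package are 0-based
#' half-open base pairs.
#'
#' @param chrom character vector of unique chromosome names (order is kept).
#' @param length_bp integer-ish vector of chromosome lengths in bp (> 0).
#' @param centromere_bp centromere positions in bp, strictly inside
#'   `(0, length_bp)`.
#' @return A `genome_model`: a data frame with columns `chrom`, `length_bp`,
#'   `centromere_bp`.
#' @examples
#' g <- genome_model(c("1", "2"), c(100e6, 80e6), c(40e6, 30e6))
#' arm_table(g)
#' @export
genome_model <- function(chrom, length_bp, centromere_bp) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  centromere_bp <- as.numeric(centromere_bp)
  if (length(chrom) < 1L) stop("genome model needs at least one chromosome")
  if (length(length_bp) != length(chrom) || length(centromere_bp) != length(chrom)) {
    stop("chrom, length_bp and centromere_bp must have equal length")
  }
  dup <- chrom[duplicated(chrom)]
  if (length(dup)) stop("duplicate chromosome name: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(length_bp) | length_bp <= 0)
  if (length(bad)) stop("non-positive length for chromosome ", paste(chrom[bad], collapse = ", "))
  bad <- which(!is.finite(centromere_bp) | centromere_bp <= 0 | centromere_bp >= length_bp)
  if (length(bad)) {
    stop("centromere outside (0, length) for chromosome ", paste(chrom[bad], collapse = ", "))
  }
  out <- data.frame(
    chrom = chrom, length_bp = length_bp, centromere_bp = centromere_bp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_model", "data.frame")
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome model:", nrow(x), "chromosomes,",
      format(sum(x$length_bp) / 1e6, digits = 5), "Mb total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-arm coordinate table
#'
#' @param genome a [genome_model()].
#' @return Data frame with one row per arm: `chrom`, `arm` ("p"/"q"),
#'   `start`, `end`, `length_bp`.
#' @export
arm_table <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  data.frame(
    chrom = rep(genome$chrom, each = 2L),
    arm = rep(c("p", "q"), nrow(genome)),
    start = as.numeric(rbind(0, genome$centromere_bp)),
    end = as.numeric(rbind(genome$centromere_bp, genome$length_bp)),
    stringsAsFactors = FALSE
  ) -> tab
  tab$length_bp <- tab$end - tab$start
  tab
}

#' Assign a segment to a chromosome arm
#'
#' A segment entirely on the p side of the centromere is "p", entirely on the
#' q side "q", and "spanning" otherwise. Vectorized over segments.
#'
#' @param genome a [genome_model()].
#' @param chrom,start,end segment coordinates (0-based half-open).
#' @return Character vector in `c("p", "q", "spanning")`.
#' @export
arm_of <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_model"))
  idx <- match(as.character(chrom), genome$chrom)
  if (anyNA(idx)) {
    stop("chromosome absent from genome model: ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  if (any(start < 0 | end > genome$length_bp[idx] | start >= end)) {
    stop("segment outside chromosome bounds")
  }
  cen <- genome$centromere_bp[idx]
  ifelse(end <= cen, "p", ifelse(start >= cen, "q", "spanning"))
}

#' Read / write a genome model config
#'
#' JSON layout: `{"chromosomes": [{"name": "1", "length_bp": 1e8,
#' "centromere_bp": 4e7}, ...]}`. A tab-separated table with columns
#' `chrom`, `length_bp`, `centromere_bp` is accepted as a fallback.
#'
#' @param path file path.
#' @return [read_genome_model()] returns a validated `genome_model`;
#'   `write_genome_model()` returns `path` invisibly.
#' @export
read_genome_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(cfg$chromosomes)) stop("genome config lacks a 'chromosomes' entry")
    ch <- cfg$chromosomes
    need <- c("name", "length_bp", "centromere_bp")
    if (!all(need %in% names(ch))) {
      stop("genome config chromosomes need fields: ", paste(need, collapse = ", "))
    }
    genome_model(ch$name, ch$length_bp, ch$centromere_bp)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "length_bp", "centromere_bp")
    if (!all(need %in% names(tab))) {
      stop("genome table needs columns: ", paste(need, collapse = ", "))
    }
    genome_model(tab$chrom, tab$length_bp, tab$centromere_bp)
  }
}

#' @rdname read_genome_model
#' @param genome a `genome_model` to serialize.
#' @export
write_genome_model <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  jsonlite::write_json(
    list(chromosomes = data.frame(
      name = genome$chrom, length_bp = genome$length_bp,
      centromere_bp = genome$centromere_bp, stringsAsFactors = FALSE
    )),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Built-in genome models
#'
#' `toy_genome()` is a 3-chromosome model (100/80/60 Mb, centromeres at
#' 40/30/25 Mb) used throughout the unit tests. `hg_autosomes()` is an
#' approximate GRCh38 autosome model (lengths and centromere midpoints
#' rounded to 0.1 Mb); it is a coordinate frame for simulation and scoring,
#' not a replacement for a real cytoband file.
#'
#' @return A [genome_model()].
#' @export
toy_genome <- function() {
  genome_model(c("1", "2", "3"), c(100e6, 80e6, 60e6), c(40e6, 30e6, 25e6))
}

#' @rdname toy_genome
#' @export
hg_autosomes <- function() {
  len <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35, 145.14,
           138.39, 133.80, 135.09, 133.28, 114.36, 107.04, 101.99, 90.34,
           83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  cen <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0, 39.8,
           53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5, 26.2, 28.1,
           12.0, 15.0)
  genome_model(as.character(1:22), len * 1e6, cen * 1e6)
}
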