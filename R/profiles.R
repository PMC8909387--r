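#' Segmented copy-number profile container
#'
#' A `cn_profile` is one sample's ordered copy-number segmentation: a data
#' frame with columns `chrom`, `start`, `end` (0-based half-open bp),
#' `mean_log2`, `status` (`"loss"`, `"normal"`, `"gain"`, or `NA` before
#' status calling) and `n_probes`, plus a `sample_id` attribute. Within each
#' chromosome segments must be sorted and non-overlapping; a profile that
#' tiles its genome (each segment starting where the previous one ends,
#' jointly covering `[0, length)`) additionally satisfies
#' [validate_profile()].
#'
#' @param segments data frame with the columns above (`status`/`n_probes`
#'   optional; they default to `NA` and `0L`).
#' @param sample_id sample identifier.
#' @return A `cn_profile`.
#' @export
cn_profile <- function(segments, sample_id = "sample") {
  need <- c("chrom", "start", "end", "mean_log2")
  if (!all(need %in% names(segments))) {
    stop("segments need columns: ", paste(need, collapse = ", "))
  }
  seg <- data.frame(
    chrom = as.character(segments$chrom),
    start = as.numeric(segments$start),
    end = as.numeric(segments$end),
    mean_log2 = as.numeric(segments$mean_log2),
    status = if ("status" %in% names(segments)) as.character(segments$status) else NA_character_,
    n_probes = if ("n_probes" %in% names(segments)) as.integer(segments$n_probes) else 0L,
    stringsAsFactors = FALSE
  )
  bad <- which(seg$start < 0 | seg$end <= seg$start)
  if (length(bad)) stop("invalid segment coordinates (end <= start) at rows: ",
                        paste(bad, collapse = ", "))
  known <- seg$status[!is.na(seg$status)]
  if (length(known) && !all(known %in% c("loss", "normal", "gain"))) {
    stop("status must be one of loss/normal/gain")
  }
  # keep chromosome order of first appearance, sort by start within
  ord <- order(match(seg$chrom, unique(seg$chrom)), seg$start)
  seg <- seg[ord, , drop = FALSE]
  rownames(seg) <- NULL
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)] - 1e-9)) {
      ov <- which(s$start[-1L] < s$end[-nrow(s)] - 1e-9)
      stop("overlapping segments on chromosome ", ch,
           " (segment pairs ", paste(ov, collapse = ", "), ")")
    }
  }
  attr(seg, "sample_id") <- as.character(sample_id)
  class(seg) <- c("cn_profile", "data.frame")
  seg
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("copy-number profile '", sample_id(x), "': ", nrow(x), " segments on ",
      length(unique(x$chrom)), " chromosomes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' @rdname cn_profile
#' @param x a `cn_profile` or `cn_probes` object.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Check a profile against a genome model
#'
#' Verifies that every chromosome is known, coordinates are in bounds, and
#' the segments tile each covered chromosome contiguously from 0 to its
#' length.
#'
#' @param profile a [cn_profile()].
#' @param genome a [genome_model()].
#' @return `profile`, invisibly; errors name the offending chromosome.
#' @export
validate_profile <- function(profile, genome) {
  stopifnot(inherits(profile, "cn_profile"), inherits(genome, "genome_model"))
  idx <- match(profile$chrom, genome$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome in profile: ",
         paste(unique(profile$chrom[is.na(idx)]), collapse = ", "))
  }
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    len <- genome$length_bp[match(ch, genome$chrom)]
    ok <- s$start[1L] == 0 && abs(s$end[nrow(s)] - len) < 1e-6 &&
      (nrow(s) == 1L || all(abs(s$start[-1L] - s$end[-nrow(s)]) < 1e-6))
    if (!ok) stop("profile does not tile chromosome ", ch)
  }
  invisible(profile)
}

#' Probe-level log-ratio series container
#'
#' @param probes data frame with columns `chrom`, `pos`, `log2ratio`.
#' @param sample_id sample identifier.
#' @return A `cn_probes` data frame sorted by (chromosome appearance, pos).
#' @export
cn_probes <- function(probes, sample_id = "sample") {
  need <- c("chrom", "pos", "log2ratio")
  if (!all(need %in% names(probes))) {
    stop("probes need columns: ", paste(need, collapse = ", "))
  }
  p <- data.frame(
    chrom = as.character(probes$chrom),
    pos = as.numeric(probes$pos),
    log2ratio = as.numeric(probes$log2ratio),
    stringsAsFactors = FALSE
  )
  p <- p[order(match(p$chrom, unique(p$chrom)), p$pos), , drop = FALSE]
  rownames(p) <- NULL
  attr(p, "sample_id") <- as.character(sample_id)
  class(p) <- c("cn_probes", "data.frame")
  p
}

seg_columns <- c("sample", "chrom", "start", "end", "mean_log2", "status", "n_probes")

#' Read and write SEG-like segment tables
#'
#' The on-disk format is a tab-separated table with header
#' `sample  chrom  start  end  mean_log2  status  n_probes` (the last two
#' optional on input), UTF-8, `.` decimal. Coordinates are 0-based half-open
#' by default; `dialect = "one_based_inclusive"` converts the common 1-based
#' inclusive SEG convention on the way in (start-1, end unchanged).
#'
#' @param path file path.
#' @param genome optional [genome_model()]; when supplied, chromosomes are
#'   checked and (with `fill_gaps = TRUE`) uncovered intervals are filled
#'   with neutral segments so the tiling invariant holds.
#' @param dialect `"zero_half_open"` (default) or `"one_based_inclusive"`.
#' @param fill_gaps insert `mean_log2 = 0`, `status = "normal"` filler
#'   segments for uncovered intervals (requires `genome`).
#' @return A named list of [cn_profile()] objects, one per sample.
#' @export
read_segments <- function(path, genome = NULL,
                          dialect = c("zero_half_open", "one_based_inclusive"),
                          fill_gaps = FALSE) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "mean_log2")
  if (!all(need %in% names(tab))) {
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  }
  if (dialect == "one_based_inclusive") tab$start <- tab$start - 1
  bad <- which(tab$end <= tab$start)
  if (length(bad)) stop("segments with end <= start at rows: ", paste(bad, collapse = ", "))
  if (!is.null(genome)) {
    unknown <- setdiff(unique(tab$chrom), genome$chrom)
    if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  out <- lapply(split(tab, tab$sample), function(s) {
    p <- cn_profile(s, sample_id = s$sample[1L])
    if (fill_gaps) {
      if (is.null(genome)) stop("fill_gaps requires a genome model")
      p <- fill_profile_gaps(p, genome)
    }
    p
  })
  out[order(names(out))]
}

fill_profile_gaps <- function(profile, genome) {
  pieces <- list()
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    len <- genome$length_bp[match(ch, genome$chrom)]
    bounds <- c(0, as.vector(rbind(s$start, s$end)), len)
    starts <- bounds[seq(1, length(bounds), 2)]
    ends <- bounds[seq(2, length(bounds), 2)]
    gap <- ends > starts + 1e-9
    if (any(gap)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = starts[gap], end = ends[gap],
        mean_log2 = 0, status = "normal", n_probes = 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(pieces)) return(profile)
  cn_profile(rbind(as.data.frame(profile), do.call(rbind, pieces)),
             sample_id = sample_id(profile))
}

#' @rdname read_segments
#' @param profiles a `cn_profile` or list of them.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    cbind(sample = sample_id(p), as.data.frame(p), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab[, seg_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write probe tables
#'
#' TSV columns: `sample`, `chrom`, `pos`, `log2ratio`.
#'
#' @param path file path.
#' @return A named list of [cn_probes()], one per sample.
#' @export
read_probes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "log2ratio")
  if (!all(need %in% names(tab))) {
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$sample), function(s) cn_probes(s, s$sample[1L]))
  out[order(names(out))]
}

#' @rdname read_probes
#' @param probes a `cn_probes` or list of them.
#' @export
write_probes <- function(probes, path) {
  if (inherits(probes, "cn_probes")) probes <- list(probes)
  tab <- do.call(rbind, lapply(probes, function(p) {
    cbind(sample = sample_id(p), as.data.frame(p), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write per-patient marker/endpoint tables
#'
#' One row per patient; columns `patient_id`, one column per marker, and the
#' endpoints `pfs_time`, `pfs_event`, `os_time`, `os_event`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_patients <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(tab)) stop("patients table needs a patient_id column")
  tab
}

#' @rdname read_patients
#' @param patients data frame as above.
#' @export
write_patients <- function(patients, path) {
  utils::write.table(patients, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
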