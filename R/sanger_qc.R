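#' A Sanger read with per-base qualities
#'
#' Container for one chromatogram-derived read: base calls, per-base
#' Phred quality scores, and (optionally) per-position primary and
#' secondary peak heights from the trace, used for secondary-peak
#' counting.
#'
#' @param id Read identifier.
#' @param bases Nucleotide string.
#' @param quals Integer vector of Phred scores, one per base, all >= 0.
#' @param peaks Optional data frame with columns `position` (1-based),
#'   `primary`, `secondary` (heights >= 0, secondary <= primary).
#' @return Object of class `quality_read`.
#' @export
quality_read <- function(id, bases, quals, peaks = NULL) {
  bases <- as.character(bases)
  if (nchar(bases) == 0) stop("read must be nonempty", call. = FALSE)
  quals <- as.integer(quals)
  if (length(quals) != nchar(bases)) {
    stop("quals must have one score per base", call. = FALSE)
  }
  if (any(is.na(quals)) || any(quals < 0)) {
    stop("quality scores must be >= 0", call. = FALSE)
  }
  if (!is.null(peaks)) {
    needed <- c("position", "primary", "secondary")
    if (!all(needed %in% names(peaks))) {
      stop("peaks must have columns position, primary, secondary",
           call. = FALSE)
    }
    if (any(peaks$primary < 0) || any(peaks$secondary < 0)) {
      stop("peak heights must be >= 0", call. = FALSE)
    }
    if (any(peaks$secondary > peaks$primary)) {
      stop("secondary peak height cannot exceed the primary", call. = FALSE)
    }
    if (any(peaks$position < 1) || any(peaks$position > nchar(bases))) {
      stop("peak positions must fall inside the read", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), bases = bases, quals = quals,
                 peaks = peaks),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat("quality_read ", x$id, ": ", nchar(x$bases), " bases, mean Q ",
      round(mean(x$quals), 1), "\n", sep = "")
  invisible(x)
}

#' Mott quality trimming
#'
#' Mott's modified trimming algorithm: each base gets the score
#' `s_i = p_c - 10^(-Q_i / 10)`, where `p_c = 10^(-cutoff / 10)` is the
#' error probability at the cutoff Phred score, and the retained segment
#' is the contiguous window maximising the cumulative score. If no
#' window has positive score the whole read is discarded. Ties are
#' broken by leftmost start, then by longest window.
#'
#' @param read A [quality_read()].
#' @param cutoff_phred Phred score defining a bad-quality base
#'   (default 40, i.e. error probability 1e-4).
#' @return List of class `trim_result` with 0-based half-open indices
#'   `start` and `end`, the window `score`, and `read`, the trimmed
#'   [quality_read()] (or `NULL` when the read is discarded).
#' @export
mott_trim <- function(read, cutoff_phred = 40) {
  stopifnot(inherits(read, "quality_read"))
  L <- length(read$quals)
  s <- 10^(-cutoff_phred / 10) - 10^(-read$quals / 10)
  # best-window scan over prefix sums: leftmost start, then longest
  prefix <- c(0, cumsum(s))
  best_score <- 0; best_start <- 0L; best_end <- 0L
  min_p <- 0; min_idx <- 0L
  for (e in seq_len(L)) {
    if (prefix[e] < min_p) { min_p <- prefix[e]; min_idx <- e - 1L }
    score <- prefix[e + 1L] - min_p
    if (score > best_score ||
        (score == best_score && score > 0 &&
         (min_idx < best_start || (min_idx == best_start && e > best_end)))) {
      best_score <- score; best_start <- min_idx; best_end <- e
    }
  }
  trimmed <- NULL
  if (best_score > 0) {
    idx <- (best_start + 1L):best_end
    peaks <- read$peaks
    if (!is.null(peaks)) {
      peaks <- peaks[peaks$position %in% idx, , drop = FALSE]
      peaks$position <- peaks$position - best_start
      rownames(peaks) <- NULL
    }
    trimmed <- quality_read(read$id, substr(read$bases, best_start + 1L, best_end),
                            read$quals[idx], peaks)
  } else {
    best_start <- 0L; best_end <- 0L
  }
  structure(list(start = best_start, end = best_end, score = best_score,
                 read = trimmed),
            class = "trim_result")
}

#' Count secondary peaks in a read
#'
#' A position carries a secondary peak when the lower trace peak is at
#' least one third as high as the higher peak (boundary inclusive).
#' Reads without peak data count zero, flagged in the `"no_data"`
#' attribute.
#'
#' @param read A [quality_read()].
#' @return Integer count with a logical `"no_data"` attribute.
#' @export
count_secondary_peaks <- function(read) {
  stopifnot(inherits(read, "quality_read"))
  if (is.null(read$peaks) || nrow(read$peaks) == 0) {
    return(structure(0L, no_data = TRUE))
  }
  p <- read$peaks
  structure(sum(p$secondary >= p$primary / 3), no_data = FALSE)
}

#' Sanger read retention filters
#'
#' Applies the three retention filters to trimmed reads: length strictly
#' greater than `min_length` bases, at most `max_secondary` secondary
#' peaks (inclusive), and mean Phred quality strictly greater than
#' `min_mean_quality`. A read passes overall only if it passes all
#' three.
#'
#' @param reads List of trimmed [quality_read()] objects.
#' @param min_length Length threshold (default 100; a 100-base read
#'   fails).
#' @param max_secondary Secondary-peak cap (default 5; five peaks pass).
#' @param min_mean_quality Mean-quality threshold (default 30; exactly
#'   30 fails).
#' @return Data frame with one row per read: `id`, `length`,
#'   `n_secondary`, `mean_quality`, `pass_length`, `pass_secondary`,
#'   `pass_quality`, `pass`.
#' @export
qc_filter <- function(reads, min_length = 100, max_secondary = 5,
                      min_mean_quality = 30) {
  rows <- lapply(reads, function(rd) {
    stopifnot(inherits(rd, "quality_read"))
    len <- nchar(rd$bases)
    nsec <- as.integer(count_secondary_peaks(rd))
    mq <- mean(rd$quals)
    data.frame(id = rd$id, length = len, n_secondary = nsec,
               mean_quality = mq,
               pass_length = len > min_length,
               pass_secondary = nsec <= max_secondary,
               pass_quality = mq > min_mean_quality,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- out$pass_length & out$pass_secondary & out$pass_quality
  rownames(out) <- NULL
  out
}

#' Full Sanger QC pipeline
#'
#' Mott-trims each read at the given cutoff, then applies the three
#' retention filters to the trimmed reads (length, secondary peaks,
#' mean quality; mean quality is computed on the trimmed segment).
#' Reads whose trim is empty fail with zero length.
#'
#' @param reads List of [quality_read()] objects.
#' @param cutoff_phred Mott trimming cutoff (default 40).
#' @inheritParams qc_filter
#' @return List with `report` (the [qc_filter()] data frame, plus trim
#'   coordinates) and `trimmed` (named list of retained trimmed reads).
#' @export
run_sanger_qc <- function(reads, cutoff_phred = 40, min_length = 100,
                          max_secondary = 5, min_mean_quality = 30) {
  trims <- lapply(reads, mott_trim, cutoff_phred = cutoff_phred)
  ids <- vapply(reads, function(r) r$id, character(1))
  kept <- !vapply(trims, function(tr) is.null(tr$read), logical(1))
  report <- do.call(rbind, lapply(seq_along(reads), function(i) {
    tr <- trims[[i]]
    if (is.null(tr$read)) {
      data.frame(id = ids[i], trim_start = 0L, trim_end = 0L, length = 0L,
                 n_secondary = 0L, mean_quality = NA_real_,
                 pass_length = FALSE, pass_secondary = TRUE,
                 pass_quality = FALSE, pass = FALSE, stringsAsFactors = FALSE)
    } else {
      qc <- qc_filter(list(tr$read), min_length, max_secondary,
                      min_mean_quality)
      cbind(qc[, "id", drop = FALSE],
            data.frame(trim_start = tr$start, trim_end = tr$end),
            qc[, setdiff(names(qc), "id")])
    }
  }))
  rownames(report) <- NULL
  trimmed <- lapply(trims[kept], function(tr) tr$read)
  names(trimmed) <- ids[kept]
  list(report = report, trimmed = trimmed[report$pass[kept]])
}

#' Read FASTQ (and optional peak sidecar) into quality reads
#'
#' Reads Phred+33 FASTQ into a list of [quality_read()] objects. An
#' optional tab-separated sidecar supplies per-position primary and
#' secondary trace peak heights (columns `id`, `position`, `primary`,
#' `secondary`); binary chromatogram formats are not parsed.
#'
#' @param fastq Path to a FASTQ file.
#' @param peaks_tsv Optional path to the peak-height TSV.
#' @return Named list of [quality_read()] objects.
#' @export
read_fastq_reads <- function(fastq, peaks_tsv = NULL) {
  # the reader drops its internal quality metadata column with a warning
  seqs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  quals <- methods::as(Biostrings::quality(seqs), "IntegerList")
  peaks <- NULL
  if (!is.null(peaks_tsv)) {
    peaks <- read.delim(peaks_tsv, stringsAsFactors = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    pk <- NULL
    if (!is.null(peaks)) {
      pk <- peaks[peaks$id == ids[i], c("position", "primary", "secondary")]
      if (nrow(pk) == 0) pk <- NULL else rownames(pk) <- NULL
    }
    quality_read(ids[i], as.character(seqs[[i]]), as.integer(quals[[i]]), pk)
  })
  names(out) <- ids
  out
}

#' Write quality reads as FASTQ
#'
#' Writes a list of [quality_read()] objects (e.g. trimmed reads) to a
#' Phred+33 FASTQ file.
#'
#' @param reads List of [quality_read()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, function(r) r$bases,
                                          character(1)))
  names(seqs) <- vapply(reads, function(r) r$id, character(1))
  qual <- Biostrings::PhredQuality(
    vapply(reads, function(r) rawToChar(as.raw(r$quals + 33L)), character(1)))
  # the constructors drop (empty) metadata columns with a warning
  suppressWarnings({
    qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    Biostrings::writeQualityScaledXStringSet(qs, path)
  })
  invisible(path)
}
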