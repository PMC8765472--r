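# Read binning: fixed-size non-overlapping bins for first-pass chromosome
# labelling, and single-base sliding windows for junction refinement.

#' Binning parameters
#'
#' Long-read mode (the default) uses 0.2 kb bins on reads of at least
#' 600 bases; short-read mode uses 0.05 kb bins on reads of at least
#' 150 bases. A read must hold at least three bins (A, U and B each need
#' one).
#'
#' @param bin_size Bin length in bases.
#' @param min_read_len Minimum read length; shorter reads are skipped.
#' @param max_mismatch Per-bin mismatch allowance for unique alignment;
#'   defaults to [default_max_mismatch()] of the bin size.
#' @param window_step Sliding-window step for refinement (single base).
#' @return A `binning_params` list.
#' @export
binning_params <- function(bin_size = 200L, min_read_len = 600L,
                           max_mismatch = default_max_mismatch(bin_size),
                           window_step = 1L) {
  bin_size <- as.integer(bin_size)
  min_read_len <- as.integer(min_read_len)
  if (min_read_len < 3L * bin_size)
    stop("min_read_len must be at least 3 * bin_size")
  structure(list(bin_size = bin_size, min_read_len = min_read_len,
                 max_mismatch = as.integer(max_mismatch),
                 window_step = as.integer(window_step)),
            class = "binning_params")
}

#' Short-read (0.05 kb bin) parameter preset
#'
#' @inheritParams binning_params
#' @return A `binning_params` list with 50-base bins and a 150-base
#'   minimum read length.
#' @export
binning_params_short <- function(max_mismatch = default_max_mismatch(50L)) {
  binning_params(bin_size = 50L, min_read_len = 150L, max_mismatch = max_mismatch)
}

#' Split a read into non-overlapping fixed-size bins
#'
#' Bins are contiguous from position 0; the trailing fragment shorter than
#' `bin_size` is discarded, so every bin is exactly `bin_size` long.
#'
#' @param seq Read sequence (character or `DNAString`).
#' @param bin_size Bin length in bases.
#' @return A data frame with `bin` (1-based ordinal), `read_start`
#'   (0-based), `read_end` (exclusive) and `sequence`.
#' @export
split_read_into_bins <- function(seq, bin_size) {
  seq <- as.character(seq)
  n <- nchar(seq) %/% bin_size
  starts <- (seq_len(n) - 1L) * bin_size
  data.frame(
    bin = seq_len(n),
    read_start = starts,
    read_end = starts + bin_size,
    sequence = substring(seq, starts + 1L, starts + bin_size),
    stringsAsFactors = FALSE
  )
}

#' Enumerate single-base-shift sliding windows over a read
#'
#' @param seq Read sequence.
#' @param window Window length in bases.
#' @param step Step between window starts (default 1).
#' @param from,to Optional 0-based bounds restricting window starts to
#'   `[from, to - window]` (defaults: the whole read).
#' @return A data frame with `read_start` (0-based) and `sequence`; zero
#'   rows when the read (or restricted span) is shorter than `window`.
#' @export
sliding_windows <- function(seq, window, step = 1L, from = 0L, to = nchar(seq)) {
  seq <- as.character(seq)
  to <- min(to, nchar(seq))
  if (to - from < window) {
    return(data.frame(read_start = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(from, to - window, by = step)
  data.frame(
    read_start = as.integer(starts),
    sequence = substring(seq, starts + 1L, starts + window),
    stringsAsFactors = FALSE
  )
}

#' Align every bin of a read
#'
#' @param read_id Read identifier.
#' @param seq Read sequence.
#' @param index A [genome_index()].
#' @param params A [binning_params()].
#' @return A bin-alignment data frame (`read_id`, `bin`, `read_start`,
#'   `read_end`, `status`, `chrom`, `pos`, `strand`, `mismatches`), or
#'   `NULL` when the read is shorter than `min_read_len`.
#' @export
align_read_bins <- function(read_id, seq, index, params = binning_params()) {
  seq <- as.character(seq)
  if (nchar(seq) < params$min_read_len) return(NULL)
  bins <- split_read_into_bins(seq, params$bin_size)
  hits <- lapply(bins$sequence, align_sequence, index = index,
                 max_mismatch = params$max_mismatch)
  data.frame(
    read_id = read_id,
    bin = bins$bin,
    read_start = bins$read_start,
    read_end = bins$read_end,
    status = vapply(hits, `[[`, character(1), "status"),
    chrom = vapply(hits, `[[`, character(1), "chrom"),
    pos = vapply(hits, `[[`, integer(1), "pos"),
    strand = vapply(hits, `[[`, character(1), "strand"),
    mismatches = vapply(hits, `[[`, integer(1), "mismatches"),
    stringsAsFactors = FALSE
  )
}

#' Ingest externally computed bin alignments from SAM/BAM
#'
#' Real-data mode: bins are aligned by an external aligner whose query names
#' encode the read and bin as `"readid/binindex"`. Per bin, the status is
#' `unmapped` when every record carries the unmapped flag, `unique` when
#' there is exactly one primary mapped record and no secondary record, and
#' `multi` otherwise.
#'
#' @param path Path to a SAM or BAM file.
#' @return A bin-alignment data frame as from [align_read_bins()] (without
#'   `read_end`/`mismatches` guarantees beyond what the records carry).
#' @export
ingest_alignments <- function(path) {
  fmt <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "SAM" else "BAM"
  if (fmt == "SAM") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "strand"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(rec$qname) == 0L) {
    return(data.frame(read_id = character(0), bin = integer(0),
                      status = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  ok <- grepl("^.+/[0-9]+$", rec$qname)
  if (any(!ok)) stop("un-parseable query name (expected 'readid/binindex'): ",
                     rec$qname[which(!ok)[1]])
  read_id <- sub("/[0-9]+$", "", rec$qname)
  bin <- as.integer(sub("^.*/", "", rec$qname))
  key <- paste0(read_id, "\r", bin)
  out <- lapply(split(seq_along(key), key), function(i) {
    fl <- rec$flag[i]
    unmapped <- bitwAnd(fl, 0x4L) != 0L
    secondary <- bitwAnd(fl, 0x100L) != 0L
    primary_mapped <- which(!unmapped & !secondary)
    if (all(unmapped)) {
      status <- "unmapped"; j <- i[1]
      chrom <- NA_character_; pos <- NA_integer_; strand <- NA_character_
    } else if (length(primary_mapped) == 1L && !any(secondary)) {
      status <- "unique"; j <- i[primary_mapped]
      chrom <- as.character(rec$rname[j]); pos <- rec$pos[j] - 1L  # SAM is 1-based
      strand <- as.character(rec$strand[j])
    } else {
      status <- "multi"; j <- i[1]
      chrom <- NA_character_; pos <- NA_integer_; strand <- NA_character_
    }
    data.frame(read_id = read_id[j], bin = bin[j], status = status,
               chrom = chrom, pos = pos, strand = strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$read_id, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
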