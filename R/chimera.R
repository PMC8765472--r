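# A-U-B chimera calling: curation of bin-alignment vectors into
# non-chimeric / chimeric / eliminated classes, and single-base junction
# refinement with the signed gap metric.
#
# Gap sign convention: gap = first_b_window_start - last_a_window_start -
# window_size. Negative = dually aligning (microhomology of length -gap),
# zero = base-to-base juxtaposition, positive = gapped (inserted bases
# aligning to neither donor).

#' Classify one read from its bin-alignment vector
#'
#' A read is `non_chimeric` when all bins align uniquely to one chromosome;
#' `aub_chimeric` when the bins form the pattern A+ U B+ (one or more bins
#' unique to chromosome A, exactly one unmapped transition bin, one or more
#' bins unique to a different chromosome B, no multi-mapping bins and no
#' other unmapped bins); `unmapped` when no bin aligns; `eliminated`
#' otherwise. Direct A-to-B transitions without an unmapped bin are
#' eliminated: the definition requires a single transition bin, so a
#' junction falling exactly on a bin boundary is missed by design.
#'
#' @param bin_aln Bin-alignment data frame for one read (from
#'   [align_read_bins()] or [ingest_alignments()]), ordered by bin.
#' @return A list with `read_id`, `label`, and for chimeric reads the
#'   skeleton fields `chrom_a`, `chrom_b`, `u_bin`, `a_last_start`,
#'   `b_first_end` (read coordinates bounding the refinement span).
#' @export
classify_read <- function(bin_aln) {
  stopifnot(nrow(bin_aln) >= 1L)
  read_id <- bin_aln$read_id[1]
  st <- bin_aln$status
  n <- length(st)
  res <- list(read_id = read_id, label = "eliminated",
              chrom_a = NA_character_, chrom_b = NA_character_,
              u_bin = NA_integer_, a_last_start = NA_integer_,
              b_first_end = NA_integer_)
  if (all(st == "unmapped")) { res$label <- "unmapped"; return(res) }
  if (any(st == "multi")) return(res)
  if (all(st == "unique") && length(unique(bin_aln$chrom)) == 1L) {
    res$label <- "non_chimeric"
    return(res)
  }
  u <- which(st == "unmapped")
  if (length(u) == 1L && u > 1L && u < n && n >= 3L) {
    before <- unique(bin_aln$chrom[seq_len(u - 1L)])
    after <- unique(bin_aln$chrom[(u + 1L):n])
    if (length(before) == 1L && length(after) == 1L && before != after) {
      res$label <- "aub_chimeric"
      res$chrom_a <- before
      res$chrom_b <- after
      res$u_bin <- u
      res$a_last_start <- bin_aln$read_start[u - 1L]
      res$b_first_end <- bin_aln$read_end[u + 1L]
      return(res)
    }
  }
  res
}

#' Refine a chimeric junction to single-base resolution
#'
#' Slides a window of one bin length in single-base steps across the span
#' from the start of the last A bin to the end of the first B bin. The last
#' window uniquely aligned to chromosome A and the first window uniquely
#' aligned to chromosome B (downstream of it) define the junction:
#' gap = first_b_start - last_a_start - window.
#'
#' @param read_seq The read sequence.
#' @param skeleton Chimeric-read skeleton from [classify_read()].
#' @param index A [genome_index()].
#' @param params A [binning_params()].
#' @param refine_max_mismatch Mismatch allowance for refinement windows.
#'   The default 0 keeps the gap estimate unbiased (each tolerated
#'   mismatch could shift the measured gap by up to 2 bases).
#' @return A list describing the junction (`gap`, `junction_type`,
#'   `homology_len`, window starts, genomic A/B footprints), or, when no
#'   qualifying window pair exists, `label = "eliminated"` with a
#'   `reason` of `"no_a_window"`, `"no_b_window"` or `"non_monotonic"`.
#' @export
refine_breakpoint <- function(read_seq, skeleton, index,
                              params = binning_params(),
                              refine_max_mismatch = 0L) {
  stopifnot(skeleton$label == "aub_chimeric")
  w <- params$bin_size
  win <- sliding_windows(as.character(read_seq), window = w,
                         step = params$window_step,
                         from = skeleton$a_last_start,
                         to = skeleton$b_first_end)
  hits <- lapply(win$sequence, align_sequence, index = index,
                 max_mismatch = refine_max_mismatch)
  uniq <- vapply(hits, `[[`, character(1), "status") == "unique"
  chrom <- vapply(hits, `[[`, character(1), "chrom")
  sa <- which(uniq & chrom == skeleton$chrom_a)
  sb <- which(uniq & chrom == skeleton$chrom_b)
  demoted <- function(reason) {
    list(read_id = skeleton$read_id, label = "eliminated", reason = reason)
  }
  if (length(sa) == 0L) return(demoted("no_a_window"))
  ia <- max(sa)
  sb_after <- sb[sb > ia]
  if (length(sb_after) == 0L) {
    return(demoted(if (length(sb) > 0L) "non_monotonic" else "no_b_window"))
  }
  ib <- min(sb_after)
  last_a <- win$read_start[ia]
  first_b <- win$read_start[ib]
  gap <- first_b - last_a - w
  ga <- hits[[ia]]; gb <- hits[[ib]]
  list(
    read_id = skeleton$read_id, label = "aub_chimeric",
    chrom_a = skeleton$chrom_a, chrom_b = skeleton$chrom_b,
    last_a_window_start = last_a, first_b_window_start = first_b,
    gap = gap,
    junction_type = if (gap < 0L) "dual" else if (gap == 0L) "base_to_base" else "gapped",
    homology_len = if (gap < 0L) -gap else 0L,
    a_start = ga$pos, a_end = ga$pos + w, a_strand = ga$strand,
    b_start = gb$pos, b_end = gb$pos + w, b_strand = gb$strand,
    reason = NA_character_
  )
}

chrom_sex_class <- function(chrom_a, chrom_b) {
  is_x <- function(ch) grepl("(^|chr)X$", ch)
  is_y <- function(ch) grepl("(^|chr)Y$", ch)
  x <- is_x(chrom_a) | is_x(chrom_b)
  y <- is_y(chrom_a) | is_y(chrom_b)
  ifelse(x & y, "XY",
         ifelse(x, "X_autosome", ifelse(y, "Y_autosome", "autosome_autosome")))
}

#' Run the full chimera-detection pipeline over a read set
#'
#' Bins and aligns every read, classifies the bin-alignment vectors, and
#' refines every A-U-B candidate to a junction call. Candidates whose
#' refinement fails are demoted to `eliminated`.
#'
#' @param reads Named `DNAStringSet` (or named character vector).
#' @param index A [genome_index()].
#' @param params A [binning_params()].
#' @param refine_max_mismatch Passed to [refine_breakpoint()].
#' @return A list with:
#'   \describe{
#'     \item{classes}{data frame `read_id`, `label` for every processed read}
#'     \item{events}{data frame of refined chimeric events (one per A-U-B
#'       read: chromosomes, window starts, signed `gap`, `junction_type`,
#'       `homology_len`, genomic A/B footprints, `hemizygosity_class`)}
#'     \item{alignments}{all bin alignments (for support counting)}
#'     \item{tallies}{counts: `non_chimeric`, `aub`, `eliminated`,
#'       `unmapped`, `reads_processed`, `reads_skipped`, `total_bases`}
#'   }
#' @export
call_events <- function(reads, index, params = binning_params(),
                        refine_max_mismatch = 0L) {
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) stop("reads must be named")
  classes <- character(0); class_ids <- character(0)
  events <- list()
  aln_all <- list()
  skipped <- 0L
  total_bases <- 0
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    seq <- as.character(reads[[i]])
    ba <- align_read_bins(id, seq, index, params)
    if (is.null(ba)) { skipped <- skipped + 1L; next }
    total_bases <- total_bases + nchar(seq)
    aln_all[[length(aln_all) + 1L]] <- ba
    cls <- classify_read(ba)
    label <- cls$label
    if (label == "aub_chimeric") {
      j <- refine_breakpoint(seq, cls, index, params, refine_max_mismatch)
      if (j$label == "aub_chimeric") {
        events[[length(events) + 1L]] <- data.frame(
          read_id = id, chrom_a = j$chrom_a, chrom_b = j$chrom_b,
          last_a_window_start = j$last_a_window_start,
          first_b_window_start = j$first_b_window_start,
          gap = j$gap, junction_type = j$junction_type,
          homology_len = j$homology_len,
          a_start = j$a_start, a_end = j$a_end, a_strand = j$a_strand,
          b_start = j$b_start, b_end = j$b_end, b_strand = j$b_strand,
          u_bin = cls$u_bin,
          hemizygosity_class = chrom_sex_class(j$chrom_a, j$chrom_b),
          stringsAsFactors = FALSE
        )
      } else {
        label <- "eliminated"
      }
    }
    classes <- c(classes, label)
    class_ids <- c(class_ids, id)
  }
  classes_df <- data.frame(read_id = class_ids, label = classes,
                           stringsAsFactors = FALSE)
  events_df <- if (length(events)) do.call(rbind, events) else data.frame(
    read_id = character(0), chrom_a = character(0), chrom_b = character(0),
    last_a_window_start = integer(0), first_b_window_start = integer(0),
    gap = integer(0), junction_type = character(0), homology_len = integer(0),
    a_start = integer(0), a_end = integer(0), a_strand = character(0),
    b_start = integer(0), b_end = integer(0), b_strand = character(0),
    u_bin = integer(0), hemizygosity_class = character(0),
    stringsAsFactors = FALSE)
  list(
    classes = classes_df,
    events = events_df,
    alignments = if (length(aln_all)) do.call(rbind, aln_all) else NULL,
    tallies = list(
      non_chimeric = sum(classes == "non_chimeric"),
      aub = sum(classes == "aub_chimeric"),
      eliminated = sum(classes == "eliminated"),
      unmapped = sum(classes == "unmapped"),
      reads_processed = length(classes),
      reads_skipped = skipped,
      total_bases = total_bases
    )
  )
}

#' Write called events as BED6 plus junction columns
#'
#' One row per event anchored at the A-side footprint, with extra columns
#' for the B side, signed gap, junction class and homology length.
#'
#' @param events Events data frame from [call_events()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(
    chrom = events$chrom_a, start = events$a_start, end = events$a_end,
    name = events$read_id, score = 0L, strand = events$a_strand,
    chrom_b = events$chrom_b, b_start = events$b_start, b_end = events$b_end,
    gap = events$gap, junction_type = events$junction_type,
    homology_len = events$homology_len,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
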