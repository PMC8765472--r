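# Per-sample summary statistics and event annotation: rates per billion
# bases, non-chimeric support, repeat-context annotation, sequence
# composition, chromosome-pair distribution, sex-chromosome accounting,
# gap-frequency distribution and observed-vs-expected gene-body coverage.

# 0-based half-open interval data frame -> GRanges (1-based) for overlap work
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Chimeric events per billion bases sequenced
#'
#' @param aub_events Number of chimeric (A-U-B) events.
#' @param total_bases Total bases sequenced.
#' @param digits Decimals reported (default 2).
#' @return The rate `aub_events / total_bases * 1e9`, rounded.
#' @export
events_per_billion <- function(aub_events, total_bases, digits = 2L) {
  if (any(total_bases <= 0)) stop("total_bases must be positive")
  round(aub_events / total_bases * 1e9, digits)
}

#' Fold change between two event rates
#'
#' @param rate_test,rate_ref Rates (e.g. events per billion bases).
#' @param digits Decimals reported (default 1).
#' @return `rate_test / rate_ref`, rounded.
#' @export
rate_fold_change <- function(rate_test, rate_ref, digits = 1L) {
  round(rate_test / rate_ref, digits)
}

#' Per-sample sequencing and event summary
#'
#' @param total_reads,total_bases Read and base counts after QC.
#' @param reads_mapped Reads mapped by the aligner.
#' @param aub_events Number of chimeric events.
#' @param support Optional vector of per-event non-chimeric support counts.
#' @return A list with `events_per_billion_bases`, `pct_mapped`,
#'   `mean_read_length` (all 2 decimals) and support mean/sd/median.
#' @export
sample_summary <- function(total_reads, total_bases, reads_mapped = NA,
                           aub_events = NA, support = NULL) {
  list(
    total_reads = total_reads,
    total_bases = total_bases,
    mean_read_length = round(total_bases / total_reads, 2),
    pct_mapped = if (is.na(reads_mapped)) NA_real_
                 else round(reads_mapped / total_reads * 100, 2),
    aub_events = aub_events,
    events_per_billion_bases = if (is.na(aub_events)) NA_real_
                               else events_per_billion(aub_events, total_bases),
    support_mean = if (is.null(support)) NA_real_ else round(mean(support), 2),
    support_sd = if (is.null(support)) NA_real_ else round(stats::sd(support), 2),
    support_median = if (is.null(support)) NA_real_ else stats::median(support)
  )
}

#' Non-chimeric read support per chimeric event
#'
#' For each event, counts the non-chimeric reads having at least one
#' uniquely aligned bin overlapping the A-side or B-side junction
#' footprint, each padded by `window` bases.
#'
#' @param events Events data frame from [call_events()].
#' @param alignments Bin-alignment data frame from [call_events()].
#' @param classes Read-class data frame from [call_events()].
#' @param window Padding around each footprint (default one bin, taken
#'   from the footprint width).
#' @return A list with per-event `support` counts and `mean`, `sd`,
#'   `median`.
#' @export
nonchimeric_support <- function(events, alignments, classes,
                                window = NULL) {
  if (nrow(events) == 0L) {
    return(list(support = integer(0), mean = NA_real_, sd = NA_real_,
                median = NA_real_))
  }
  if (is.null(window)) window <- events$a_end[1] - events$a_start[1]
  nc_ids <- classes$read_id[classes$label == "non_chimeric"]
  aln <- alignments[alignments$status == "unique" &
                      alignments$read_id %in% nc_ids, , drop = FALSE]
  foot <- data.frame(
    chrom = c(events$chrom_a, events$chrom_b),
    start = pmax(0L, c(events$a_start, events$b_start) - window),
    end = c(events$a_end, events$b_end) + window,
    event = rep(seq_len(nrow(events)), 2L)
  )
  if (nrow(aln) == 0L) {
    return(list(support = rep(0L, nrow(events)), mean = 0, sd = NA_real_,
                median = 0))
  }
  bin_w <- aln$read_end - aln$read_start
  gr_aln <- GenomicRanges::GRanges(aln$chrom,
                                   IRanges::IRanges(aln$pos + 1L, aln$pos + bin_w))
  gr_foot <- intervals_to_granges(foot)
  ov <- GenomicRanges::findOverlaps(gr_foot, gr_aln)
  support <- vapply(seq_len(nrow(events)), function(e) {
    rows <- S4Vectors::queryHits(ov) %in% which(foot$event == e)
    length(unique(aln$read_id[S4Vectors::subjectHits(ov)[rows]]))
  }, integer(1))
  list(support = support, mean = mean(support), sd = stats::sd(support),
       median = stats::median(support))
}

#' Annotate events with overlapping repeat classes
#'
#' Intersects each event's junction footprint (the union of the refined
#' A-side and B-side window footprints) with a repeat annotation. The
#' repeat class with the largest overlap (ties broken alphabetically)
#' becomes the event's primary class; events overlapping no repeat are
#' `repeat_free`.
#'
#' @param events Events data frame from [call_events()].
#' @param repeats Repeat interval data frame (0-based; `name` carries
#'   "class/subfamily").
#' @param genome_chroms Optional chromosome names of the genome; when
#'   given, repeat records on unknown chromosomes raise an error.
#' @return A list with `per_event` (data frame: `read_id`,
#'   `primary_class`, `overlap_bases`) and `fractions` (percent of events
#'   per primary class, summing to 100).
#' @export
annotate_repeats <- function(events, repeats, genome_chroms = NULL) {
  if (!is.null(genome_chroms)) {
    bad <- setdiff(unique(repeats$chrom), genome_chroms)
    if (length(bad))
      stop("repeat annotation names unknown chromosome(s): ",
           paste(bad, collapse = ", "))
  }
  n <- nrow(events)
  primary <- rep("repeat_free", n)
  overlap <- rep(0L, n)
  if (n > 0L && nrow(repeats) > 0L) {
    foot <- data.frame(
      chrom = c(events$chrom_a, events$chrom_b),
      start = c(events$a_start, events$b_start),
      end = c(events$a_end, events$b_end),
      event = rep(seq_len(n), 2L)
    )
    gr_foot <- intervals_to_granges(foot)
    gr_rep <- intervals_to_granges(repeats)
    ov <- GenomicRanges::findOverlaps(gr_foot, gr_rep)
    if (length(ov) > 0L) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(GenomicRanges::pintersect(gr_foot[qh], gr_rep[sh]))
      tab <- stats::aggregate(
        w, by = list(event = foot$event[qh], class = repeats$name[sh]), FUN = sum)
      for (e in unique(tab$event)) {
        sub <- tab[tab$event == e, , drop = FALSE]
        sub <- sub[order(-sub$x, sub$class), , drop = FALSE]
        primary[e] <- sub$class[1]
        overlap[e] <- sub$x[1]
      }
    }
  }
  fr <- if (n > 0L) table(primary) / n * 100 else table(character(0))
  list(
    per_event = data.frame(read_id = events$read_id, primary_class = primary,
                           overlap_bases = overlap, stringsAsFactors = FALSE),
    fractions = fr
  )
}

#' Sequence composition: GC, CpG and G/C skew
#'
#' @param seq DNA sequence (character or `DNAString`); case-insensitive.
#' @return A list with `gc_percent` (G+C over A/C/G/T bases, N excluded),
#'   `cpg_percent` (CG dinucleotides over the L-1 dinucleotide positions)
#'   and `gc_skew` ((G-C)/(G+C), 0 when G+C = 0).
#' @export
composition <- function(seq) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L == 0L) stop("empty sequence")
  counts <- table(strsplit(seq, "")[[1]])
  g <- sum(counts[names(counts) == "G"])
  c_ <- sum(counts[names(counts) == "C"])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  cpg <- if (L < 2L) 0L else
    Biostrings::countPattern("CG", Biostrings::DNAString(seq))
  list(
    gc_percent = if (acgt == 0L) 0 else round((g + c_) / acgt * 100, 2),
    cpg_percent = if (L < 2L) 0 else round(cpg / (L - 1) * 100, 2),
    gc_skew = if (g + c_ == 0L) 0 else (g - c_) / (g + c_)
  )
}

#' Chromosome-pair event counts and length correlation
#'
#' Builds the symmetric chromosome-pair count matrix of events and
#' correlates per-chromosome event involvement against chromosome length
#' (chimeras are expected to distribute in proportion to size).
#'
#' @param events Events data frame from [call_events()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A list with `pair_matrix`, `marginal` (events touching each
#'   chromosome), and Pearson `r` and `p` (two-sided, t approximation;
#'   both `NA` with fewer than 3 chromosomes).
#' @export
chromosome_pair_matrix <- function(events, chrom_lengths) {
  chroms <- names(chrom_lengths)
  m <- matrix(0L, length(chroms), length(chroms),
              dimnames = list(chroms, chroms))
  for (i in seq_len(nrow(events))) {
    a <- events$chrom_a[i]; b <- events$chrom_b[i]
    m[a, b] <- m[a, b] + 1L
    m[b, a] <- m[b, a] + 1L
  }
  marginal <- rowSums(m)
  if (length(chroms) < 3L) {
    return(list(pair_matrix = m, marginal = marginal,
                r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(marginal, as.numeric(chrom_lengths),
                        method = "pearson", alternative = "two.sided")
  list(pair_matrix = m, marginal = marginal,
       r = unname(ct$estimate), p = ct$p.value)
}

#' Observed and representation-normalized expected X-U-A percentages
#'
#' The observed percentage is the share of chimeric events joining the X
#' chromosome to an autosome. Because capture of the X can differ between
#' samples, the expected percentage for a test sample re-scales its
#' observed value by the ratio of X-mapped read fractions
#' (test over reference): with equal X representation, expected equals
#' observed.
#'
#' @param test,reference Lists with `reads_mapped`, `reads_mapped_x`,
#'   `xua_events`, `total_events`.
#' @return A list with `observed_ref`, `observed_test`, `expected_test`
#'   (percent, 2 decimals) and the X-mapped fractions.
#' @export
sex_chromosome_accounting <- function(test, reference) {
  pct <- function(s) {
    if (s$total_events <= 0 || s$reads_mapped <= 0) stop("zero totals")
    round(s$xua_events / s$total_events * 100, 2)
  }
  frac_x <- function(s) s$reads_mapped_x / s$reads_mapped
  obs_t <- pct(test); obs_r <- pct(reference)
  fx_t <- frac_x(test); fx_r <- frac_x(reference)
  list(
    observed_ref = obs_r,
    observed_test = obs_t,
    expected_test = round(obs_t * fx_t / fx_r, 2),
    frac_x_test = fx_t,
    frac_x_ref = fx_r
  )
}

#' Histogram of signed junction gaps
#'
#' @param gaps Integer vector of signed gap values (negative = dually
#'   aligning, 0 = base-to-base, positive = gapped).
#' @param bin_width Histogram bin width in bases.
#' @return A data frame with `gap_bin` (left edge), `count` and `percent`
#'   (summing to 100).
#' @export
gap_distribution <- function(gaps, bin_width = 1L) {
  if (length(gaps) == 0L) {
    return(data.frame(gap_bin = integer(0), count = integer(0),
                      percent = numeric(0)))
  }
  left <- floor(gaps / bin_width) * bin_width
  tab <- table(left)
  data.frame(
    gap_bin = as.integer(names(tab)),
    count = as.integer(tab),
    percent = as.numeric(tab) / length(gaps) * 100
  )
}

#' Observed vs expected transcript coverage of event locations
#'
#' Counts how many transcripts are overlapped (by at least 1 base) by a
#' seeded random selection of `n_normalized` event intervals (the
#' "observed" condition), and by the same intervals re-placed uniformly at
#' random genome-wide with lengths preserved (the "expected" condition,
#' averaged over `n_shuffles` shuffles).
#'
#' @param event_intervals 0-based interval data frame (`chrom`, `start`,
#'   `end`) of event locations.
#' @param transcripts 0-based interval data frame of transcript bodies.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_normalized Number of events to select (all, with a warning,
#'   when fewer are available).
#' @param n_shuffles Number of random re-placements (default 10).
#' @param seed Integer seed for selection and shuffling.
#' @return A list with `observed`, `expected` (mean over shuffles) and
#'   `per_shuffle` counts.
#' @export
gene_body_coverage <- function(event_intervals, transcripts, chrom_lengths,
                               n_normalized = nrow(event_intervals),
                               n_shuffles = 10L, seed = 1L) {
  gr_tx <- intervals_to_granges(transcripts)
  n_avail <- nrow(event_intervals)
  if (n_avail == 0L) {
    return(list(observed = 0L, expected = 0, per_shuffle = numeric(0)))
  }
  if (n_normalized > n_avail) {
    warning("n_normalized (", n_normalized, ") exceeds available events (",
            n_avail, "); using all")
    n_normalized <- n_avail
  }
  count_covered <- function(df) {
    sum(GenomicRanges::countOverlaps(gr_tx, intervals_to_granges(df)) > 0L)
  }
  with_sim_seed(seed, {
    sel <- event_intervals[sample.int(n_avail, n_normalized), , drop = FALSE]
    observed <- count_covered(sel)
    widths <- sel$end - sel$start
    lens <- as.numeric(chrom_lengths)
    per_shuffle <- vapply(seq_len(n_shuffles), function(s) {
      ci <- vapply(widths, function(w) {
        p <- pmax(lens - w + 1, 0)
        sample.int(length(lens), 1L, prob = p)
      }, integer(1))
      start <- vapply(seq_along(widths), function(j)
        sample.int(chrom_lengths[ci[j]] - widths[j] + 1L, 1L) - 1L, integer(1))
      count_covered(data.frame(chrom = names(chrom_lengths)[ci],
                               start = start, end = start + widths))
    }, numeric(1))
    list(observed = observed, expected = mean(per_shuffle),
         per_shuffle = per_shuffle)
  })
}
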