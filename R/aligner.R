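# Seed-and-extend end-to-end aligner for toy genomes.
#
# The detection method only needs, per fixed-length query, the set of genomic
# loci with at most `max_mismatch` substitutions over the full query length
# (no gaps). Seeding uses the pigeonhole principle: a query is cut into
# max_mismatch + 1 disjoint exact seeds of length k, so every qualifying
# locus is hit by at least one seed; candidates are then verified by direct
# mismatch counting. This makes the aligner provably equivalent to an
# exhaustive scan for queries of length >= (max_mismatch + 1) * k.

RAW_N <- charToRaw("N")

#' Build a k-mer index over a genome
#'
#' @param genome Named `DNAStringSet` (or object coercible to one).
#' @param k Seed length in bases (default 15).
#' @return A `genome_index` object used by [align_sequence()].
#' @export
genome_index <- function(genome, k = 15L) {
  genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must have unique sequence names")
  k <- as.integer(k)
  chrom_len <- Biostrings::width(genome)
  if (any(chrom_len < k)) stop("all chromosomes must be at least k bases long")
  offsets <- c(0, cumsum(as.numeric(chrom_len)))  # global 0-based chromosome offsets
  seqs <- as.character(genome)
  kmers <- character(0)
  globals <- numeric(0)
  for (i in seq_along(seqs)) {
    starts <- seq_len(chrom_len[i] - k + 1L)
    km <- substring(seqs[i], starts, starts + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)  # N never seeds
    kmers <- c(kmers, km[ok])
    globals <- c(globals, offsets[i] + starts[ok] - 1)
  }
  map <- list2env(split(globals, kmers), hash = TRUE,
                  size = max(2L * length(globals), 64L))
  structure(
    list(
      k = k,
      chrom_names = names(genome),
      chrom_len = chrom_len,
      offsets = offsets,
      raw = lapply(seqs, charToRaw),
      map = map,
      genome = genome
    ),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index: ", length(x$chrom_names), " chromosome(s), ",
      sum(x$chrom_len), " bases, k = ", x$k, "\n", sep = "")
  invisible(x)
}

revcomp <- function(seq) {
  rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", seq))))
}

# Mismatches between query raw bytes and a genome segment; N (in either)
# mismatches everything, including another N.
count_mismatches <- function(qraw, graw) {
  sum(qraw != graw) + sum(qraw == RAW_N & graw == RAW_N)
}

#' Align a query end-to-end against an indexed genome
#'
#' Searches both strands for loci matching the full query with at most
#' `max_mismatch` substitutions (no gaps). The status is `unique` when
#' exactly one such locus exists, `multi` for two or more, `unmapped` for
#' none. Deterministic for a given index.
#'
#' @param query DNA character string (A/C/G/T; N never matches).
#' @param index A [genome_index()].
#' @param max_mismatch Maximum substitutions tolerated over the query.
#' @return A list with `status`, `n_loci`, and for unique hits `chrom`,
#'   `pos` (0-based genomic start), `strand`, `mismatches`.
#' @export
align_sequence <- function(query, index, max_mismatch = 0L) {
  stopifnot(inherits(index, "genome_index"))
  k <- index$k
  qlen <- nchar(query)
  if (qlen < k) stop("query shorter than seed length (", k, ")")
  loci_chrom <- character(0); loci_pos <- integer(0)
  loci_strand <- character(0); loci_mm <- integer(0)
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qraw <- charToRaw(qs)
    n_seeds <- min(max_mismatch + 1L, qlen %/% k)
    seed_off <- (seq_len(n_seeds) - 1L) * k  # disjoint, left-anchored
    cand <- numeric(0)
    for (o in seed_off) {
      hits <- get0(substr(qs, o + 1L, o + k), envir = index$map)
      if (!is.null(hits)) cand <- c(cand, hits - o)
    }
    for (g in unique(cand)) {
      ci <- findInterval(g, index$offsets, rightmost.closed = FALSE)
      pos <- g - index$offsets[ci]
      if (pos < 0 || pos + qlen > index$chrom_len[ci]) next
      mm <- count_mismatches(qraw, index$raw[[ci]][(pos + 1):(pos + qlen)])
      if (mm <= max_mismatch) {
        loci_chrom <- c(loci_chrom, index$chrom_names[ci])
        loci_pos <- c(loci_pos, as.integer(pos))
        loci_strand <- c(loci_strand, strand)
        loci_mm <- c(loci_mm, as.integer(mm))
      }
    }
  }
  n <- length(loci_pos)
  if (n == 0L) {
    list(status = "unmapped", n_loci = 0L, chrom = NA_character_,
         pos = NA_integer_, strand = NA_character_, mismatches = NA_integer_)
  } else if (n == 1L) {
    list(status = "unique", n_loci = 1L, chrom = loci_chrom,
         pos = loci_pos, strand = loci_strand, mismatches = loci_mm)
  } else {
    list(status = "multi", n_loci = n, chrom = NA_character_,
         pos = NA_integer_, strand = NA_character_, mismatches = NA_integer_)
  }
}

#' Default mismatch tolerance for a bin size
#'
#' The uniqueness criterion tolerates substitutions on up to 2% of the bin
#' length (ceiling), e.g. 4 for 200-base bins, 1 for 50-base bins.
#'
#' @param bin_size Bin length in bases.
#' @return Integer mismatch allowance.
#' @export
default_max_mismatch <- function(bin_size) as.integer(ceiling(0.02 * bin_size))
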