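# Shared fixtures, built in code at test time.

# Exhaustive-scan alignment oracle, independent of the seeded aligner:
# counts substitutions at every offset and strand by direct character
# comparison (N mismatches everything, including N).
brute_force_loci <- function(query, genome, max_mismatch) {
  seqs <- as.character(Biostrings::DNAStringSet(genome))
  out <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), mismatches = integer(0))
  mism <- function(q, s) sum(q != s | q == "N" | s == "N")
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else
      rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", query))))
    qc <- strsplit(qs, "")[[1]]
    L <- length(qc)
    for (ch in names(seqs)) {
      sc <- strsplit(seqs[[ch]], "")[[1]]
      if (length(sc) < L) next
      for (off in 0:(length(sc) - L)) {
        mm <- mism(qc, sc[(off + 1):(off + L)])
        if (mm <= max_mismatch) {
          out <- rbind(out, data.frame(chrom = ch, pos = off, strand = strand,
                                       mismatches = mm))
        }
      }
    }
  }
  out
}

# Memoised standard toy world: a repeat-free two-chromosome genome, its
# index, a 9-implant read set covering the three junction types, and the
# pipeline result on those reads.
.toy_cache <- new.env(parent = emptyenv())

toy_world <- function() {
  if (!is.null(.toy_cache$world)) return(.toy_cache$world)
  cfg <- sim_genome_config(c(chrA = 30000L, chrB = 30000L), seed = 101L)
  g <- make_genome(cfg)
  set.seed(202)
  n <- 9L
  implants <- data.frame(
    chrom_a = "chrA", pos_a = sample(2000:28000, n),
    chrom_b = "chrB", pos_b = sample(2000:28000, n),
    junction_type = rep(c("dual", "base_to_base", "gapped"), each = 3L),
    homology_len = c(20L, 40L, 60L, 0L, 0L, 0L, 0L, 0L, 0L),
    insert_len = c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 25L, 50L),
    read_id = sprintf("imp%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  ic <- implant_chimeric_reads(g$genome, implants, read_len = 1000L,
                               flank_min = 300L, a_len = 500L, seed = 303L)
  idx <- genome_index(ic$genome)
  res <- call_events(ic$reads, idx, binning_params())
  .toy_cache$world <- list(genome = ic$genome, index = idx,
                           implants = implants, truth = ic$truth,
                           reads = ic$reads, result = res)
  .toy_cache$world
}

# Minimal trio-site and observation builders for phasing unit tests.
phasing_sites <- function() {
  data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    gt_mother = c("A/A", "C/C", "G/A", "T/T"),
    gt_father = c("G/G", "C/T", "G/G", "T/C"),
    stringsAsFactors = FALSE
  )
}

obs_row <- function(read_id, pos, allele) {
  data.frame(read_id = read_id, chrom = "chr1", pos = pos, allele = allele,
             stringsAsFactors = FALSE)
}

# Write a small VCF from raw text lines (edge-case fixtures).
write_vcf_text <- function(body_lines, path, sample = "s1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    body_lines
  ), path)
  path
}
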