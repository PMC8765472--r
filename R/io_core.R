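# I/O for the standard formats the pipeline touches.
#
# Internal coordinate convention: 0-based half-open everywhere (BED-native).
# 1-based formats (SAM, VCF) and 1-based containers (IRanges/GRanges) are
# shifted only at the parse/write boundary.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on input. Chromosome names are taken from the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one entry per chromosome).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(genome) == 0L) stop("empty FASTA: ", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(names(genome) == "")) stop("malformed FASTA header (empty name) in ", path)
  if (anyDuplicated(names(genome))) {
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(genome))
}

#' Write a genome to FASTA
#'
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, format = "fasta")
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Also tallies the totals used as rate denominators downstream
#' (reads and bases sequenced).
#'
#' @param path Path to a 4-line-record FASTQ file.
#' @return A list with `reads` (named `DNAStringSet`), `qualities`
#'   (`BStringSet`, per-base scores), `n_reads` and `total_bases`.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of ", path)
  if (length(lines) > 0L) {
    i1 <- seq(1L, length(lines), by = 4L)
    if (any(substr(lines[i1], 1, 1) != "@") ||
        any(substr(lines[i1 + 2L], 1, 1) != "+"))
      stop("malformed FASTQ record (header lines) near record ",
           which(substr(lines[i1], 1, 1) != "@")[1])
    bad <- which(nchar(lines[i1 + 1L]) != nchar(lines[i1 + 3L]))
    if (length(bad))
      stop("FASTQ quality length differs from sequence length in record ",
           bad[1])
  }
  reads <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e))
    ),
    # benign: the FASTQ description line metadata is not kept
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  names(reads) <- sub("\\s.*$", "", names(reads))
  list(
    # plain DNAStringSet; dropping the quality metadata column is intended
    reads = suppressWarnings(Biostrings::DNAStringSet(reads)),
    qualities = methods::as(Biostrings::quality(reads), "BStringSet"),
    n_reads = length(reads),
    total_bases = sum(Biostrings::width(reads))
  )
}

#' Write reads to FASTQ
#'
#' @param reads Named `DNAStringSet`.
#' @param path Output path.
#' @param qualities Optional `BStringSet` of per-base scores; constant high
#'   quality ("I") is written when absent.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, qualities = NULL) {
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(qualities)) {
    qualities <- Biostrings::BStringSet(vapply(
      Biostrings::width(reads), function(w) strrep("I", w), character(1)
    ))
  }
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qualities)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED3+ with an optional name in column 4; for repeat annotations the name
#' carries "class/subfamily" (RepeatMasker convention). Coordinates stay in
#' the internal 0-based half-open convention (BED-native).
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `name`, `strand`.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED in ", path, ": ", conditionMessage(e))
  )
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else "",
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$name[is.na(df$name)] <- ""
  df$strand[df$strand == "*"] <- "."
  validate_intervals(df)
  df
}

#' Write genomic intervals to BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  validate_intervals(intervals)
  n <- nrow(intervals)
  name <- if (!is.null(intervals$name)) intervals$name else rep(".", n)
  name[is.na(name) | name == ""] <- "."
  score <- if (!is.null(intervals$score)) intervals$score else rep(0L, n)
  strand <- if (!is.null(intervals$strand)) intervals$strand else rep(".", n)
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) stop("negative interval start")
  if (any(df$start >= df$end)) stop("interval start >= end")
  invisible(df)
}

#' Intersect trio VCFs into bi-parental SNV genotype sites
#'
#' Reads three single-sample VCFs (offspring, mother, father), keeps only
#' single-base substitution sites (indels excluded) present in all three
#' files with a parseable GT, and returns genotypes as unordered allele
#' pairs. This mirrors a three-way `bcftools isec -n +3` intersection.
#'
#' @param offspring,mother,father Paths to the three VCF files.
#' @return A data frame with columns `chrom`, `pos` (0-based), `ref`, `alt`
#'   (comma-joined alternates) and `gt_offspring`, `gt_mother`, `gt_father`
#'   ("X/Y" allele-pair strings). The number of sites skipped for missing
#'   genotypes is attached as attribute `n_skipped`.
#' @export
read_trio_vcf <- function(offspring, mother, father) {
  tabs <- lapply(c(offspring = offspring, mother = mother, father = father),
                 read_vcf_genotypes)
  n_skipped <- sum(vapply(tabs, function(t) attr(t, "n_skipped"), integer(1)))
  key <- function(t) paste(t$chrom, t$pos)
  common <- Reduce(intersect, lapply(tabs, key))
  tabs <- lapply(tabs, function(t) t[match(common, key(t)), , drop = FALSE])
  out <- data.frame(
    chrom = tabs$offspring$chrom,
    pos = tabs$offspring$pos,
    ref = tabs$offspring$ref,
    alt = tabs$offspring$alt,
    gt_offspring = tabs$offspring$gt,
    gt_mother = tabs$mother$gt,
    gt_father = tabs$father$gt,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (n_skipped > 0L) warning(n_skipped, " site(s) skipped for missing GT")
  attr(out, "n_skipped") <- n_skipped
  out
}

# One single-sample VCF -> data frame of SNV sites with "A/G" genotypes.
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- if (ncol(v@gt) >= 2L) {
    vcfR::extract.gt(v, element = "GT")[, 1L]
  } else {
    rep(NA_character_, nrow(fix))
  }
  ref <- toupper(fix$REF)
  alt <- toupper(ifelse(is.na(fix$ALT), "", fix$ALT))
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  snv <- nchar(ref) == 1L &
    vapply(alt_list, function(a) length(a) > 0L && all(nchar(a) == 1L), logical(1))
  has_gt <- !is.na(gt_raw) & grepl("^[0-9]+([/|][0-9]+)?$", gt_raw)
  keep <- snv & has_gt
  n_skipped <- sum(snv & !has_gt)
  alleles <- mapply(function(r, a, g) {
    idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
    paste(c(r, a)[idx], collapse = "/")
  }, ref[keep], alt_list[keep], gt_raw[keep], USE.NAMES = FALSE)
  out <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]) - 1L,  # VCF is 1-based
    ref = ref[keep],
    alt = alt[keep],
    gt = as.character(alleles),
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a minimal single-sample VCF of SNV genotype sites
#'
#' Emits the fixed columns plus a GT-only FORMAT for one sample; intended
#' for simulator output and consumed back through standard VCF parsers.
#'
#' @param sites Data frame with `chrom`, `pos` (0-based), `ref`, `alt` and a
#'   genotype column of "X/Y" allele pairs named by `gt_col`.
#' @param sample_name Sample name for the VCF header/column.
#' @param path Output path.
#' @param gt_col Name of the genotype column in `sites`.
#' @return `path`, invisibly.
#' @export
write_simple_vcf <- function(sites, sample_name, path, gt_col = "gt") {
  stopifnot(gt_col %in% names(sites))
  alleles <- strsplit(sites[[gt_col]], "/", fixed = TRUE)
  alt_list <- strsplit(sites$alt, ",", fixed = TRUE)
  gt_idx <- mapply(function(r, a, al) {
    paste(match(al, c(r, a)) - 1L, collapse = "/")
  }, sites$ref, alt_list, alleles)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  body <- paste(sites$chrom, sites$pos + 1L, ".", sites$ref, sites$alt,
                ".", "PASS", ".", "GT", gt_idx, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
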