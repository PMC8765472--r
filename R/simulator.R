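# Synthetic genomes, reads, implanted chimeric junctions and trios with
# machine-readable truth, so every downstream stage is testable without
# external data. All generators are deterministic for a given seed.

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Substitute each base with probability `rate` by a different random base.
mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  chars
}

#' Configuration for a synthetic genome
#'
#' @param chrom_lengths Integer vector of chromosome lengths in bases;
#'   chromosomes are named `chr1`, `chr2`, ... (or per `names()`).
#' @param repeat_plan Data frame with columns `family` (BED name,
#'   "class/subfamily" convention), `unit_len` (copy length, bases),
#'   `copies` (count) and `divergence` (per-base substitution fraction in
#'   [0, 0.3] applied independently to each copy).
#' @param seed Integer seed.
#' @param bin_size Bin size the genome must support (lengths must be at
#'   least 10 bins).
#' @return A `sim_genome_config` list.
#' @export
sim_genome_config <- function(chrom_lengths, repeat_plan = NULL, seed = 1L,
                              bin_size = 200L) {
  nm <- names(chrom_lengths)
  chrom_lengths <- as.integer(chrom_lengths)
  names(chrom_lengths) <- nm
  if (any(chrom_lengths < 10L * bin_size))
    stop("chromosome lengths must be at least 10 * bin_size")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(repeat_plan)) {
    stopifnot(all(c("family", "unit_len", "copies", "divergence") %in%
                    names(repeat_plan)))
    if (any(repeat_plan$divergence < 0 | repeat_plan$divergence > 0.3))
      stop("repeat divergence must be in [0, 0.3]")
  }
  structure(list(chrom_lengths = chrom_lengths, repeat_plan = repeat_plan,
                 seed = as.integer(seed)),
            class = "sim_genome_config")
}

#' Generate a synthetic genome with planted repeat families
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. Each repeat family
#' has one master unit; copies are placed non-overlapping (uniformly at
#' random across chromosomes, weighted by length) and each copy is diverged
#' independently from the master at the family's divergence rate.
#'
#' @param config A [sim_genome_config()].
#' @return A list with `genome` (named `DNAStringSet`) and `repeats`
#'   (0-based interval data frame with `name` = family).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  with_sim_seed(config$seed, {
    lens <- config$chrom_lengths
    chroms <- lapply(lens, function(L) sample(BASES, L, replace = TRUE))
    placed <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), name = character(0),
                         strand = character(0), stringsAsFactors = FALSE)
    plan <- config$repeat_plan
    if (!is.null(plan) && nrow(plan) > 0L) {
      masters <- vapply(plan$unit_len, function(u)
        paste(sample(BASES, u, replace = TRUE), collapse = ""), character(1))
      if (sum(plan$unit_len * plan$copies) > 0.6 * sum(as.numeric(lens)))
        stop("repeat plan exceeds chromosome capacity")
      for (f in seq_len(nrow(plan))) {
        u <- plan$unit_len[f]
        master <- strsplit(masters[f], "")[[1]]
        for (cp in seq_len(plan$copies[f])) {
          ok <- FALSE
          for (try in 1:200) {
            ci <- sample.int(length(lens), 1L, prob = as.numeric(lens))
            start <- sample.int(lens[ci] - u + 1L, 1L) - 1L
            same <- placed[placed$chrom == names(lens)[ci], , drop = FALSE]
            if (!any(start < same$end & start + u > same$start)) { ok <- TRUE; break }
          }
          if (!ok) stop("repeat plan exceeds chromosome capacity ",
                        "(could not place a non-overlapping copy)")
          copy <- mutate_bases(master, plan$divergence[f])
          chroms[[ci]][(start + 1L):(start + u)] <- copy
          placed <- rbind(placed, data.frame(
            chrom = names(lens)[ci], start = start, end = start + u,
            name = plan$family[f], strand = ".", stringsAsFactors = FALSE))
        }
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1),
                                              collapse = ""))
    names(genome) <- names(lens)
    placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
    rownames(placed) <- NULL
    list(genome = genome, repeats = placed)
  })
}

#' Simulate non-chimeric background reads
#'
#' Reads are drawn uniformly from the genome (chromosome weighted by
#' length, either strand), with an optional i.i.d. per-base substitution
#' error.
#'
#' @param genome Named `DNAStringSet`.
#' @param n_reads Number of reads.
#' @param read_length Fixed read length in bases, or a list
#'   `list(meanlog=, sdlog=, min=)` for log-normal lengths truncated below
#'   at `min`.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param id_prefix Prefix for read identifiers.
#' @return A list with `reads` (named `DNAStringSet`) and `truth` (data
#'   frame: `read_id`, `label = "non_chimeric"`, `chrom`, `start`, `strand`).
#' @export
simulate_reads <- function(genome, n_reads, read_length = 800L,
                           error_rate = 0.01, seed = 1L,
                           id_prefix = "simread") {
  genome <- Biostrings::DNAStringSet(genome)
  lens <- Biostrings::width(genome)
  seqs_chr <- as.character(genome)
  with_sim_seed(seed, {
    if (is.list(read_length)) {
      rl <- pmax(as.integer(round(stats::rlnorm(
        n_reads, read_length$meanlog, read_length$sdlog))),
        as.integer(read_length$min %||% 1L))
    } else rl <- rep(as.integer(read_length), n_reads)
    rl <- pmin(rl, max(lens))
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = as.numeric(lens))
    # chromosome must hold the read
    redo <- which(rl > lens[ci])
    for (i in redo) ci[i] <- sample(which(lens >= rl[i]), 1L)
    start <- vapply(seq_len(n_reads), function(i)
      sample.int(lens[ci[i]] - rl[i] + 1L, 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i) {
      s <- substr(seqs_chr[ci[i]], start[i] + 1L, start[i] + rl[i])
      if (error_rate > 0)
        s <- paste(mutate_bases(strsplit(s, "")[[1]], error_rate), collapse = "")
      if (strand[i] == "-") s <- revcomp(s)
      s
    }, character(1))
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_reads))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    list(
      reads = reads,
      truth = data.frame(read_id = ids, label = "non_chimeric",
                         chrom = names(genome)[ci], start = start,
                         strand = strand, stringsAsFactors = FALSE)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build reads carrying implanted inter-chromosomal junctions
#'
#' Each implant joins a donor-A flank ending at `pos_a` to a donor-B flank
#' starting at `pos_b`, in one of the three junction classes:
#' \describe{
#'   \item{dual}{the `homology_len` bases immediately upstream of both
#'     breakpoints are made identical (the tract is copied from A into the
#'     genome of B), so the junction region aligns to both donors; truth
#'     gap = -homology_len.}
#'   \item{base_to_base}{direct juxtaposition; truth gap = 0.}
#'   \item{gapped}{`insert_len` random bases between the flanks; truth
#'     gap = +insert_len.}
#' }
#'
#' @param genome Named `DNAStringSet`; returned possibly modified (dual
#'   implants plant their homology tract into donor B).
#' @param implants Data frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `junction_type`, `homology_len`, `insert_len`, `read_id`.
#' @param read_len Total read length in bases.
#' @param flank_min Minimum unique donor-derived sequence per side
#'   (default 2 bins of 200 bases).
#' @param a_len Length of read taken from donor A (including, for dual
#'   implants, the homology tract); default splits the read evenly. Choose
#'   `a_len` not a multiple of the bin size so the junction falls inside a
#'   bin (junctions exactly on a bin boundary have no U bin and are missed
#'   by design).
#' @param seed Integer seed (used for gapped inserts).
#' @return A list with `genome` (updated), `reads`, and `truth` (data frame
#'   with the implant coordinates, `gap`, and `junction_read_pos`, the
#'   0-based read coordinate where donor-B-only sequence begins).
#' @export
implant_chimeric_reads <- function(genome, implants, read_len = 1000L,
                                   flank_min = 400L, a_len = NULL, seed = 1L) {
  genome <- Biostrings::DNAStringSet(genome)
  stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b", "junction_type",
                  "homology_len", "insert_len", "read_id") %in% names(implants)))
  bad <- implants$chrom_a == implants$chrom_b
  if (any(bad)) stop("chrom_a must differ from chrom_b for non-homologous implants")
  dual <- implants$junction_type == "dual"
  gapped <- implants$junction_type == "gapped"
  if (any(dual & implants$homology_len <= 0) || any(!dual & implants$homology_len != 0))
    stop("homology_len must be > 0 exactly for dual implants")
  if (any(gapped & implants$insert_len <= 0) || any(!gapped & implants$insert_len != 0))
    stop("insert_len must be > 0 exactly for gapped implants")
  seqs <- as.character(genome)
  with_sim_seed(seed, {
    out_seq <- character(nrow(implants))
    truth <- implants
    truth$label <- "aub_chimeric"
    truth$gap <- ifelse(dual, -implants$homology_len,
                        ifelse(gapped, implants$insert_len, 0L))
    truth$junction_read_pos <- NA_integer_
    n_imp <- nrow(implants)
    la_v <- integer(n_imp); lb_v <- integer(n_imp)
    mid_v <- integer(n_imp); h_v <- integer(n_imp)
    pick_diff <- function(base) sample(setdiff(BASES, base), 1L)
    ## Pass 1: validate and apply all genome edits (homology tracts and
    ## junction-maximality fixes), so every read is built from the final
    ## genome and overlapping edits cannot desynchronise reads from it.
    for (i in seq_len(n_imp)) {
      im <- implants[i, ]
      mid_v[i] <- if (im$junction_type == "gapped") im$insert_len else 0L
      h_v[i] <- if (im$junction_type == "dual") im$homology_len else 0L
      la_v[i] <- if (is.null(a_len)) (read_len - mid_v[i]) %/% 2L
                 else as.integer(a_len)
      lb_v[i] <- read_len - mid_v[i] - la_v[i]
      if (la_v[i] - h_v[i] < flank_min || lb_v[i] < flank_min)
        stop("implant ", im$read_id, ": flanks shorter than flank_min ",
             "(undetectable by design)")
      A <- seqs[[im$chrom_a]]
      if (im$pos_a - la_v[i] < 0L || im$pos_a > nchar(A))
        stop("implant ", im$read_id, ": A flank out of bounds")
      if (im$pos_b - h_v[i] < 0L || im$pos_b + lb_v[i] > nchar(seqs[[im$chrom_b]]))
        stop("implant ", im$read_id, ": B flank out of bounds")
      h <- h_v[i]
      if (h > 0L) {  # plant the homology tract into donor B
        tract <- substr(A, im$pos_a - h + 1L, im$pos_a)
        substr(seqs[[im$chrom_b]], im$pos_b - h + 1L, im$pos_b) <- tract
      }
      # Make the declared junction maximal so the truth gap is identifiable:
      # the base following the A breakpoint must not be extendable into the
      # read, nor the base preceding the B-compatible tract; coincident
      # matches there would lengthen the apparent homology (or shorten an
      # insert) and legitimately shift the refined gap.
      a_next <- substr(A, im$pos_a + 1L, im$pos_a + 1L)
      if (mid_v[i] == 0L) {
        if (substr(seqs[[im$chrom_b]], im$pos_b + 1L, im$pos_b + 1L) == a_next)
          substr(seqs[[im$chrom_b]], im$pos_b + 1L, im$pos_b + 1L) <-
            pick_diff(a_next)
        a_prev <- substr(A, im$pos_a - h, im$pos_a - h)
        if (substr(seqs[[im$chrom_b]], im$pos_b - h, im$pos_b - h) == a_prev)
          substr(seqs[[im$chrom_b]], im$pos_b - h, im$pos_b - h) <-
            pick_diff(a_prev)
      }
    }
    ## Pass 2: build reads from the final genome.
    for (i in seq_len(n_imp)) {
      im <- implants[i, ]
      mid <- mid_v[i]; h <- h_v[i]; la <- la_v[i]; lb <- lb_v[i]
      A <- seqs[[im$chrom_a]]; B <- seqs[[im$chrom_b]]
      a_part <- substr(A, im$pos_a - la + 1L, im$pos_a)
      b_part <- substr(B, im$pos_b + 1L, im$pos_b + lb)
      middle <- if (mid > 0L) {
        a_next <- substr(A, im$pos_a + 1L, im$pos_a + 1L)
        b_prev <- substr(B, im$pos_b, im$pos_b)
        mch <- sample(BASES, mid, replace = TRUE)
        if (mid == 1L) {
          mch[1] <- sample(setdiff(BASES, c(a_next, b_prev)), 1L)
        } else {
          if (mch[1] == a_next) mch[1] <- pick_diff(a_next)
          if (mch[mid] == b_prev) mch[mid] <- pick_diff(b_prev)
        }
        paste(mch, collapse = "")
      } else ""
      out_seq[i] <- paste0(a_part, middle, b_part)
      truth$junction_read_pos[i] <- la + mid
    }
    reads <- Biostrings::DNAStringSet(out_seq)
    names(reads) <- implants$read_id
    genome_out <- Biostrings::DNAStringSet(seqs)
    names(genome_out) <- names(genome)
    list(genome = genome_out, reads = reads, truth = truth)
  })
}

#' Configuration for a trio simulation
#'
#' @param n_reads Offspring reads to simulate.
#' @param read_length Read length in bases.
#' @param het_site_density Candidate variant sites per kilobase.
#' @param informative_fraction Fraction of sites where at least one parent
#'   carries a unique allele (parent-of-origin informative).
#' @param switch_rate_s Fraction of reads given exactly one mid-read
#'   maternal/paternal haplotype switch.
#' @param mutation_rate_m Fraction of reads given one non-parental allele
#'   at a covered site (disjoint from switches; `s + m` must be <= 1).
#' @param seed Integer seed.
#' @return A `trio_sim_config` list.
#' @export
trio_sim_config <- function(n_reads = 1000L, read_length = 300L,
                            het_site_density = 20, informative_fraction = 0.8,
                            switch_rate_s = 0.05, mutation_rate_m = 0,
                            seed = 1L) {
  if (switch_rate_s < 0 || mutation_rate_m < 0 ||
      switch_rate_s + mutation_rate_m > 1)
    stop("need s, m >= 0 and s + m <= 1 for unambiguous truth labels")
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 het_site_density = het_site_density,
                 informative_fraction = informative_fraction,
                 switch_rate_s = switch_rate_s,
                 mutation_rate_m = mutation_rate_m,
                 seed = as.integer(seed)),
            class = "trio_sim_config")
}

# Ordered parental genotype patterns over {ref, alt}; "R"/"A" alleles.
# Informative = at least one allele unique to one parent.
TRIO_INFORMATIVE_PATTERNS <- list(
  c("R/R", "A/A"), c("A/A", "R/R"), c("R/R", "R/A"), c("R/A", "R/R"),
  c("R/A", "A/A"), c("A/A", "R/A")
)
TRIO_UNINFORMATIVE_PATTERNS <- list(
  c("R/R", "R/R"), c("R/A", "R/A"), c("A/A", "A/A")
)

#' Simulate a trio: genotype sites, offspring reads and truth labels
#'
#' Variant sites are placed uniformly; parents receive genotypes so that a
#' configurable fraction of sites are informative. Offspring reads are
#' sampled from one parental haplotype; a fraction `s` of reads carries
#' exactly one haplotype switch placed between two adjacent covered
#' informative sites, and a disjoint fraction `m` carries one non-parental
#' allele at a covered site.
#'
#' @param genome Named `DNAStringSet`.
#' @param config A [trio_sim_config()].
#' @return A list with `sites` (trio genotype table as from
#'   [read_trio_vcf()]), `observations` (`read_id`, `chrom`, `pos`,
#'   `allele`, per covered site in read order), `reads` (named
#'   `DNAStringSet`) and `truth` (`read_id`, `label`, `switch_site_index`).
#' @export
simulate_trio <- function(genome, config) {
  stopifnot(inherits(config, "trio_sim_config"))
  genome <- Biostrings::DNAStringSet(genome)
  lens <- Biostrings::width(genome)
  seqs_chr <- as.character(genome)
  rl <- config$read_length
  with_sim_seed(config$seed, {
    ## --- sites ---
    site_list <- lapply(seq_along(genome), function(ci) {
      n_sites <- max(1L, round(lens[ci] / 1000 * config$het_site_density))
      pos <- sort(sample.int(lens[ci], min(n_sites, lens[ci]))) - 1L
      data.frame(chrom = names(genome)[ci], pos = pos, stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_list)
    sites$ref <- toupper(substring(seqs_chr[sites$chrom], sites$pos + 1L,
                                   sites$pos + 1L))
    sites <- sites[sites$ref %in% BASES, , drop = FALSE]
    sites$alt <- vapply(sites$ref, function(r) sample(setdiff(BASES, r), 1L),
                        character(1), USE.NAMES = FALSE)
    informative <- stats::runif(nrow(sites)) < config$informative_fraction
    pat <- vapply(informative, function(inf) {
      p <- if (inf) TRIO_INFORMATIVE_PATTERNS[[sample.int(6L, 1L)]]
      else TRIO_UNINFORMATIVE_PATTERNS[[sample.int(3L, 1L)]]
      paste(p, collapse = ";")
    }, character(1))
    to_alleles <- function(p, ref, alt) {
      a <- strsplit(p, "/", fixed = TRUE)[[1]]
      paste(ifelse(a == "R", ref, alt), collapse = "/")
    }
    pat2 <- strsplit(pat, ";", fixed = TRUE)
    sites$gt_mother <- mapply(function(p, r, a) to_alleles(p[1], r, a),
                              pat2, sites$ref, sites$alt, USE.NAMES = FALSE)
    sites$gt_father <- mapply(function(p, r, a) to_alleles(p[2], r, a),
                              pat2, sites$ref, sites$alt, USE.NAMES = FALSE)
    if (!any(informative)) stop("simulated trio has zero informative sites")
    ## transmitted haplotypes
    pick <- function(gt) vapply(strsplit(gt, "/", fixed = TRUE),
                                function(a) sample(a, 1L), character(1))
    sites$hap_m <- pick(sites$gt_mother)
    sites$hap_p <- pick(sites$gt_father)
    sites$gt_offspring <- paste(sites$hap_m, sites$hap_p, sep = "/")
    sites$informative <- informative
    # Doubly diagnostic: both transmitted alleles are unique to their
    # parent, so any read covering such a site is classifiable with
    # certainty and a haplotype switch between two of them is always
    # visible in the label sequence (truth labels = recoverable labels).
    fa_alleles <- strsplit(sites$gt_father, "/", fixed = TRUE)
    mo_alleles <- strsplit(sites$gt_mother, "/", fixed = TRUE)
    sites$doubly_diagnostic <- !mapply(`%in%`, sites$hap_m, fa_alleles) &
      !mapply(`%in%`, sites$hap_p, mo_alleles)
    rownames(sites) <- NULL
    ## per-chromosome site lookup
    by_chrom <- split(seq_len(nrow(sites)), sites$chrom)

    ## --- reads ---
    n <- config$n_reads
    u <- stats::runif(n)
    category <- ifelse(u < config$switch_rate_s, "allelic_switch",
                       ifelse(u < config$switch_rate_s + config$mutation_rate_m,
                              "mutated", "non_chimeric"))
    obs <- vector("list", n)
    read_seqs <- character(n)
    truth_switch <- rep(NA_integer_, n)
    ids <- sprintf("trioread%06d", seq_len(n))
    for (i in seq_len(n)) {
      cov_dd <- integer(0)
      for (try in 1:200) {
        ci <- sample.int(length(genome), 1L, prob = as.numeric(lens))
        start <- sample.int(lens[ci] - rl + 1L, 1L) - 1L
        idx <- by_chrom[[names(genome)[ci]]]
        cov <- idx[sites$pos[idx] >= start & sites$pos[idx] < start + rl]
        cov_dd <- cov[sites$doubly_diagnostic[cov]]
        if (length(cov_dd) >= 2L) break
      }
      if (length(cov_dd) < 2L)
        stop("could not place a read covering >= 2 doubly diagnostic sites; ",
             "increase het_site_density")
      parent0 <- sample(c("m", "p"), 1L)
      K <- length(cov)
      hap_col <- if (parent0 == "m") "hap_m" else "hap_p"
      alleles <- sites[[hap_col]][cov]
      if (category[i] == "allelic_switch") {
        # switch between two adjacent covered doubly diagnostic sites
        kdd <- match(cov_dd, cov)
        j <- kdd[sample.int(length(kdd) - 1L, 1L)]  # after j-th covered site
        other <- if (parent0 == "m") "hap_p" else "hap_m"
        later <- which(seq_len(K) > j)
        alleles[later] <- sites[[other]][cov][later]
        truth_switch[i] <- j
      } else if (category[i] == "mutated") {
        k <- match(sample(cov_dd, 1L), cov)
        par_alleles <- unique(unlist(strsplit(
          c(sites$gt_mother[cov[k]], sites$gt_father[cov[k]]), "/")))
        alleles[k] <- sample(setdiff(BASES, par_alleles), 1L)
      }
      s <- strsplit(substr(seqs_chr[ci], start + 1L, start + rl), "")[[1]]
      s[sites$pos[cov] - start + 1L] <- alleles
      read_seqs[i] <- paste(s, collapse = "")
      obs[[i]] <- data.frame(read_id = ids[i], chrom = names(genome)[ci],
                             pos = sites$pos[cov], allele = alleles,
                             stringsAsFactors = FALSE)
    }
    reads <- Biostrings::DNAStringSet(read_seqs)
    names(reads) <- ids
    list(
      sites = sites[, c("chrom", "pos", "ref", "alt", "gt_offspring",
                        "gt_mother", "gt_father", "informative")],
      observations = do.call(rbind, obs),
      reads = reads,
      truth = data.frame(read_id = ids, label = category,
                         switch_site_index = truth_switch,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Write the three VCFs of a simulated trio
#'
#' @param sites Site table from [simulate_trio()].
#' @param dir Output directory.
#' @return Character vector of the three paths (offspring, mother, father).
#' @export
write_trio_vcfs <- function(sites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("offspring.vcf", "mother.vcf", "father.vcf"))
  write_simple_vcf(sites, "offspring", paths[1], gt_col = "gt_offspring")
  write_simple_vcf(sites, "mother", paths[2], gt_col = "gt_mother")
  write_simple_vcf(sites, "father", paths[3], gt_col = "gt_father")
  paths
}

#' Simulate hemizygous X genotype observations under per-site mutation
#'
#' For a male offspring the X is maternally derived, so in the absence of
#' mutation every X observation matches the maternal allele. Each
#' observation is mutated to one of the three other bases with probability
#' `mutation_prob` (0.75 under the somatic-mutation model, giving an
#' expected maternal-consistent fraction of 0.25).
#'
#' @param n_obs Number of genotype observations.
#' @param mutation_prob Per-observation mutation probability.
#' @param seed Integer seed.
#' @return Data frame with `maternal` and `observed` alleles.
#' @export
simulate_hemizygous_x <- function(n_obs, mutation_prob = 0.75, seed = 1L) {
  with_sim_seed(seed, {
    maternal <- sample(BASES, n_obs, replace = TRUE)
    observed <- maternal
    hit <- which(stats::runif(n_obs) < mutation_prob)
    for (i in hit) observed[i] <- sample(setdiff(BASES, maternal[i]), 1L)
    data.frame(maternal = maternal, observed = observed,
               stringsAsFactors = FALSE)
  })
}
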