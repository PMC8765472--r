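# Interallelic (homologous-chromosome) chimera detection from trio
# genotypes: informative sites, parent-of-origin read labels with a
# single-switch rule, somatic-mutation-rate estimation, and the corrected
# recombination frequency.

# Two-allele somatic mutation model: any base mutates to one of the three
# others with probability MUT_P_ALLELE per allele, so a diploid genotype is
# unexpected with probability MUT_P_ALLELE^2 and a hemizygous observation
# still matches the inherited allele with probability 1 - MUT_P_ALLELE.
MUT_P_ALLELE <- 0.75

#' Select parent-of-origin informative sites
#'
#' A site is informative when at least one parent carries an allele absent
#' from the other parent's genotype; such diagnostic alleles permit
#' maternal/paternal assignment of a read allele. Alleles shared by both
#' parents are ambiguous; alleles in neither parent are non-parental.
#'
#' @param sites Trio genotype table (from [read_trio_vcf()] or
#'   [simulate_trio()]): `chrom`, `pos`, `gt_mother`, `gt_father` at
#'   minimum.
#' @return `sites` with added columns `informative` (logical),
#'   `maternal_only` and `paternal_only` (comma-joined diagnostic
#'   alleles). Sites with missing parental genotypes are dropped with a
#'   count in attribute `n_skipped`.
#' @export
select_informative_sites <- function(sites) {
  ok <- !is.na(sites$gt_mother) & !is.na(sites$gt_father)
  n_skipped <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  mo <- strsplit(sites$gt_mother, "/", fixed = TRUE)
  fa <- strsplit(sites$gt_father, "/", fixed = TRUE)
  sites$maternal_only <- mapply(function(m, f)
    paste(setdiff(m, f), collapse = ","), mo, fa)
  sites$paternal_only <- mapply(function(m, f)
    paste(setdiff(f, m), collapse = ","), mo, fa)
  sites$informative <- sites$maternal_only != "" | sites$paternal_only != ""
  rownames(sites) <- NULL
  attr(sites, "n_skipped") <- n_skipped
  sites
}

# Label one allele at one informative site: M / P / ambiguous / non_parental
label_allele <- function(allele, gt_mother, gt_father) {
  m <- strsplit(gt_mother, "/", fixed = TRUE)[[1]]
  f <- strsplit(gt_father, "/", fixed = TRUE)[[1]]
  in_m <- allele %in% m
  in_f <- allele %in% f
  if (in_m && in_f) "ambiguous"
  else if (in_m) "M"
  else if (in_f) "P"
  else "non_parental"
}

#' Label offspring reads as maternal, paternal or interallelic chimera
#'
#' Each read's allele observations at informative sites are mapped to
#' maternal (M), paternal (P), ambiguous or non-parental labels. A read
#' with any non-parental allele is `eliminated_mutated` (sporadic mutation
#' or sequencing error). Otherwise, ambiguous labels are skipped and the
#' M/P sequence is classified by its number of transitions: 0 =
#' `maternal`/`paternal`, 1 = `interallelic_chimera` (with the switch
#' index), 2+ = `eliminated_multiswitch`. Reads with no usable label are
#' `uninformative`.
#'
#' @param observations Data frame `read_id`, `chrom`, `pos`, `allele`
#'   (read-order observations at variant sites).
#' @param sites Informative-site table from [select_informative_sites()].
#' @return A data frame with one row per read: `read_id`, `class`,
#'   `n_sites` (informative sites covered), `switch_index` (position of
#'   the single M-P transition among the read's M/P labels, chimeras
#'   only) and `labels` (the concatenated label string).
#' @export
label_reads <- function(observations, sites) {
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(observations$chrom, observations$pos), key)
  keep <- !is.na(idx)
  keep[keep] <- sites$informative[idx[keep]]
  obs <- observations[keep, , drop = FALSE]
  idx <- idx[keep]
  lab <- vapply(seq_len(nrow(obs)), function(i)
    label_allele(obs$allele[i], sites$gt_mother[idx[i]],
                 sites$gt_father[idx[i]]), character(1))
  all_ids <- unique(observations$read_id)
  per_read <- split(lab, factor(obs$read_id, levels = all_ids))
  res <- lapply(all_ids, function(id) {
    labels <- per_read[[id]]
    if (length(labels) == 0L) {
      return(data.frame(read_id = id, class = "uninformative", n_sites = 0L,
                        switch_index = NA_integer_, labels = "",
                        stringsAsFactors = FALSE))
    }
    row <- data.frame(read_id = id, class = "uninformative",
                      n_sites = length(labels),
                      switch_index = NA_integer_,
                      labels = paste(labels, collapse = ""),
                      stringsAsFactors = FALSE)
    if (any(labels == "non_parental")) {
      row$class <- "eliminated_mutated"
      return(row)
    }
    mp <- labels[labels %in% c("M", "P")]
    if (length(mp) == 0L) return(row)  # ambiguous-only: uninformative
    transitions <- sum(mp[-1] != mp[-length(mp)])
    row$class <- if (transitions == 0L) {
      if (mp[1] == "M") "maternal" else "paternal"
    } else if (transitions == 1L) {
      row$switch_index <- which(mp[-1] != mp[-length(mp)])[1]
      "interallelic_chimera"
    } else "eliminated_multiswitch"
    row
  })
  do.call(rbind, res)
}

#' Estimate the somatic mutation rate from labeled reads
#'
#' The rate is computed per read: the fraction of genotype-comparable
#' reads (at least one observation at an informative site) that carry at
#' least one allele found in neither parent. The independence-model
#' constants are attached for reporting: 0.75 per allele, 0.5625
#' (75% of 75%) for a diploid genotype, 0.25 expected maternal-consistent
#' fraction at a hemizygous locus.
#'
#' @param labeled Read-label data frame from [label_reads()].
#' @return A list with `reads_compared`, `reads_unexpected`, `rate`,
#'   `model_p_allele`, `model_p_biallelic`,
#'   `model_p_hemizygous_expected`.
#' @export
estimate_mutation_rate <- function(labeled) {
  compared <- labeled$n_sites > 0L
  if (!any(compared)) stop("no genotype-comparable reads")
  unexpected <- sum(labeled$class == "eliminated_mutated")
  list(
    reads_compared = sum(compared),
    reads_unexpected = unexpected,
    rate = unexpected / sum(compared),
    model_p_allele = MUT_P_ALLELE,
    model_p_biallelic = MUT_P_ALLELE^2,
    model_p_hemizygous_expected = 1 - MUT_P_ALLELE
  )
}

#' Interallelic chimera frequency, raw and mutation-corrected
#'
#' The raw percentage is the share of classifiable reads (maternal +
#' paternal + chimera) showing a single allelic switch. Because roughly
#' the mutation-rate fraction of apparent recombinations is attributable
#' to somatic mutation or sequencing error, the corrected percentage
#' deflates the raw one: corrected = raw * (1 - mutation_rate).
#'
#' @param labeled Read-label data frame from [label_reads()], or `NULL`
#'   when counts are given directly.
#' @param mutation_rate Somatic mutation rate in [0, 1].
#' @param counts Optional list with `chimera`, `maternal`, `paternal`
#'   counts, overriding `labeled`.
#' @param compartment Label carried through to the output (e.g.
#'   "autosomes", "chrX").
#' @return A list with `n_maternal`, `n_paternal`, `n_chimera`,
#'   `n_classifiable`, `raw_percent` and `corrected_percent` (2 decimals).
#' @export
recombination_frequency <- function(labeled = NULL, mutation_rate = 0,
                                    counts = NULL,
                                    compartment = "autosomes") {
  if (is.null(counts)) {
    counts <- list(
      chimera = sum(labeled$class == "interallelic_chimera"),
      maternal = sum(labeled$class == "maternal"),
      paternal = sum(labeled$class == "paternal")
    )
  }
  total <- counts$maternal + counts$paternal + counts$chimera
  if (total <= 0) stop("no classifiable reads")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  raw <- counts$chimera / total * 100
  list(
    compartment = compartment,
    n_maternal = counts$maternal,
    n_paternal = counts$paternal,
    n_chimera = counts$chimera,
    n_classifiable = total,
    raw_percent = round(raw, 2),
    corrected_percent = round(raw * (1 - mutation_rate), 2)
  )
}

#' Maternal-consistent fraction of hemizygous X observations
#'
#' For a male offspring the X chromosome is maternally derived, so every
#' X genotype observation should match the maternal allele; under the
#' somatic-mutation model with per-allele mutation probability 0.75 the
#' expected maternal-consistent fraction is 0.25.
#'
#' @param observations Data frame with `maternal` and `observed` allele
#'   columns (e.g. from [simulate_hemizygous_x()]).
#' @return A list with `n_observations`, `fraction_maternal` and the
#'   model expectation.
#' @export
hemizygous_check <- function(observations) {
  if (nrow(observations) == 0L) stop("no X-chromosome observations")
  frac <- mean(observations$observed == observations$maternal)
  list(n_observations = nrow(observations),
       fraction_maternal = frac,
       model_expected = 1 - MUT_P_ALLELE)
}
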