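test_that("events-per-billion reproduces published sample arithmetic", {
  expect_equal(events_per_billion(16131, 7363547914), 2190.66)
  expect_equal(events_per_billion(19074, 5950672728), 3205.35)
  expect_equal(events_per_billion(0, 123456), 0)
  expect_error(events_per_billion(10, 0), "positive")
  # rate linearity
  expect_equal(events_per_billion(7 * 8633, 7 * 8003273001),
               events_per_billion(8633, 8003273001))
})

test_that("sample summaries compute mapped percent and mean read length", {
  ss <- sample_summary(total_reads = 3466514, total_bases = 7363547914,
                       reads_mapped = 2686403, aub_events = 16131)
  expect_equal(ss$pct_mapped, 77.50)
  expect_equal(ss$mean_read_length, 2124.19)
  expect_equal(ss$events_per_billion_bases, 2190.66)
  expect_equal(rate_fold_change(1727.77, 1217.64), 1.4)
})

test_that("non-chimeric support counts reads near either junction flank", {
  events <- data.frame(
    read_id = "ev1", chrom_a = "c1", chrom_b = "c2",
    a_start = 1000L, a_end = 1200L, b_start = 5000L, b_end = 5200L,
    stringsAsFactors = FALSE)
  aln <- data.frame(
    read_id = c("n1", "n1", "n2", "n3", "n4", "chim"),
    bin = 1L, read_start = 0L, read_end = 200L, status = "unique",
    chrom = c("c1", "c1", "c1", "c2", "c1", "c1"),
    pos = c(900L, 1100L, 1150L, 5100L, 9000L, 1100L),
    strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  classes <- data.frame(
    read_id = c("n1", "n2", "n3", "n4", "chim"),
    label = c("non_chimeric", "non_chimeric", "non_chimeric", "non_chimeric",
              "aub_chimeric"), stringsAsFactors = FALSE)
  # n1 and n2 overlap the A flank, n3 the B flank; n4 is far away and the
  # chimeric read itself never counts
  sup <- nonchimeric_support(events, aln, classes, window = 200L)
  expect_equal(sup$support, 3L)
  expect_equal(sup$median, 3L)

  far <- events; far$a_start <- 20000L; far$a_end <- 20200L
  far$b_start <- 30000L; far$b_end <- 30200L
  expect_equal(nonchimeric_support(far, aln, classes, window = 200L)$support, 0L)
})

test_that("repeat annotation picks the class with the largest overlap", {
  repeats <- data.frame(
    chrom = c("c1", "c1", "c2"),
    start = c(1000L, 1150L, 0L),
    end = c(1050L, 1400L, 9000L),
    name = c("SINE/AluY", "LINE/L1PA", "LINE/L1M"),
    strand = ".", stringsAsFactors = FALSE)
  events <- data.frame(
    read_id = c("e1", "e2", "e3"),
    chrom_a = c("c1", "c3", "c2"), chrom_b = c("c3", "c4", "c3"),
    a_start = c(1000L, 100L, 100L), a_end = c(1200L, 300L, 300L),
    b_start = c(100L, 500L, 500L), b_end = c(300L, 700L, 700L),
    stringsAsFactors = FALSE)
  ann <- annotate_repeats(events, repeats)
  # e1: Alu overlap 50, L1PA overlap 50 -> tie broken alphabetically,
  # then the A footprint [1000,1200) hits Alu 50 and L1PA 50
  expect_equal(ann$per_event$primary_class[1], "LINE/L1PA")
  expect_equal(ann$per_event$primary_class[2], "repeat_free")
  expect_equal(ann$per_event$primary_class[3], "LINE/L1M")
  expect_equal(sum(ann$fractions), 100)

  expect_error(annotate_repeats(events, repeats, genome_chroms = c("c1", "c3")),
               "c2")
})

test_that("composition statistics follow their definitions", {
  g4 <- composition("GGGG")
  expect_equal(g4$gc_skew, 1)
  expect_equal(g4$gc_percent, 100)

  gcgc <- composition("GCGC")
  expect_equal(gcgc$gc_skew, 0)
  expect_equal(gcgc$cpg_percent, 33.33)  # 1 CG / 3 dinucleotide positions

  atat <- composition("ATAT")
  expect_equal(atat$gc_percent, 0)
  expect_equal(atat$gc_skew, 0)  # G+C = 0 convention

  expect_error(composition(""), "empty")

  # reverse complement: gc preserved, skew negated
  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(composition(s)$gc_percent, composition(rc)$gc_percent)
    expect_equal(composition(s)$gc_skew, -composition(rc)$gc_skew)
  }
})

test_that("chromosome-pair counts track chromosome length", {
  lens <- c(cA = 50000L, cB = 100000L, cC = 150000L, cD = 200000L,
            cE = 250000L, cF = 300000L)
  set.seed(17)
  n <- 3000L
  pick2 <- t(replicate(n, sample(names(lens), 2L, prob = as.numeric(lens))))
  events <- data.frame(read_id = sprintf("e%d", 1:n),
                       chrom_a = pick2[, 1], chrom_b = pick2[, 2],
                       stringsAsFactors = FALSE)
  cp <- chromosome_pair_matrix(events, lens)
  expect_true(isSymmetric(cp$pair_matrix))
  expect_gt(cp$r, 0.9)
  expect_lt(cp$p, 0.05)

  one <- data.frame(read_id = "e", chrom_a = "cA", chrom_b = "cB")
  m1 <- chromosome_pair_matrix(one, lens)$pair_matrix
  expect_equal(sum(m1 > 0), 2L)  # the cell and its mirror
  expect_equal(m1["cA", "cB"], m1["cB", "cA"])

  expect_true(is.na(chromosome_pair_matrix(one, lens[1:2])$r))
})

test_that("X-U-A accounting reproduces the published observed/expected split", {
  kd <- list(reads_mapped = 80980111, reads_mapped_x = 2263810,
             xua_events = 1625, total_events = 30298)
  ct <- list(reads_mapped = 67725152, reads_mapped_x = 3230110,
             xua_events = 1458, total_events = 18809)
  sx <- sex_chromosome_accounting(test = kd, reference = ct)
  expect_equal(sx$observed_ref, 7.75)
  expect_equal(sx$observed_test, 5.36)
  expect_equal(sx$expected_test, 3.14)

  # equal X representation -> expected equals observed
  same <- sex_chromosome_accounting(test = ct, reference = ct)
  expect_equal(same$expected_test, same$observed_test)

  expect_error(sex_chromosome_accounting(
    test = list(reads_mapped = 10, reads_mapped_x = 1, xua_events = 0,
                total_events = 0),
    reference = ct), "zero totals")
})

test_that("gap histograms are percentages that partition by junction type", {
  all0 <- gap_distribution(rep(0L, 40))
  expect_equal(nrow(all0), 1L)
  expect_equal(all0$percent, 100)

  set.seed(23)
  hom <- -sample(21:60, 500, replace = TRUE)
  ins <- sample(1:50, 300, replace = TRUE)
  gaps <- c(hom, rep(0L, 200), ins)
  gd <- gap_distribution(gaps, bin_width = 5L)
  expect_equal(sum(gd$percent), 100)
  # mass below zero equals the dual fraction exactly
  expect_equal(sum(gd$percent[gd$gap_bin < 0]), length(hom) / length(gaps) * 100)
  # uniform homology lengths: flat negative flank within sampling error
  neg <- gap_distribution(hom, bin_width = 10L)
  chi <- suppressWarnings(stats::chisq.test(neg$count))
  expect_gt(chi$p.value, 0.001)
})

test_that("gene-body coverage compares observed placement against shuffles", {
  lens <- c(c1 = 50000L, c2 = 50000L)
  tx <- data.frame(chrom = rep(c("c1", "c2"), each = 10),
                   start = rep(seq(0L, 45000L, by = 5000L), 2),
                   end = rep(seq(0L, 45000L, by = 5000L), 2) + 2500L,
                   name = sprintf("tx%02d", 1:20), strand = "+")
  # uniformly placed events: observed within the shuffle distribution
  set.seed(31)
  ev_u <- data.frame(chrom = sample(names(lens), 60, replace = TRUE),
                     start = sample(0:49500, 60))
  ev_u$end <- ev_u$start + 200L
  gc_u <- gene_body_coverage(ev_u, tx, lens, n_shuffles = 20L, seed = 5L)
  spread <- stats::sd(gc_u$per_shuffle)
  # observed is a single draw from the same placement distribution: allow
  # 3 SD plus a 2-count discreteness margin
  expect_lt(abs(gc_u$observed - gc_u$expected), 3 * spread + 2)

  # transcript-avoiding events: observed 0, expected > 0 (depletion)
  gap_starts <- seq(2600L, 42600L, by = 5000L)  # inside the 2.5 kb gaps
  ev_a <- data.frame(chrom = rep("c1", length(gap_starts)),
                     start = gap_starts, end = gap_starts + 100L)
  gc_a <- gene_body_coverage(ev_a, tx, lens, n_shuffles = 20L, seed = 6L)
  expect_equal(gc_a$observed, 0L)
  expect_gt(gc_a$expected, 0)

  # zero events -> observed = expected = 0
  gc_0 <- gene_body_coverage(ev_u[0, ], tx, lens, seed = 7L)
  expect_equal(gc_0$observed, 0L)
  expect_equal(gc_0$expected, 0)

  # seed reproducibility and n_normalized downsampling warning
  gc_r <- gene_body_coverage(ev_u, tx, lens, n_shuffles = 20L, seed = 5L)
  expect_identical(gc_r$per_shuffle, gc_u$per_shuffle)
  expect_warning(gene_body_coverage(ev_u, tx, lens, n_normalized = 1000L,
                                    seed = 8L), "exceeds")
})
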