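test_that("informative sites are those with a parent-unique allele", {
  info <- select_informative_sites(phasing_sites())
  # A/A vs G/G: both alleles diagnostic
  expect_true(info$informative[1])
  expect_equal(info$maternal_only[1], "A")
  expect_equal(info$paternal_only[1], "G")
  # C/C vs C/T: T unique to father, C shared
  expect_true(info$informative[2])
  expect_equal(info$maternal_only[2], "")
  expect_equal(info$paternal_only[2], "T")
  # G/A vs G/G: A unique to mother
  expect_true(info$informative[3])
  expect_equal(info$maternal_only[3], "A")

  # both parents share all alleles -> non-informative
  shared <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                       gt_mother = "A/G", gt_father = "A/G")
  expect_false(select_informative_sites(shared)$informative)

  # missing parental genotype -> dropped and counted
  miss <- phasing_sites()
  miss$gt_father[2] <- NA
  out <- select_informative_sites(miss)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("read labeling applies the single-switch and elimination rules", {
  info <- select_informative_sites(phasing_sites())
  # site 100: A=M, G=P; site 300: A=M, G ambiguous; site 400: C=P, T ambiguous
  obs <- rbind(
    obs_row("mat", c(100L, 300L), c("A", "A")),             # M,M -> maternal
    obs_row("chim", c(100L, 300L, 400L), c("A", "A", "C")), # M,M,P -> chimera
    obs_row("multi", c(100L, 400L, 300L), c("A", "C", "A")),  # M,P,M
    obs_row("mut", c(100L, 300L), c("A", "T")),             # T non-parental
    obs_row("amb", c(300L, 400L), c("G", "T")),             # all ambiguous
    obs_row("none", 999L, "A")                              # no informative site
  )
  lab <- label_reads(obs, info)
  lab <- lab[match(c("mat", "chim", "multi", "mut", "amb", "none"),
                   lab$read_id), ]
  expect_equal(lab$class[1], "maternal")
  expect_equal(lab$class[2], "interallelic_chimera")
  expect_equal(lab$switch_index[2], 2L)
  expect_equal(lab$class[3], "eliminated_multiswitch")
  expect_equal(lab$class[4], "eliminated_mutated")
  expect_equal(lab$class[5], "uninformative")  # ambiguous alleles carry no signal
  expect_equal(lab$class[6], "uninformative")

  # classification partition over processed reads
  expect_equal(nrow(lab), length(unique(obs$read_id)))
})

test_that("the two-allele mutation model constants are as published", {
  lab <- data.frame(read_id = "r", class = "maternal", n_sites = 1L)
  mr <- estimate_mutation_rate(lab)
  expect_equal(mr$model_p_allele, 0.75)
  expect_equal(mr$model_p_biallelic, 0.5625)
  expect_equal(round(mr$model_p_biallelic * 100), 56)  # "about 56%"
  expect_equal(mr$model_p_hemizygous_expected, 0.25)
})

test_that("recombination frequencies reproduce all published count pairs", {
  # autosomes, control: 75879 chimeric of 4,506,012 classifiable
  ct_auto <- recombination_frequency(
    counts = list(chimera = 75879, maternal = 2053554, paternal = 2376579),
    mutation_rate = 0.5908)
  expect_equal(ct_auto$n_classifiable, 4506012)
  expect_equal(ct_auto$raw_percent, 1.68)
  expect_equal(ct_auto$corrected_percent, 0.69)

  kd_auto <- recombination_frequency(
    counts = list(chimera = 108513, maternal = 940277, paternal = 1002715),
    mutation_rate = 0.5266)
  expect_equal(kd_auto$raw_percent, 5.29)
  expect_equal(kd_auto$corrected_percent, 2.50)

  ct_x <- recombination_frequency(
    counts = list(chimera = 2244, maternal = 91118, paternal = 71182),
    mutation_rate = 0.5908, compartment = "chrX")
  expect_equal(ct_x$raw_percent, 1.36)
  expect_equal(ct_x$corrected_percent, 0.56)

  kd_x <- recombination_frequency(
    counts = list(chimera = 2083, maternal = 20649, paternal = 11238),
    mutation_rate = 0.5266, compartment = "chrX")
  expect_equal(kd_x$raw_percent, 6.13)
  expect_equal(kd_x$corrected_percent, 2.90)

  expect_error(recombination_frequency(
    counts = list(chimera = 0, maternal = 0, paternal = 0)), "classifiable")
})

test_that("correction never exceeds the raw frequency", {
  for (rate in c(0, 0.25, 0.5, 0.99)) {
    rf <- recombination_frequency(
      counts = list(chimera = 100, maternal = 5000, paternal = 5000),
      mutation_rate = rate)
    expect_lte(rf$corrected_percent, rf$raw_percent)
    if (rate == 0) expect_equal(rf$corrected_percent, rf$raw_percent)
  }
})

test_that("simulated switch and mutation rates are recovered", {
  cfg <- sim_genome_config(c(chr1 = 40000L, chr2 = 40000L), seed = 41L)
  g <- make_genome(cfg)
  s <- 0.04; m <- 0.30; n <- 2000L
  tr <- simulate_trio(g$genome, trio_sim_config(
    n_reads = n, read_length = 300L, het_site_density = 25,
    switch_rate_s = s, mutation_rate_m = m, seed = 42L))
  info <- select_informative_sites(tr$sites)
  lab <- label_reads(tr$observations, info)

  # labeling recovers the truth exactly in noise-free observations
  tt <- table(tr$truth$label)
  expect_equal(sum(lab$class == "interallelic_chimera"),
               unname(tt["allelic_switch"]))
  expect_equal(sum(lab$class == "eliminated_mutated"), unname(tt["mutated"]))

  mr <- estimate_mutation_rate(lab)
  expect_lt(abs(mr$rate - m), 3 * sqrt(m * (1 - m) / n))
  rf <- recombination_frequency(lab, mutation_rate = mr$rate)
  # corrected percent estimates s (raw estimates s / (1 - m)); the
  # estimate's denominator is the classifiable-read count
  expect_lt(abs(rf$corrected_percent - s * 100),
            3 * sqrt(s * (1 - s) / rf$n_classifiable) * 100)
})

test_that("swapping parents swaps labels but conserves chimera calls", {
  cfg <- sim_genome_config(c(chr1 = 40000L), seed = 51L)
  g <- make_genome(cfg)
  tr <- simulate_trio(g$genome, trio_sim_config(
    n_reads = 400L, het_site_density = 25, switch_rate_s = 0.1,
    mutation_rate_m = 0.1, seed = 52L))
  info <- select_informative_sites(tr$sites)
  lab <- label_reads(tr$observations, info)

  swapped <- tr$sites
  tmp <- swapped$gt_mother
  swapped$gt_mother <- swapped$gt_father
  swapped$gt_father <- tmp
  lab_sw <- label_reads(tr$observations, select_informative_sites(swapped))

  expect_equal(sum(lab$class == "maternal"), sum(lab_sw$class == "paternal"))
  expect_equal(sum(lab$class == "paternal"), sum(lab_sw$class == "maternal"))
  expect_equal(sum(lab$class == "interallelic_chimera"),
               sum(lab_sw$class == "interallelic_chimera"))
})

test_that("hemizygous X observations recover the per-allele mutation model", {
  # mutation probability 0 -> all observations maternal
  h0 <- hemizygous_check(simulate_hemizygous_x(500L, 0, seed = 61L))
  expect_equal(h0$fraction_maternal, 1)
  # mutation probability 1 -> none maternal
  h1 <- hemizygous_check(simulate_hemizygous_x(500L, 1, seed = 62L))
  expect_equal(h1$fraction_maternal, 0)
  # model rate 0.75 -> ~25% maternal-consistent
  hm <- hemizygous_check(simulate_hemizygous_x(5000L, 0.75, seed = 63L))
  expect_lt(abs(hm$fraction_maternal - 0.25), 3 * sqrt(0.25 * 0.75 / 5000))
  expect_error(hemizygous_check(data.frame(maternal = character(0),
                                           observed = character(0))),
               "no X")
})
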