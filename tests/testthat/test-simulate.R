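test_that("DH recombinant fraction matches the Haldane closed form", {
  m <- sim_map(tibble::tibble(chromosome = "1A", length_cM = 10),
               tibble::tibble(marker_id = c("a", "b"), chromosome = "1A",
                              pos_cM = c(0, 10)))
  s <- simulate_biparental(m, "DH", 2000, seed = 4, missing_rate = 0,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  pat <- as_seg_patterns(s$geno)
  est <- estimate_recfrac(unlist(pat[1, -1]), unlist(pat[2, -1]), "DH")
  r_true <- haldane_r(10)  # 0.0906
  se <- sqrt(r_true * (1 - r_true) / 2000)
  expect_lt(abs(est$r - r_true), 3 * se)
  expect_equal(s$truth$adjacent_r$r_true, r_true)
})

test_that("doubled haploids carry no heterozygous calls at codominant markers", {
  s <- simulate_biparental(sim_map_regular(1, 50, 20), "DH", 80, seed = 5,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  expect_false(any(as.matrix(s$geno[, -1]) == "AB"))
})

test_that("selfing designs reach the expected residual heterozygosity", {
  m1 <- sim_map(tibble::tibble(chromosome = "1A", length_cM = 1),
                tibble::tibble(marker_id = "m1", chromosome = "1A", pos_cM = 0.5))
  s <- simulate_biparental(m1, "SSD_F5", 4000, seed = 6, missing_rate = 0,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  het <- mean(as.matrix(s$geno[, -1]) == "AB")
  se <- sqrt(0.0625 * (1 - 0.0625) / 4000)
  expect_lt(abs(het - 0.0625), 3 * se)
  expect_equal(cross_design("SSD_F5")$expected_het_fraction, 0.5^4)
  expect_equal(cross_design("RIL_F6")$expected_het_fraction, 0.5^5)
  expect_equal(cross_design("RIL_F7")$expected_het_fraction, 0.5^6)
  expect_equal(cross_design("DH")$expected_het_fraction, 0)
})

test_that("the same seed reproduces simulations bit-identically", {
  m <- sim_map_regular(2, 80, 15)
  a <- simulate_biparental(m, "RIL_F6", 40, seed = 7)
  b <- simulate_biparental(m, "RIL_F6", 40, seed = 7)
  expect_identical(a, b)

  groups <- tibble::tibble(name = c("x", "y"), n = c(10, 12), fst = c(0.1, 0.2))
  c1 <- simulate_collections(groups, 100, seed = 8)
  c2 <- simulate_collections(groups, 100, seed = 8)
  expect_identical(c1, c2)

  ev <- tibble::tibble(sample_id = "x_001", chromosome = "1A",
                       start_cM = NA, end_cM = NA, copy_state = 1)
  i1 <- simulate_intensities(c1$geno, c1$info, ev, seed = 9)
  i2 <- simulate_intensities(c2$geno, c2$info, ev, seed = 9)
  expect_identical(i1, i2)
})

test_that("seed is mandatory for every stochastic generator", {
  m <- sim_map_regular(1, 50, 5)
  expect_error(simulate_biparental(m, "DH", 10), "seed")
  expect_error(simulate_collections(tibble::tibble(name = "a", n = 5, fst = 0), 10),
               "seed")
})

test_that("viability selection distorts segregation towards the favoured parent", {
  m <- sim_map(tibble::tibble(chromosome = "1A", length_cM = 50),
               tibble::tibble(marker_id = sprintf("m%d", 1:5), chromosome = "1A",
                              pos_cM = seq(0, 50, length.out = 5)),
               distortion = tibble::tibble(chromosome = "1A", pos_cM = 25,
                                           s = 0.6, favoured = "P2"))
  s <- simulate_biparental(m, "DH", 400, seed = 10, missing_rate = 0,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  mid <- as.matrix(s$geno[3, -1])
  expect_gt(mean(mid == "BB"), 0.55)  # expected 1/(1.4) ~ 0.714
})

test_that("structured collections honour Balding-Nichols structure and genome multipliers", {
  groups <- tibble::tibble(name = c("g1", "g2"), n = c(40, 40), fst = c(0, 0))
  sim <- simulate_collections(groups, 600, seed = 11,
                              genome_multiplier = c(A = 1, B = 1, D = 0.5),
                              missing_rate = 0)
  freq <- allele_frequencies(sim$geno, sim$partition)
  # F = 0: group frequencies track the pooled frequency
  wide <- tidyr::pivot_wider(freq[, c("marker_id", "collection", "p")],
                             names_from = "collection", values_from = "p")
  expect_lt(mean(abs(wide$g1 - wide$.pooled), na.rm = TRUE), 0.06)
  # D-genome multiplier < 1 depresses D-genome MAF by construction
  byg <- maf_by_genome(freq, sim$info)
  d <- byg[byg$genome == "D", ]$mean_MAF
  a <- byg[byg$genome == "A", ]$mean_MAF
  expect_true(all(d < a))
  # truth record stores frequencies in [0, 1]
  expect_true(all(sim$truth$group_freq >= 0 & sim$truth$group_freq <= 1))
})

test_that("intensity simulation scales with copy state and respects the floor", {
  groups <- tibble::tibble(name = "t", n = 6, fst = 0)
  sim <- simulate_collections(groups, 1260, seed = 12, missing_rate = 0)
  ev <- tibble::tibble(sample_id = c("t_001", "t_002"),
                       chromosome = c("1A", "1B"),
                       start_cM = NA_real_, end_cM = NA_real_,
                       copy_state = c(1, 0))
  intens <- simulate_intensities(sim$geno, sim$info, ev, noise_sd = 0.1, seed = 13)
  expect_equal(length(attr(intens, "reference_samples")), 25L)

  # unaffected sample: per-marker Log2R centred on zero
  prof_normal <- log2r_profile(intens, sim$info, "t_003", center = FALSE)
  expect_lt(abs(median(prof_normal$log2r)), 0.05)

  # monosomic chromosome: median Log2R within 0.05 of log2(1/2)
  prof_mono <- log2r_profile(intens, sim$info, "t_001", center = FALSE)
  med <- median(prof_mono$log2r[prof_mono$chromosome == "1A"])
  expect_lt(abs(med - (-1)), 0.05)

  # nullisomic with vanishing noise pegs at the configured floor
  intens0 <- simulate_intensities(sim$geno, sim$info, ev, noise_sd = 1e-4, seed = 14)
  prof_null <- log2r_profile(intens0, sim$info, "t_002", center = FALSE)
  null_vals <- prof_null$log2r[prof_null$chromosome == "1B"]
  expect_true(all(null_vals >= -5 & null_vals < -4.9))

  # an event region containing no markers is an error
  bad <- tibble::tibble(sample_id = "t_001", chromosome = "1A",
                        start_cM = 1e5, end_cM = 1e5 + 1, copy_state = 1)
  expect_error(simulate_intensities(sim$geno, sim$info, bad, seed = 15),
               "no markers")
})
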