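# Independent brute-force binning oracle: first-fit over explicit pairwise
# comparisons on the raw pattern vectors.
oracle_bins <- function(patterns) {
  m <- as.matrix(patterns[, -1])
  rownames(m) <- patterns$marker_id
  compat <- function(i, j) {
    co <- m[i, ] != "NC" & m[j, ] != "NC"
    sum(co) > 0 && all(m[i, co] == m[j, co])
  }
  bins <- list()
  for (i in seq_len(nrow(m))) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      if (all(vapply(bins[[b]], function(j) compat(i, j), TRUE))) {
        bins[[b]] <- c(bins[[b]], i); placed <- TRUE; break
      }
    }
    if (!placed) bins[[length(bins) + 1]] <- i
  }
  member <- integer(nrow(m))
  for (b in seq_along(bins)) member[bins[[b]]] <- b
  member
}

test_that("missing-data filter removes strictly above the threshold", {
  calls <- rbind(rep(c("AA", "NC"), c(79, 21)),
                 rep(c("AA", "NC"), c(80, 20)),
                 rep("AB", 100))
  g <- pattern_tbl(calls, ids = c("over", "boundary", "full"))
  names(g)[1] <- "marker_id"
  kept <- filter_missing(g, 0.2)
  expect_equal(kept$marker_id, c("boundary", "full"))
  complete <- random_geno(10, 10, seed = 30, missing = 0)
  expect_identical(filter_missing(complete), complete)
})

test_that("binning groups identical patterns and separates any co-called mismatch", {
  base <- sample(c("P1", "P2"), 60, replace = TRUE)
  m <- rbind(base, base, base)
  m[3, 17] <- ifelse(base[17] == "P1", "P2", "P1")
  pat <- pattern_tbl(m, ids = c("a", "b", "c"))
  bins <- bin_markers(pat)
  expect_equal(bins$bin_id[1], bins$bin_id[2])
  expect_false(bins$bin_id[3] == bins$bin_id[1])
  # representative is the member with fewest no-calls, ties by id
  m2 <- rbind(base, replace(base, 1, "NC"))
  b2 <- bin_markers(pattern_tbl(m2, ids = c("z", "a")))
  expect_equal(b2$marker_id[b2$representative], "z")
})

test_that("binning equals the O(n^2) brute-force partition on random patterns", {
  set.seed(31)
  for (rep in 1:3) {
    templates <- matrix(sample(c("P1", "P2"), 8 * 40, replace = TRUE), 8)
    pick <- sample.int(8, 30, replace = TRUE)
    m <- templates[pick, ]
    m[matrix(runif(length(m)) < 0.15, nrow(m))] <- "NC"
    pat <- pattern_tbl(m, ids = sprintf("mk%02d", 1:30))
    got <- bin_markers(pat)
    want <- oracle_bins(pat)
    # same partition up to bin relabelling
    expect_equal(got$bin_id, want)
  }
})

test_that("two-point estimators match their closed forms", {
  a <- c(rep("P1", 8), rep("P2", 2))
  b <- c(rep("P1", 6), rep("P2", 4))  # discordant at 4 of 10
  dh <- estimate_recfrac(a, b, "DH")
  expect_equal(dh$r, 0.2)  # discordant at positions 7 and 8 only
  # DH with 4 recombinants of 10
  b2 <- rep("P1", 10); b2[c(1, 2)] <- "P2"
  expect_equal(estimate_recfrac(a, b2, "DH")$r, 0.4)
  # RIL: discordance R = 0.2 maps to r = 0.125
  a2 <- rep(c("P1", "P2"), each = 10)
  b3 <- a2; b3[c(1, 2, 11, 12)] <- setdiff(c("P1", "P2"), "")[c(2, 2, 1, 1)]
  ril <- estimate_recfrac(a2, b3, "RIL_F6")
  expect_equal(ril$r, 0.2 / (2 - 2 * 0.2))
  expect_error(estimate_recfrac(a[1:5], b[1:5], "DH"), "insufficient")
})

test_that("unlinked markers estimate r near 0.5 with low LOD", {
  set.seed(32)
  a <- sample(c("P1", "P2"), 200, replace = TRUE)
  b <- sample(c("P1", "P2"), 200, replace = TRUE)
  est <- estimate_recfrac(a, b, "DH")
  expect_lt(abs(est$r - 0.5), 3 * sqrt(0.25 / 200))
  expect_lt(est$lod, 3)
})

test_that("the F5 selfing-chain distribution is coherent and its MLE consistent", {
  d <- two_locus_selfing_dist(0.2, 4)
  expect_equal(sum(d), 1)
  # locus marginal at F5: het fraction 0.5^4
  expect_equal(sum(d[2, ]), 0.0625)
  # selfing to convergence reproduces the RIL discordance attractor 2r/(1+2r)
  r <- 0.1
  dinf <- two_locus_selfing_dist(r, 60)
  hom_disc <- (dinf[1, 3] + dinf[3, 1]) / (dinf[1, 1] + dinf[1, 3] + dinf[3, 1] + dinf[3, 3])
  expect_equal(hom_disc, 2 * r / (1 + 2 * r), tolerance = 1e-6)

  # ML on simulated F5 data recovers r
  m <- sim_map(tibble::tibble(chromosome = "1A", length_cM = 20),
               tibble::tibble(marker_id = c("a", "b"), chromosome = "1A",
                              pos_cM = c(0, 20)))
  s <- simulate_biparental(m, "SSD_F5", 1500, seed = 33, missing_rate = 0,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  pat <- as_seg_patterns(s$geno)
  est <- estimate_recfrac(unlist(pat[1, -1]), unlist(pat[2, -1]), "SSD_F5")
  r_true <- haldane_r(20)
  expect_lt(abs(est$r - r_true), 0.03)
})

test_that("linkage grouping recovers simulated chromosomes and splits marker deserts", {
  s <- simulate_biparental(sim_map_regular(2, 100, 25), "DH", 150, seed = 34,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  pat <- as_seg_patterns(s$geno)
  rf <- pairwise_recfrac(pat, "DH")
  grp <- group_markers(rf)
  truth <- s$truth$markers
  tab <- table(grp$group, truth$chromosome[match(grp$marker_id, truth$marker_id)])
  expect_equal(length(unique(grp$group)), 2L)
  expect_true(all(apply(tab, 1, function(x) sum(x > 0)) == 1))

  # one chromosome with a 70 cM marker desert (Haldane r above max_r) splits
  md <- sim_map(tibble::tibble(chromosome = "1A", length_cM = 150),
                tibble::tibble(marker_id = sprintf("m%02d", 1:10), chromosome = "1A",
                               pos_cM = c(seq(0, 40, 10), seq(110, 150, 10))))
  s2 <- simulate_biparental(md, "DH", 150, seed = 35, missing_rate = 0,
                            dominant_fraction = 0, polymorphic_fraction = 1)
  rf2 <- pairwise_recfrac(as_seg_patterns(s2$geno), "DH")
  expect_equal(length(unique(group_markers(rf2)$group)), 2L)

  # independent markers give singleton groups
  set.seed(36)
  ind <- pattern_tbl(matrix(sample(c("P1", "P2"), 5 * 100, replace = TRUE), 5))
  rf3 <- pairwise_recfrac(ind, "DH")
  expect_equal(length(unique(group_markers(rf3)$group)), 5L)
})

test_that("ordering solves the triangle case and spaces by the map function", {
  r <- matrix(0.5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  r["A", "B"] <- r["B", "A"] <- 0.1
  r["B", "C"] <- r["C", "B"] <- 0.1
  r["A", "C"] <- r["C", "A"] <- 0.18
  rf <- structure(list(markers = c("A", "B", "C"), r = r,
                       lod = matrix(10, 3, 3, dimnames = dimnames(r)),
                       n = matrix(100, 3, 3), design = "DH"),
                  class = "wba_recfrac")
  om <- order_and_space(c("A", "B", "C"), rf, map_function = "haldane")
  expect_equal(om$marker_id, c("A", "B", "C"))
  expect_equal(om$position_cM[1], 0)
  expect_equal(diff(om$position_cM), rep(haldane_d(0.1), 2))
  # inverse Haldane: r = 0.0906 spans 10 cM
  expect_equal(haldane_d(haldane_r(10)), 10)
  expect_equal(haldane_d(0.0906), 10, tolerance = 1e-3)
})

test_that("full map construction recovers simulated order and length", {
  s <- simulate_biparental(sim_map_regular(1, 150, 60), "DH", 180, seed = 37,
                           polymorphic_fraction = 1)
  lm1 <- build_linkage_map(s$geno, "DH", population = "sim")
  expect_s3_class(lm1, "wba_map")
  expect_equal(length(unique(lm1$chromosome)), 1L)
  j <- dplyr::inner_join(tibble::as_tibble(lm1),
                         s$truth$markers[, c("marker_id", "pos_cM")], by = "marker_id")
  tau <- abs(cor(j$position_cM, j$pos_cM, method = "kendall"))
  expect_gte(tau, 0.95)
  # positions non-decreasing from zero; length identity
  expect_true(all(diff(j$position_cM[order(j$position_cM)]) >= 0))
  expect_equal(min(lm1$position_cM), 0)
  g <- glance(lm1)
  expect_equal(g$total_length_cM, max(lm1$position_cM) - min(lm1$position_cM))
})

test_that("distortion scan reproduces the chi-square worked examples", {
  sc <- distortion_scan(dplyr::bind_rows(
    distortion_pattern(31, 83, "d1"),
    pattern_tbl(matrix(c(rep("P1", 77), rep("P2", 29), rep("NC", 8)), 1), "d2"),
    pattern_tbl(matrix(rep(c("P1", "P2"), each = 57), 1), "d3")
  ))
  expect_equal(sc$statistic[1], 52^2 / 114)
  expect_equal(sc$p_value[1], pchisq(52^2 / 114, 1, lower.tail = FALSE))
  expect_equal(sc$p_value[1], 1.12e-6, tolerance = 0.01)
  expect_equal(sc$p_value[2], 3.13e-6, tolerance = 0.01)
  expect_equal(sc$favoured, c("P2", "P1", "none"))
  expect_equal(sc$statistic[3], 0)
  expect_equal(sc$p_value[3], 1)
  expect_equal(sc$significant, c(TRUE, TRUE, FALSE))
  expect_error(distortion_scan(pattern_tbl(matrix(c("H", "NC"), 1), "h1")),
               "no homozygous")
})

test_that("null simulation keeps the distortion false-positive rate near alpha", {
  s <- simulate_biparental(sim_map_regular(25, 100, 8), "DH", 128, seed = 38,
                           dominant_fraction = 0, polymorphic_fraction = 1)
  sc <- distortion_scan(as_seg_patterns(s$geno))
  frac <- mean(sc$significant)
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 * 0.995 / nrow(sc)) + 0.003)
})

test_that("consensus merging handles identity, union and conflicts", {
  m1 <- tibble::tibble(chromosome = "1A", marker_id = c("A", "B", "C"),
                       position_cM = c(0, 10, 20))
  m2 <- tibble::tibble(chromosome = "1A", marker_id = c("B", "C", "D"),
                       position_cM = c(0, 10, 20))
  cons_id <- merge_consensus(list(p1 = m1, p2 = m1))
  expect_equal(cons_id$marker_id, m1$marker_id)
  expect_equal(cons_id$position_cM, m1$position_cM)
  expect_equal(cons_id$provenance, rep("p1,p2", 3))

  cons <- merge_consensus(list(p1 = m1, p2 = m2))
  expect_equal(cons$marker_id, c("A", "B", "C", "D"))
  expect_true(all(diff(cons$position_cM) >= 0))

  m3 <- tibble::tibble(chromosome = "2B", marker_id = "B", position_cM = 0)
  expect_error(merge_consensus(list(p1 = m1, p2 = m3)), "different chromosomes")
  expect_equal(ambiguous_markers(list(m1, m3)), "B")
})

test_that("consensus of conflict-free components preserves every component order", {
  set.seed(39)
  truth <- sprintf("t%02d", 1:20)
  comps <- lapply(1:3, function(k) {
    keep <- sort(sample.int(20, 14))
    tibble::tibble(chromosome = "3B", marker_id = truth[keep],
                   position_cM = keep * 5 + runif(14, 0, 0.5))
  })
  names(comps) <- c("a", "b", "c")
  cons <- merge_consensus(comps)
  rank_cons <- setNames(seq_len(nrow(cons)), cons$marker_id)
  for (cmp in comps) {
    r <- rank_cons[cmp$marker_id]
    expect_true(all(diff(r) > 0))  # no inversions vs any component
  }
})
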