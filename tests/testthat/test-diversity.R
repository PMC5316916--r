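coll2 <- function() {
  # two small named collections over 4 markers with hand-checkable counts
  g <- tibble::tibble(
    marker_id = c("m1", "m2", "m3", "m4"),
    a1 = c("AA", "AA", "AA", "AB"), a2 = c("AA", "AA", "AA", "AA"),
    a3 = c("BB", "AA", "NC", "BB"), a4 = c("AB", "AA", "AA", "NC"),
    b1 = c("BB", "AA", "AB", "AA"), b2 = c("BB", "AA", "AA", "AA")
  )
  part <- tibble::tibble(sample_id = c("a1", "a2", "a3", "a4", "b1", "b2"),
                         collection = rep(c("A", "B"), c(4, 2)))
  list(geno = g, part = part)
}

test_that("allele frequencies match hand-tabulated counts, NC excluded", {
  f <- coll2()
  freq <- allele_frequencies(f$geno, f$part)
  fa <- freq[freq$collection == "A", ]
  expect_equal(fa$p, c(5 / 8, 1, 6 / 6, 3 / 6))   # m1: AA,AA,BB,AB of 4 samples
  expect_equal(fa$maf, c(0.375, 0, 0, 0.5))
  fb <- freq[freq$collection == "B", ]
  expect_equal(fb$p[1], 0)                        # monomorphic BB
  pooled <- freq[freq$collection == ".pooled", ]
  expect_equal(pooled$p[2], 1)
  # all-NC marker in a group is absent there, not zero
  g2 <- f$geno
  g2[3, c("b1", "b2")] <- "NC"
  f2 <- allele_frequencies(g2, f$part)
  expect_true(is.na(f2$p[f2$collection == "B" & f2$marker_id == "m3"]))
})

test_that("diversity summary identities hold", {
  f <- coll2()
  # the whole dataset scored as one collection has RI exactly 1
  one <- tibble::tibble(sample_id = f$part$sample_id, collection = "all")
  ds <- diversity_summary(allele_frequencies(f$geno, one))
  expect_equal(ds$RI, 1)
  expect_equal(ds$n, 6)
  # biallelic marker at p = 0.5 contributes He of exactly 0.5
  gh <- tibble::tibble(marker_id = "m", s1 = "AA", s2 = "BB")
  dh <- diversity_summary(allele_frequencies(gh, tibble::tibble(
    sample_id = c("s1", "s2"), collection = "g")))
  expect_equal(dh$He, 0.5)
  # He of a biallelic marker can never exceed 0.5
  rnd <- random_geno(80, 12, seed = 40)
  prt <- tibble::tibble(sample_id = names(rnd)[-1],
                        collection = rep(c("x", "y"), 6))
  dd <- diversity_summary(allele_frequencies(rnd, prt))
  expect_true(all(dd$He >= 0 & dd$He <= 0.5))
  expect_true(all(dd$RI >= 0))
})

test_that("shared/unique polymorphism counts equal the set-logic oracle", {
  f <- coll2()
  su <- shared_unique_matrix(allele_frequencies(f$geno, f$part))
  # hand check: polymorphic in A = {m1, m4}; in B = {m3}
  expect_equal(su["A", "A"], 2L)  # unique to A
  expect_equal(su["B", "B"], 1L)
  expect_equal(su["A", "B"], 0L)

  set.seed(41)
  g <- random_geno(30, 12, seed = 41)
  part <- tibble::tibble(sample_id = names(g)[-1],
                         collection = rep(c("g1", "g2", "g3"), each = 4))
  su2 <- shared_unique_matrix(allele_frequencies(g, part))
  # oracle by explicit set logic
  m <- as.matrix(g[, -1])
  poly <- sapply(split(part$sample_id, part$collection), function(s) {
    apply(m[, s, drop = FALSE], 1, function(x) {
      x <- x[x != "NC"]
      n_a <- 2 * sum(x == "AA") + sum(x == "AB")
      length(x) > 0 && n_a > 0 && n_a < 2 * length(x)
    })
  })
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) sum(poly[, i] & rowSums(poly) == 1) else sum(poly[, i] & poly[, j])
    expect_equal(unname(su2[i, j]), want)
  }
  # shared(j,k) bounded by each group's polymorphic count
  expect_true(all(su2["g1", "g2"] <= c(sum(poly[, 1]), sum(poly[, 2]))))

  # two identical collections share everything and own nothing uniquely
  gid <- random_geno(40, 4, seed = 42, missing = 0)
  gdup <- dplyr::bind_cols(gid, setNames(gid[, -1], c("T1", "T2", "T3", "T4")))
  pdup <- tibble::tibble(sample_id = names(gdup)[-1],
                         collection = rep(c("c1", "c2"), each = 4))
  sud <- shared_unique_matrix(allele_frequencies(gdup, pdup))
  expect_equal(sud["c1", "c1"], 0L)
  expect_equal(sud["c2", "c2"], 0L)
  expect_equal(sud["c1", "c2"], unname(sud["c2", "c1"]))
})

test_that("Weir-Cockerham FST hits its fixed points", {
  # groups fixed for alternate alleles: theta = 1
  g <- tibble::tibble(marker_id = sprintf("m%d", 1:20),
                      x1 = "AA", x2 = "AA", x3 = "AA",
                      y1 = "BB", y2 = "BB", y3 = "BB")
  part <- tibble::tibble(sample_id = names(g)[-1],
                         collection = rep(c("x", "y"), each = 3))
  expect_equal(fst_matrix(g, part)["x", "y"], 1)

  # two groups drawn from one panmictic pool: theta near 0 (can be negative)
  sim <- simulate_collections(tibble::tibble(name = c("u", "v"), n = c(40, 40),
                                             fst = c(0, 0)),
                              n_markers = 1500, seed = 43,
                              genome_multiplier = c(A = 1, B = 1, D = 1))
  th <- fst_matrix(sim$geno, sim$partition)["u", "v"]
  expect_lt(abs(th), 0.01)
  expect_error(fst_matrix(g, tibble::tibble(sample_id = c("x1", "y1"),
                                            collection = c("x", "y"))),
               "two samples")
})

test_that("the combined differentiation matrix lays out fst/shared/unique", {
  sim <- simulate_collections(tibble::tibble(name = c("u", "v"), n = c(15, 15),
                                             fst = c(0.1, 0.1)),
                              n_markers = 300, seed = 44)
  dm <- differentiation_matrix(sim$geno, sim$partition)
  expect_s3_class(dm, "wba_diffmat")
  td <- tidy(dm)
  expect_named(td, c("collection_1", "collection_2", "shared", "fst"))
  expect_equal(dm["v", "u"], td$fst[1])
  expect_equal(dm["u", "v"], td$shared[1])
})

test_that("IBS similarity equals the brute-force pairwise count", {
  g <- tibble::tibble(marker_id = sprintf("m%d", 1:4),
                      s1 = c("AA", "AB", "BB", "NC"),
                      s2 = c("AA", "AB", "AB", "AA"),
                      s3 = c("AA", "AB", "BB", "AA"))
  sim <- ibs_similarity(g)
  expect_equal(sim["s1", "s2"], 2 / 3)  # co-called m1..m3, identical at 2
  expect_equal(sim["s2", "s3"], 3 / 4)
  expect_equal(diag(sim), c(s1 = 1, s2 = 1, s3 = 1))

  g10 <- random_geno(25, 10, seed = 45)
  s10 <- ibs_similarity(g10)
  expect_equal(s10, t(s10))
  m <- as.matrix(g10[, -1])
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    a <- m[, pair[1]]; b <- m[, pair[2]]
    co <- a != "NC" & b != "NC"
    expect_equal(unname(s10[pair[1], pair[2]]), sum(a[co] == b[co]) / sum(co))
  }
})

test_that("classical MDS embeds a 3-4-5 triangle exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  sim <- 1 - d / 10  # similarities in [0,1]; distances scale to d/10
  res <- classical_mds(sim, n_axes = 2)
  pts <- as.matrix(res$points[, -1])
  got <- as.matrix(dist(pts))
  expect_equal(got, unname(d / 10), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colMeans(pts), c(Axis1 = 0, Axis2 = 0), tolerance = 1e-12)
  expect_true(all(diff(res$eig[1:2]) <= 0))

  # identical samples collapse to the origin (with an axis-truncation warning)
  sid <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(res0 <- classical_mds(sid, n_axes = 2), "positive eigenvalues")
  expect_equal(ncol(res0$points) - 1L, 0L)
})

test_that("MDS separates simulated differentiated clusters on axis 1", {
  sim <- simulate_collections(tibble::tibble(name = c("u", "v"), n = c(20, 20),
                                             fst = c(0.2, 0.2)),
                              n_markers = 800, seed = 46,
                              genome_multiplier = c(A = 1, B = 1, D = 1))
  res <- classical_mds(ibs_similarity(sim$geno), n_axes = 2)
  pts <- dplyr::left_join(res$points, sim$partition, by = "sample_id")
  x <- split(pts$Axis1, pts$collection)
  # silhouette-style separation: gap between group means dwarfs spread
  gap <- abs(mean(x$u) - mean(x$v))
  expect_gt(gap, 2 * (stats::sd(x$u) + stats::sd(x$v)) / 2)
})

test_that("per-genome MAF means honour construction and drop empty genomes", {
  f <- coll2()
  info <- simple_marker_info(f$geno, chromosome = c("1A", "1A", "2B", NA))
  freq <- allele_frequencies(f$geno, f$part)
  byg <- maf_by_genome(freq, info)
  expect_true(!"D" %in% byg$genome)  # absent, not zero
  a_mean <- byg$mean_MAF[byg$collection == "A" & byg$genome == "A"]
  expect_equal(a_mean, mean(c(0.375, 0)))
})

test_that("rarefaction is deterministic at full size and non-decreasing in mean", {
  sim <- simulate_collections(tibble::tibble(name = "g", n = 25, fst = 0.05),
                              n_markers = 300, seed = 47)
  rar <- polymorphism_rarefaction(sim$geno, sim$partition,
                                  sizes = c(2, 5, 10, 25), n_reps = 8, seed = 48)
  full <- rar[rar$size == 25, ]
  expect_equal(full$sd_pct_P, 0)
  ds <- diversity_summary(allele_frequencies(sim$geno, sim$partition))
  expect_equal(full$mean_pct_P, ds$pct_P)
  expect_true(all(diff(rar$mean_pct_P) >= 0))
  expect_error(polymorphism_rarefaction(sim$geno, sim$partition, sizes = 2, n_reps = 2),
               "seed")
})
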