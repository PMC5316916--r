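#' Per-marker allele frequencies by collection
#'
#' Counts the `A` allele (AA = 2 copies, AB = 1, BB = 0) over called
#' genotypes only; a marker with no calls in a collection gets `NA` there.
#' Dominant markers enter under the two-state convention (their collapsed
#' heterozygotes bias the frequency towards the collapse class; see the
#' methods vignette). Pooled frequencies over all partitioned samples are
#' appended as the pseudo-collection `".pooled"` — these are the `p_i` of the
#' rarity index.
#'
#' @param geno Genotype tibble.
#' @param partition Sample metadata tibble with `sample_id`, `collection`.
#' @param include_pooled Append pooled rows (default TRUE).
#' @return Long tibble: `marker_id`, `collection`, `n_samples`, `n_called`,
#'   `p`, `maf`.
#' @export
allele_frequencies <- function(geno, partition, include_pooled = TRUE) {
  validate_genotypes(geno)
  partition <- dplyr::filter(partition, .data$sample_id %in% names(geno)[-1])
  if (nrow(partition) == 0L) abort("no partitioned samples present in the genotype table")
  m <- geno_matrix(geno)
  groups <- split(partition$sample_id, partition$collection)
  if (any(lengths(groups) == 0)) abort("collection with zero samples")
  if (include_pooled) groups <- c(groups, list(.pooled = partition$sample_id))
  purrr::imap_dfr(groups, function(samp, coll) {
    sub <- m[, samp, drop = FALSE]
    n_aa <- rowSums(sub == "AA"); n_ab <- rowSums(sub == "AB"); n_bb <- rowSums(sub == "BB")
    called <- n_aa + n_ab + n_bb
    p <- unname(ifelse(called > 0, (2 * n_aa + n_ab) / (2 * called), NA_real_))
    tibble::tibble(marker_id = rownames(m), collection = coll,
                   n_samples = length(samp), n_called = as.integer(unname(called)),
                   p = p, maf = pmin(p, 1 - p))
  })
}

#' Collection-level diversity summary
#'
#' Per collection: sample count `n`; `pct_P`, the percentage of all panel
#' markers polymorphic within the collection (`0 < p < 1`); mean expected
#' heterozygosity `He` (per-marker `1 - p^2 - q^2 = 2pq`); mean minor allele
#' frequency `MAF`; and the rarity index
#' `RI = mean over markers of p_ij / p_i`, where `p_i` is the pooled
#' frequency — markers with `p_i = 0` (or undefined in the collection) are
#' excluded, and the number actually used is reported as `I_effective`.
#' `He` and `MAF` are averaged over all panel markers with a defined
#' frequency, monomorphic markers contributing zero. The pooled dataset
#' scored against itself has `RI = 1` exactly.
#'
#' @param freq Output of [allele_frequencies()] (pooled rows required for
#'   RI).
#' @return One row per collection: `collection`, `n`, `pct_P`, `He`, `MAF`,
#'   `RI`, `I_effective`.
#' @export
diversity_summary <- function(freq) {
  pooled <- dplyr::filter(freq, .data$collection == ".pooled") %>%
    dplyr::select("marker_id", p_pooled = "p")
  if (nrow(pooled) == 0L) abort("freq table lacks pooled rows; rerun allele_frequencies()")
  n_panel <- dplyr::n_distinct(freq$marker_id)
  freq %>%
    dplyr::filter(.data$collection != ".pooled") %>%
    dplyr::left_join(pooled, by = "marker_id") %>%
    dplyr::group_by(.data$collection) %>%
    dplyr::summarise(
      n = .data$n_samples[1],
      pct_P = 100 * sum(.data$p > 0 & .data$p < 1, na.rm = TRUE) / n_panel,
      He = mean(2 * .data$p * (1 - .data$p), na.rm = TRUE),
      MAF = mean(.data$maf, na.rm = TRUE),
      RI = mean((.data$p / .data$p_pooled)[.data$p_pooled > 0], na.rm = TRUE),
      I_effective = sum(.data$p_pooled > 0 & !is.na(.data$p), na.rm = TRUE),
      .groups = "drop"
    )
}

#' Shared and unique polymorphism counts between collections
#'
#' A marker is polymorphic in a collection when `0 < p < 1` there.
#' `shared(j, k)` counts markers polymorphic in both `j` and `k`;
#' `unique(j)` counts markers polymorphic in `j` and in no other collection.
#'
#' @param freq Output of [allele_frequencies()].
#' @return Square symmetric integer matrix: shared counts off-diagonal,
#'   unique counts on the diagonal.
#' @export
shared_unique_matrix <- function(freq) {
  wide <- freq %>%
    dplyr::filter(.data$collection != ".pooled") %>%
    dplyr::mutate(poly = !is.na(.data$p) & .data$p > 0 & .data$p < 1) %>%
    dplyr::select("marker_id", "collection", "poly") %>%
    tidyr::pivot_wider(names_from = "collection", values_from = "poly")
  pm <- as.matrix(wide[, -1]) * 1
  if (ncol(pm) < 2) abort("need at least two collections")
  shared <- crossprod(pm)
  only_in <- t(pm) %*% (rowSums(pm) == 1)
  diag(shared) <- only_in[colnames(shared), 1]
  storage.mode(shared) <- "integer"
  shared
}

# Weir-Cockerham theta variance components for one pair of collections.
# Inputs are per-marker vectors; returns the ratio-of-sums estimate.
wc_theta_pair <- function(n1, p1, h1, n2, p2, h2) {
  use <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2 & !is.na(p1) & !is.na(p2)
  n1 <- n1[use]; p1 <- p1[use]; h1 <- h1[use]
  n2 <- n2[use]; p2 <- p2[use]; h2 <- h2[use]
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar  # (r-1) = 1
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  if (!is.finite(denom) || denom == 0) {
    abort("no co-polymorphic markers between the two collections")
  }
  sum(a) / denom
}

#' Pairwise Weir-Cockerham FST between collections
#'
#' The moment estimator theta of Weir & Cockerham, accumulated as a ratio of
#' sums of the among-population (a) and total (a + b + c) variance
#' components across markers. Negative estimates — routine for weakly
#' differentiated pairs — are reported as computed.
#'
#' @param geno Genotype tibble.
#' @param partition Sample metadata with `sample_id`, `collection`; every
#'   collection needs at least two samples.
#' @return Square symmetric matrix of pairwise theta (diagonal 0).
#' @export
fst_matrix <- function(geno, partition) {
  validate_genotypes(geno)
  partition <- dplyr::filter(partition, .data$sample_id %in% names(geno)[-1])
  groups <- split(partition$sample_id, partition$collection)
  if (length(groups) < 2) abort("need at least two collections")
  if (any(lengths(groups) < 2)) abort("every collection needs at least two samples")
  m <- geno_matrix(geno)
  stats <- purrr::map(groups, function(samp) {
    sub <- m[, samp, drop = FALSE]
    n_aa <- rowSums(sub == "AA"); n_ab <- rowSums(sub == "AB"); n_bb <- rowSums(sub == "BB")
    called <- n_aa + n_ab + n_bb
    list(n = called,
         p = ifelse(called > 0, (2 * n_aa + n_ab) / (2 * called), NA_real_),
         h = ifelse(called > 0, n_ab / called, NA_real_))
  })
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    th <- wc_theta_pair(stats[[i]]$n, stats[[i]]$p, stats[[i]]$h,
                        stats[[j]]$n, stats[[j]]$p, stats[[j]]$h)
    out[i, j] <- out[j, i] <- th
  }
  out
}

#' Combined differentiation matrix
#'
#' One square matrix in the conventional published layout: pairwise
#' Weir-Cockerham FST below the diagonal, shared-polymorphism counts above,
#' unique-polymorphism counts on the diagonal.
#'
#' @inheritParams fst_matrix
#' @return A `wba_diffmat` matrix.
#' @export
differentiation_matrix <- function(geno, partition) {
  freq <- allele_frequencies(geno, partition)
  shared <- shared_unique_matrix(freq)
  fst <- fst_matrix(geno, partition)
  groups <- colnames(shared)
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  out[upper.tri(out)] <- shared[groups, groups][upper.tri(shared)]
  diag(out) <- diag(shared)
  fst <- fst[groups, groups]
  out[lower.tri(out)] <- fst[lower.tri(fst)]
  structure(out, class = c("wba_diffmat", "matrix"))
}

#' @exportS3Method generics::tidy
tidy.wba_diffmat <- function(x, ...) {
  groups <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    collection_1 = groups[pairs[, 1]],
    collection_2 = groups[pairs[, 2]],
    shared = x[pairs],
    fst = x[pairs[, c(2, 1), drop = FALSE]]
  )
}

#' Polymorphism rarefaction
#'
#' Mean and SD of the percentage of polymorphic markers over random
#' subsamples (without replacement) of each collection, across a grid of
#' subsample sizes. Published germplasm screens show a sharp rise up to
#' roughly 50 accessions; this measures that saturation curve on any
#' dataset.
#'
#' @inheritParams allele_frequencies
#' @param sizes Subsample sizes (each must not exceed its collection size;
#'   a single homozygous line is never polymorphic, so size 1 gives 0).
#' @param n_reps Subsamples per size.
#' @param seed Random seed (mandatory).
#' @return Tibble: `collection`, `size`, `mean_pct_P`, `sd_pct_P`.
#' @export
polymorphism_rarefaction <- function(geno, partition, sizes, n_reps = 20, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (any(sizes < 1)) abort("sizes must be >= 1")
  set.seed(seed)
  m <- geno_matrix(geno)
  partition <- dplyr::filter(partition, .data$sample_id %in% colnames(m))
  groups <- split(partition$sample_id, partition$collection)
  purrr::imap_dfr(groups, function(samp, coll) {
    purrr::map_dfr(sizes[sizes <= length(samp)], function(sz) {
      pp <- vapply(seq_len(n_reps), function(rep) {
        sub <- m[, sample(samp, sz), drop = FALSE]
        n_aa <- rowSums(sub == "AA"); n_ab <- rowSums(sub == "AB"); n_bb <- rowSums(sub == "BB")
        called <- n_aa + n_ab + n_bb
        p <- ifelse(called > 0, (2 * n_aa + n_ab) / (2 * called), NA_real_)
        100 * sum(p > 0 & p < 1, na.rm = TRUE) / nrow(sub)
      }, 0)
      tibble::tibble(collection = coll, size = sz,
                     mean_pct_P = mean(pp), sd_pct_P = stats::sd(pp))
    })
  })
}

#' Identity-by-state similarity matrix
#'
#' Similarity between two samples is the number of markers with identical
#' calls divided by the number of markers called in both; markers missing in
#' either sample are excluded. Call identity is strict: AB vs AA counts as
#' non-identical. The diagonal is 1 and the matrix symmetric.
#'
#' @param geno Genotype tibble with at least two samples.
#' @return Square symmetric similarity matrix.
#' @export
ibs_similarity <- function(geno) {
  validate_genotypes(geno)
  m <- geno_matrix(geno)
  if (ncol(m) < 2) abort("need at least two samples")
  called <- (m != "NC") * 1
  co <- crossprod(called)
  if (any(co == 0)) abort("sample pair with zero co-called markers")
  same <- matrix(0, ncol(m), ncol(m))
  for (cl in c("AA", "AB", "BB")) same <- same + crossprod((m == cl) * 1)
  sim <- same / co
  diag(sim) <- 1
  dimnames(sim) <- list(colnames(m), colnames(m))
  sim
}

#' Principal coordinate analysis (classical MDS)
#'
#' Converts a similarity matrix to distances (`d = 1 - similarity`) and
#' applies classical metric multidimensional scaling: double-centre
#' `-d^2/2`, eigendecompose, scale eigenvectors by the square roots of the
#' positive eigenvalues. Coordinates are centred per axis and axes ordered
#' by decreasing eigenvalue. Requesting more axes than there are positive
#' eigenvalues truncates with a warning.
#'
#' @param similarity Square similarity matrix with values in `[0, 1]`
#'   (e.g. [ibs_similarity()]).
#' @param n_axes Number of principal coordinates to keep.
#' @return A `wba_pcoa` object: `points` (tibble `sample_id`, `Axis1`, ...),
#'   `eig` (all eigenvalues, decreasing).
#' @export
classical_mds <- function(similarity, n_axes = 2) {
  if (any(similarity < -1e-9 | similarity > 1 + 1e-9)) {
    abort("similarities must lie in [0, 1]")
  }
  ids <- rownames(similarity)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(similarity)))
  d <- 1 - similarity
  # cmdscale warns itself when k exceeds the positive spectrum; the axis
  # truncation warning below is the user-facing one
  fit <- suppressWarnings(cmdscale(d, k = min(n_axes, nrow(similarity) - 1), eig = TRUE))
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  if (n_axes > n_pos) {
    warn(sprintf("only %d positive eigenvalues; returning %d axes", n_pos, n_pos))
    n_axes <- n_pos
  }
  pts <- fit$points
  if (n_axes == 0) pts <- matrix(0, nrow(similarity), 0)
  else pts <- pts[, seq_len(min(n_axes, ncol(pts))), drop = FALSE]
  colnames(pts) <- if (ncol(pts)) paste0("Axis", seq_len(ncol(pts))) else character(0)
  structure(
    list(points = tibble::as_tibble(pts) %>%
           dplyr::mutate(sample_id = ids, .before = 1),
         eig = fit$eig),
    class = "wba_pcoa"
  )
}

#' @exportS3Method generics::tidy
tidy.wba_pcoa <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.wba_pcoa <- function(x, ...) {
  pos <- pmax(x$eig, 0)
  rel <- if (sum(pos) > 0) pos / sum(pos) else pos
  tibble::tibble(
    n_samples = nrow(x$points),
    n_axes = ncol(x$points) - 1L,
    var_axis1 = rel[1],
    var_axis2 = if (length(rel) > 1) rel[2] else NA_real_
  )
}

#' @exportS3Method base::print
print.wba_pcoa <- function(x, ...) {
  cat(sprintf("Principal coordinate analysis: %d samples, %d axes\n",
              nrow(x$points), ncol(x$points) - 1L))
  print(x$points, n = 5)
  invisible(x)
}

#' Mean minor allele frequency by subgenome
#'
#' Mean MAF per collection and subgenome (A, B, D), over mapped markers
#' only. In conventional hexaploid germplasm the D genome shows depressed
#' MAF; synthetic hexaploids show the opposite pattern.
#'
#' @param freq Output of [allele_frequencies()].
#' @param info Marker metadata with `genome` and `mapped`.
#' @return Tibble: `collection`, `genome`, `n_markers`, `mean_MAF`.
#' @export
maf_by_genome <- function(freq, info) {
  freq %>%
    dplyr::filter(.data$collection != ".pooled") %>%
    dplyr::inner_join(dplyr::filter(info, .data$mapped, !is.na(.data$genome))[, c("marker_id", "genome")],
                      by = "marker_id") %>%
    dplyr::group_by(.data$collection, .data$genome) %>%
    dplyr::summarise(n_markers = sum(!is.na(.data$maf)),
                     mean_MAF = mean(.data$maf, na.rm = TRUE),
                     .groups = "drop")
}
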