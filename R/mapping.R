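#' Filter markers by missing-data fraction
#'
#' Removes markers whose no-call fraction strictly exceeds `threshold`
#' (markers with *more than* `threshold` missing data are removed; a marker
#' exactly at the boundary is retained).
#'
#' @param geno A genotype tibble.
#' @param threshold Maximum tolerated missing fraction, default 0.2.
#' @return The filtered genotype tibble.
#' @export
filter_missing <- function(geno, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  m <- geno_matrix(geno)
  frac <- rowMeans(m == "NC")
  geno[frac <= threshold, , drop = FALSE]
}

#' Convert genotype calls to parental-origin segregation patterns
#'
#' In a biparental population with parent-1 homozygotes called `AA` and
#' parent-2 homozygotes `BB`, recodes calls to parental origin: `P1`, `P2`,
#' `H` (heterozygous) and `NC`.
#'
#' @param geno A genotype tibble.
#' @return A wide tibble of the same shape with parental-origin codes.
#' @export
as_seg_patterns <- function(geno) {
  m <- geno_matrix(geno)
  code <- c(AA = "P1", BB = "P2", AB = "H", NC = "NC")
  matrix_geno(matrix(code[m], nrow = nrow(m), dimnames = dimnames(m)))
}

pattern_matrix <- function(patterns) {
  m <- geno_matrix(patterns)
  if (!all(m %in% c("P1", "P2", "H", "NC"))) {
    abort("patterns must be parental-origin coded (P1/P2/H/NC); see as_seg_patterns()")
  }
  if (ncol(m) == 0L) abort("zero-length patterns")
  m
}

#' Bin markers with identical segregation
#'
#' Markers whose patterns agree on every individual where both are called
#' (with at least one co-called individual) have an estimated recombination
#' fraction of zero and share a single map position. Binning is greedy
#' first-fit in input order: a marker joins the first bin with which it is
#' compatible against *all* current members, otherwise founds a new bin; so
#' every bin is a clique of pairwise-identical patterns. The bin
#' representative (skeleton candidate) is the member with fewest no-calls,
#' ties broken by marker id.
#'
#' @param patterns Parental-origin patterns from [as_seg_patterns()].
#' @return Tibble with columns `marker_id`, `bin_id`, `representative`
#'   (logical) and `bin_size`.
#' @export
bin_markers <- function(patterns) {
  m <- pattern_matrix(patterns)
  n <- nrow(m)
  called <- m != "NC"
  # pairwise co-called and mismatch counts via per-class cross products
  cc <- tcrossprod(called * 1)
  conc <- matrix(0, n, n)
  for (cl in c("P1", "P2", "H")) conc <- conc + tcrossprod((m == cl) * 1)
  compatible <- (cc - conc) == 0 & cc > 0

  bins <- list()
  bin_of <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      if (all(compatible[i, bins[[b]]])) {
        bins[[b]] <- c(bins[[b]], i)
        bin_of[i] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      bins[[length(bins) + 1L]] <- i
      bin_of[i] <- length(bins)
    }
  }
  nc_count <- rowSums(!called)
  ids <- rownames(m)
  out <- tibble::tibble(marker_id = ids, bin_id = bin_of, nc = nc_count)
  out %>%
    dplyr::group_by(.data$bin_id) %>%
    dplyr::mutate(
      bin_size = dplyr::n(),
      representative = dplyr::row_number(order(.data$nc, .data$marker_id)) == 1L
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("marker_id", "bin_id", "representative", "bin_size")
}

# Two-locus genotype distribution after `selfings` rounds of selfing from an
# F1 double heterozygote in coupling, with recombination fraction r between
# the loci. Returns a 3 x 3 matrix of probabilities indexed by the count of
# parent-1 alleles at locus 1 (rows: 0,1,2) and locus 2 (columns).
two_locus_selfing_dist <- function(r, selfings) {
  # haplotypes 1..4 = (P1,P1), (P1,P2), (P2,P1), (P2,P2) over the two loci
  hap1 <- c(1, 1, 0, 0)  # carries P1 allele at locus 1
  hap2 <- c(1, 0, 1, 0)  # carries P1 allele at locus 2
  st <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)  # 10 diplotypes
  gam <- function(h1, h2) {
    p <- numeric(4)
    p[h1] <- p[h1] + (1 - r) / 2
    p[h2] <- p[h2] + (1 - r) / 2
    rec1 <- which(hap1 == hap1[h1] & hap2 == hap2[h2])
    rec2 <- which(hap1 == hap1[h2] & hap2 == hap2[h1])
    p[rec1] <- p[rec1] + r / 2
    p[rec2] <- p[rec2] + r / 2
    p
  }
  TT <- matrix(0, 10, 10)
  for (s in seq_len(10)) {
    g <- gam(st[s, 1], st[s, 2])
    off <- outer(g, g)
    for (t in seq_len(10)) {
      i <- st[t, 1]; j <- st[t, 2]
      TT[s, t] <- if (i == j) off[i, j] else off[i, j] + off[j, i]
    }
  }
  v <- numeric(10)
  v[which(st[, 1] == 1 & st[, 2] == 4)] <- 1  # F1: P1P1 / P2P2 coupling diplotype
  for (k in seq_len(selfings)) v <- as.vector(v %*% TT)
  out <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (s in seq_len(10)) {
    g1 <- hap1[st[s, 1]] + hap1[st[s, 2]]
    g2 <- hap2[st[s, 1]] + hap2[st[s, 2]]
    out[g1 + 1L, g2 + 1L] <- out[g1 + 1L, g2 + 1L] + v[s]
  }
  out
}

binom_lod <- function(k, n) {
  r <- k / n
  t1 <- ifelse(k > 0, k * log10(r), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log10(1 - r), 0)
  t1 + t2 + n * log10(2)
}

#' Two-point recombination fraction between two markers
#'
#' Design-specific estimators from co-called individuals:
#' * `DH`: recombinant fraction directly, `r = recombinants / co-called`.
#' * `RIL_F6`/`RIL_F7`: observed discordance `R` among co-called homozygous
#'   pairs mapped back to the meiotic recombination fraction through the
#'   inbreeding attractor `R = 2r / (1 + 2r)`, i.e. `r = R / (2 - 2R)`,
#'   capped at 0.49.
#' * `SSD_F5`: maximum likelihood over the exact two-locus F5 selfing-chain
#'   genotype distribution (numerically maximised multinomial likelihood over
#'   the nine two-locus genotype classes, heterozygotes included).
#'
#' LOD is `log10` of the likelihood ratio against independence (`r = 0.5`).
#'
#' @param pattern_a,pattern_b Parental-origin pattern vectors (values
#'   `P1`/`P2`/`H`/`NC`) of equal length.
#' @param design Cross design, see [cross_design()].
#' @param min_n Minimum number of informative co-called individuals.
#' @return A list with `r`, `lod` and `n` (informative individuals used).
#' @export
estimate_recfrac <- function(pattern_a, pattern_b, design = "DH", min_n = 10) {
  des <- cross_design(design)
  if (des$design == "SSD_F5") {
    co <- pattern_a != "NC" & pattern_b != "NC"
    if (sum(co) < min_n) abort("insufficient co-called individuals")
    counts <- table(factor(pattern_a[co], c("P2", "H", "P1")),
                    factor(pattern_b[co], c("P2", "H", "P1")))
    ll <- function(r) sum(counts * log(pmax(two_locus_selfing_dist(r, des$selfings), 1e-300)))
    opt <- optimize(ll, c(1e-6, 0.4999), maximum = TRUE, tol = 1e-7)
    ll_null <- sum(counts * log(pmax(two_locus_selfing_dist(0.5, des$selfings), 1e-300)))
    return(list(r = opt$maximum, lod = (opt$objective - ll_null) / log(10), n = sum(co)))
  }
  hom <- c("P1", "P2")
  co <- pattern_a %in% hom & pattern_b %in% hom
  n <- sum(co)
  if (n < min_n) abort("insufficient co-called individuals")
  k <- sum(pattern_a[co] != pattern_b[co])
  R <- k / n
  r <- if (des$design == "DH") R else min(R / (2 - 2 * R), 0.49)
  list(r = r, lod = binom_lod(k, n), n = n)
}

#' All pairwise two-point estimates
#'
#' Matrix version of [estimate_recfrac()] over a set of markers. For `DH` and
#' RIL designs discordance counts are computed by cross products; for
#' `SSD_F5` the nine two-locus class counts are tabulated by cross products
#' and the likelihood maximised on a fine grid of r values. Pairs with fewer
#' than `min_n` informative individuals get `NA`.
#'
#' @param patterns Parental-origin pattern tibble.
#' @inheritParams estimate_recfrac
#' @return A list of class `wba_recfrac` with marker ids and square matrices
#'   `r`, `lod`, `n`.
#' @export
pairwise_recfrac <- function(patterns, design = "DH", min_n = 10) {
  m <- pattern_matrix(patterns)
  des <- cross_design(design)
  ids <- rownames(m)
  if (des$design %in% c("DH", "RIL_F6", "RIL_F7")) {
    hom <- m == "P1" | m == "P2"
    n <- tcrossprod(hom * 1)
    conc <- tcrossprod((m == "P1") * 1) + tcrossprod((m == "P2") * 1)
    k <- n - conc
    R <- k / n
    r <- if (des$design == "DH") R else pmin(R / (2 - 2 * R), 0.49)
    lod <- binom_lod(k, n)
  } else {
    grid <- c(seq(0.0005, 0.0995, by = 0.0005), seq(0.1, 0.4995, by = 0.0025))
    lev <- c("P2", "H", "P1")
    ind <- lapply(lev, function(cl) (m == cl) * 1)
    logp <- matrix(0, 9, length(grid))
    cnt <- vector("list", 9)
    idx <- 1L
    for (b in 1:3) for (a in 1:3) {  # column-major to match as.vector(dist)
      cnt[[idx]] <- tcrossprod(ind[[a]], ind[[b]])
      idx <- idx + 1L
    }
    for (gi in seq_along(grid)) {
      d <- two_locus_selfing_dist(grid[gi], des$selfings)
      logp[, gi] <- log(pmax(as.vector(d), 1e-300))  # column-major: by locus-1 class
    }
    d_null <- log(pmax(as.vector(two_locus_selfing_dist(0.5, des$selfings)), 1e-300))
    np <- length(ids)^2
    LL <- matrix(0, np, length(grid))
    LL0 <- numeric(np)
    n <- matrix(0, length(ids), length(ids))
    for (cidx in seq_len(9)) {
      cv <- as.vector(cnt[[cidx]])
      LL <- LL + outer(cv, logp[cidx, ])
      LL0 <- LL0 + cv * d_null[cidx]
      n <- n + cnt[[cidx]]
    }
    best <- max.col(LL, ties.method = "first")
    r <- matrix(grid[best], length(ids))
    lod <- matrix((LL[cbind(seq_len(np), best)] - LL0) / log(10), length(ids))
  }
  low <- n < min_n
  r[low] <- NA_real_; lod[low] <- NA_real_
  diag(r) <- 0; diag(lod) <- Inf
  dimnames(r) <- dimnames(lod) <- dimnames(n) <- list(ids, ids)
  structure(list(markers = ids, r = r, lod = lod, n = n, design = des$design),
            class = "wba_recfrac")
}

#' Assign markers to linkage groups
#'
#' Builds a graph over markers with an edge wherever the two-point estimate
#' shows linkage (`r <= max_r` and `LOD >= min_lod`); linkage groups are its
#' connected components, numbered by decreasing size (`LG01`, `LG02`, ...).
#'
#' @param rf A [pairwise_recfrac()] result.
#' @param max_r Maximum recombination fraction for an edge.
#' @param min_lod Minimum LOD for an edge.
#' @return Tibble with columns `marker_id`, `group`.
#' @export
group_markers <- function(rf, max_r = 0.35, min_lod = 3) {
  adj <- !is.na(rf$r) & rf$r <= max_r & rf$lod >= min_lod
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  first_id <- vapply(seq_along(sizes), function(k) min(rf$markers[comp$membership == k]), "")
  rank <- order(-sizes, first_id)
  lg <- match(comp$membership, rank)
  tibble::tibble(marker_id = rf$markers,
                 group = sprintf("LG%02d", lg)) %>%
    dplyr::arrange(.data$group, .data$marker_id)
}

map_distance_fun <- function(map_function = c("haldane", "kosambi")) {
  switch(match.arg(map_function), haldane = haldane_d, kosambi = kosambi_d)
}

#' Order markers within a linkage group and assign cM positions
#'
#' Seriation by two-point distances: the path is seeded with the most distant
#' linked pair (largest `r <= max_r`), remaining skeleton markers are added
#' by cheapest insertion (smallest increase in the sum of adjacent `r`), and
#' the order is polished by windowed 2-opt segment reversals until no
#' reversal reduces the adjacent-`r` sum. Positions are cumulative map-function
#' distances of adjacent `r` values. Non-skeleton markers are then inserted
#' one at a time at their best position, but only while the running map
#' length stays below `inflation_limit` times the skeleton length — markers
#' that would inflate the map beyond that (typically genotyping errors) are
#' dropped and reported in the `dropped` attribute.
#'
#' The orientation of a chromosome is arbitrary; the returned order starts at
#' the end whose terminal marker id sorts first.
#'
#' @param markers Character vector of (bin-representative) marker ids forming
#'   one linkage group.
#' @param rf A [pairwise_recfrac()] result covering them.
#' @param skeleton Markers ordered in the framework phase (default: all of
#'   `markers`; the remainder is inserted under the inflation rule).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param inflation_limit Maximum tolerated map-length inflation while adding
#'   non-skeleton markers.
#' @param max_r Linkage threshold used to seed the path.
#' @param window Maximum reversed-segment length during 2-opt polishing
#'   (default: unbounded, full 2-opt).
#' @return Tibble with columns `marker_id`, `position_cM`, `skeleton`;
#'   attribute `dropped` lists markers removed by the inflation rule.
#' @export
order_and_space <- function(markers, rf, skeleton = NULL,
                            map_function = "haldane", inflation_limit = 1.2,
                            max_r = 0.35, window = Inf) {
  dfun <- map_distance_fun(map_function)
  if (length(markers) == 1L) {
    out <- tibble::tibble(marker_id = markers, position_cM = 0, skeleton = TRUE)
    attr(out, "dropped") <- tibble::tibble(marker_id = character(), reason = character())
    return(out)
  }
  if (is.null(skeleton) || length(skeleton) < 2L) skeleton <- markers
  R <- rf$r[markers, markers, drop = FALSE]
  R[is.na(R)] <- 0.5

  sk <- match(skeleton, markers)
  Rsk <- R[sk, sk, drop = FALSE]
  linked <- Rsk <= max_r
  diag(linked) <- FALSE
  seedval <- ifelse(linked, Rsk, -Inf)
  if (all(is.infinite(seedval))) seedval <- -Rsk  # fall back to closest pair
  w <- which(seedval == max(seedval), arr.ind = TRUE)
  w <- w[order(rownames(seedval)[w[, 1]], colnames(seedval)[w[, 2]]), , drop = FALSE]
  path <- as.integer(w[1, ])
  remaining <- setdiff(seq_along(sk), path)
  while (length(remaining)) {
    # nearest-neighbour choice of the next marker, cheapest-insertion placement
    near <- vapply(remaining, function(i) min(Rsk[i, path]), 0)
    nxt <- remaining[order(near, skeleton[remaining])][1]
    path <- insert_cheapest(path, nxt, Rsk)
    remaining <- setdiff(remaining, nxt)
  }
  path <- two_opt(path, Rsk, window)
  order_sk <- sk[path]

  # canonical orientation
  ends <- markers[c(order_sk[1], order_sk[length(order_sk)])]
  if (ends[2] < ends[1]) order_sk <- rev(order_sk)

  # insert unique-pattern markers at their best position while the total map
  # length stays within inflation_limit times the skeleton length; markers
  # inflating beyond that budget (typically genotyping errors) are dropped
  skeleton_len <- current_length(order_sk, R, dfun)
  ord <- order_sk
  cur_len <- skeleton_len
  dropped <- character()
  for (m in setdiff(seq_along(markers), sk)) {
    cand <- insertion_costs(ord, m, R, dfun)
    new_len <- cur_len + min(cand$cost)
    if (skeleton_len == 0 || new_len < inflation_limit * skeleton_len) {
      ord <- append(ord, m, after = cand$after[which.min(cand$cost)])
      cur_len <- new_len
    } else {
      dropped <- c(dropped, markers[m])
    }
  }
  ord <- two_opt(ord, R, window)
  ends <- markers[c(ord[1], ord[length(ord)])]
  if (ends[2] < ends[1]) ord <- rev(ord)
  d <- dfun(R[cbind(head(ord, -1), tail(ord, -1))])
  out <- tibble::tibble(
    marker_id = markers[ord],
    position_cM = cumsum(c(0, d)),
    skeleton = markers[ord] %in% skeleton
  )
  attr(out, "dropped") <- tibble::tibble(marker_id = dropped,
                                         reason = rep("inflation", length(dropped)))
  out
}

current_length <- function(ord, R, dfun) {
  if (length(ord) < 2) return(0)
  sum(dfun(R[cbind(head(ord, -1), tail(ord, -1))]))
}

insertion_costs <- function(ord, m, R, dfun) {
  n <- length(ord)
  after <- 0:n
  cost <- numeric(n + 1)
  cost[1] <- dfun(R[m, ord[1]])
  cost[n + 1] <- dfun(R[m, ord[n]])
  if (n > 1) {
    a <- ord[1:(n - 1)]; b <- ord[2:n]
    cost[2:n] <- dfun(R[m, a]) + dfun(R[m, b]) - dfun(R[cbind(a, b)])
  }
  list(after = after, cost = cost)
}

insert_cheapest <- function(path, m, R) {
  n <- length(path)
  best_cost <- Inf; best_after <- 0L
  for (pos in 0:n) {
    cost <- if (pos == 0) R[m, path[1]]
    else if (pos == n) R[m, path[n]]
    else R[m, path[pos]] + R[m, path[pos + 1]] - R[path[pos], path[pos + 1]]
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_after <- pos }
  }
  append(path, m, after = best_after)
}

two_opt <- function(path, R, window = Inf, max_pass = 25) {
  n <- length(path)
  if (n < 3) return(path)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in 1:(n - 1)) {
      for (j in (i + 1):min(n, i + window - 1)) {
        delta <- 0
        if (i > 1) delta <- delta + R[path[i - 1], path[j]] - R[path[i - 1], path[i]]
        if (j < n) delta <- delta + R[path[i], path[j + 1]] - R[path[j], path[j + 1]]
        if (delta < -1e-12) {
          path[i:j] <- rev(path[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  path
}

#' Build a linkage map from a biparental population
#'
#' The full component-map workflow: markers with more than `max_missing`
#' missing data are removed, monomorphic markers dropped, segregation
#' patterns binned ([bin_markers()]), two-point estimates computed between
#' bin representatives ([pairwise_recfrac()]), linkage groups formed
#' ([group_markers()]) and each group ordered and spaced
#' ([order_and_space()]). Representatives of multi-marker bins form the
#' skeleton; unique-pattern markers are inserted under the inflation rule.
#' Bin co-members share their representative's position.
#'
#' @param geno Genotype tibble of the population (`AA` = parent-1
#'   homozygote, `BB` = parent-2 homozygote).
#' @param design Cross design, see [cross_design()].
#' @param population Label stored on the map.
#' @param max_missing Missing-data filter threshold.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param max_r,min_lod Linkage thresholds.
#' @param inflation_limit Map-inflation tolerance for unique-pattern markers.
#' @param min_n Minimum informative individuals per two-point estimate.
#' @return A `wba_map` tibble: `chromosome` (linkage group), `marker_id`,
#'   `position_cM`, `skeleton`, `bin_id`; attributes `population`,
#'   `n_individuals`, `design` and `dropped`.
#' @export
build_linkage_map <- function(geno, design = "DH", population = "pop",
                              max_missing = 0.2, map_function = "haldane",
                              max_r = 0.35, min_lod = 3, inflation_limit = 1.2,
                              min_n = 10) {
  n_ind <- ncol(geno) - 1L
  kept <- filter_missing(geno, max_missing)
  dropped <- tibble::tibble(marker_id = setdiff(geno$marker_id, kept$marker_id),
                            reason = "missing_data")
  m <- geno_matrix(kept)
  n_classes <- apply(m, 1, function(x) length(unique(x[x != "NC"])))
  mono <- n_classes < 2
  dropped <- dplyr::bind_rows(dropped,
                              tibble::tibble(marker_id = rownames(m)[mono],
                                             reason = "monomorphic"))
  kept <- kept[!mono, , drop = FALSE]
  if (nrow(kept) < 2) abort("fewer than two polymorphic markers after filtering")

  patterns <- as_seg_patterns(kept)
  bins <- bin_markers(patterns)
  reps <- bins$marker_id[bins$representative]
  rep_patterns <- patterns[match(reps, patterns$marker_id), , drop = FALSE]
  rf <- pairwise_recfrac(rep_patterns, design = design, min_n = min_n)
  groups <- group_markers(rf, max_r = max_r, min_lod = min_lod)

  skeleton_reps <- bins$marker_id[bins$representative & bins$bin_size > 1]
  pieces <- groups %>%
    dplyr::group_by(.data$group) %>%
    dplyr::group_map(function(d, key) {
      sk <- intersect(d$marker_id, skeleton_reps)
      # in sparse data most patterns are unique and multi-member bins cannot
      # frame the chromosome; then every representative is skeleton
      if (length(sk) < 0.5 * length(d$marker_id)) sk <- character(0)
      om <- order_and_space(d$marker_id, rf,
                            skeleton = if (length(sk) >= 2) sk else NULL,
                            map_function = map_function,
                            inflation_limit = inflation_limit, max_r = max_r)
      om$chromosome <- key$group
      om
    })
  dropped <- dplyr::bind_rows(
    dropped,
    purrr::map_dfr(pieces, ~ attr(.x, "dropped"))
  )
  placed <- dplyr::bind_rows(pieces)

  # co-locate bin members with their representative
  rep_of <- bins %>%
    dplyr::group_by(.data$bin_id) %>%
    dplyr::mutate(rep_id = .data$marker_id[.data$representative]) %>%
    dplyr::ungroup()
  full <- rep_of %>%
    dplyr::inner_join(placed, by = c(rep_id = "marker_id")) %>%
    dplyr::mutate(skeleton = .data$representative & .data$skeleton) %>%
    dplyr::select("chromosome", "marker_id", "position_cM", "skeleton", "bin_id") %>%
    dplyr::arrange(.data$chromosome, .data$position_cM, .data$marker_id)

  structure(
    full,
    population = population, n_individuals = n_ind, design = design,
    dropped = dropped,
    class = c("wba_map", class(full))
  )
}

#' Per-chromosome and whole-map summaries of a linkage map
#'
#' `tidy()` returns one row per chromosome (marker count, skeleton count,
#' length in cM); `glance()` one row for the whole map.
#'
#' @param x A `wba_map`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wba_map <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::summarise(n_markers = dplyr::n(),
                     n_skeleton = sum(.data$skeleton),
                     length_cM = max(.data$position_cM) - min(.data$position_cM),
                     .groups = "drop")
}

#' @rdname tidy.wba_map
#' @exportS3Method generics::glance
glance.wba_map <- function(x, ...) {
  tibble::tibble(
    population = attr(x, "population") %||% NA_character_,
    n_individuals = attr(x, "n_individuals") %||% NA_integer_,
    n_chromosomes = length(unique(x$chromosome)),
    n_markers = nrow(x),
    n_skeleton = sum(x$skeleton),
    total_length_cM = sum(tidy(x)$length_cM),
    n_dropped = nrow(attr(x, "dropped") %||% tibble::tibble())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write linkage map tables
#'
#' Map TSV: columns `chromosome`, `marker_id`, `position_cM` (written with 4
#' decimals).
#'
#' @param map A map tibble.
#' @param path File path.
#' @export
write_linkage_map <- function(map, path) {
  out <- tibble::as_tibble(map)[, c("chromosome", "marker_id", "position_cM")]
  out$position_cM <- sprintf("%.4f", out$position_cM)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chromosome = readr::col_character(),
    marker_id = readr::col_character(),
    position_cM = readr::col_double()
  ), progress = FALSE)
}

#' Segregation-distortion chi-square scan
#'
#' Tests each marker's homozygote counts against the expected 50:50
#' parental ratio with a one-degree-of-freedom chi-square test (no continuity
#' correction): `X2 = (n1 - n2)^2 / (n1 + n2)`. Heterozygous and missing
#' calls are excluded from the counts. The favoured parent is the one with
#' the larger count. Both `-log10(p)` and `log10(X2)` are provided for
#' Manhattan-style plotting.
#'
#' @param patterns Parental-origin patterns ([as_seg_patterns()]) or a
#'   genotype tibble (recoded automatically).
#' @param map Optional map tibble (`chromosome`, `marker_id`, `position_cM`)
#'   to annotate results with positions.
#' @param alpha Significance level, default 0.005.
#' @return A `wba_distortion` tibble: `marker_id`, `n1`, `n2`, `statistic`,
#'   `p_value`, `significant`, `favoured`, `neglog10_p`, `log10_statistic`
#'   (plus `chromosome`, `position_cM` when `map` is given).
#' @export
distortion_scan <- function(patterns, map = NULL, alpha = 0.005) {
  m <- geno_matrix(patterns)
  if (any(m %in% c("AA", "BB", "AB"))) m <- geno_matrix(as_seg_patterns(matrix_geno(m)))
  n1 <- rowSums(m == "P1")
  n2 <- rowSums(m == "P2")
  if (any(n1 + n2 == 0)) {
    abort(sprintf("marker \"%s\" has no homozygous calls; cannot test distortion",
                  rownames(m)[which(n1 + n2 == 0)[1]]))
  }
  x2 <- unname((n1 - n2)^2 / (n1 + n2))
  p <- pchisq(x2, df = 1, lower.tail = FALSE)
  n1 <- unname(n1); n2 <- unname(n2)
  out <- tibble::tibble(
    marker_id = rownames(m),
    n1 = as.integer(n1), n2 = as.integer(n2),
    statistic = x2, p_value = p,
    significant = p < alpha,
    favoured = dplyr::case_when(n1 > n2 ~ "P1", n2 > n1 ~ "P2", TRUE ~ "none"),
    neglog10_p = -log10(p),
    log10_statistic = ifelse(x2 > 0, log10(x2), NA_real_)
  )
  if (!is.null(map)) {
    out <- dplyr::left_join(out,
                            tibble::as_tibble(map)[, c("marker_id", "chromosome", "position_cM")],
                            by = "marker_id")
  }
  structure(out, alpha = alpha, class = c("wba_distortion", class(out)))
}

#' Markers mapped to different chromosomes in different component maps
#'
#' These ambiguous markers must be removed (together with distorted markers)
#' before consensus merging.
#'
#' @param maps List of component map tibbles.
#' @return Character vector of ambiguous marker ids.
#' @export
ambiguous_markers <- function(maps) {
  purrr::map_dfr(maps, ~ tibble::as_tibble(.x)[, c("chromosome", "marker_id")]) %>%
    dplyr::distinct() %>%
    dplyr::count(.data$marker_id) %>%
    dplyr::filter(.data$n > 1) %>%
    dplyr::pull("marker_id")
}

#' Merge component linkage maps into a consensus map
#'
#' Heuristic consensus construction from component maps sharing a chromosome
#' nomenclature. Per chromosome, every component contributes precedence
#' edges between its consecutive markers; opposite edges are resolved by
#' majority multiplicity (ties kept for the direction backed by the larger
#' population, then lexicographically); residual cycles are broken by
#' deleting the minimum-multiplicity edge inside each strongly connected
#' component. The conflict-free graph is ordered topologically (ties by mean
#' rescaled component position) and consensus positions are the unweighted
#' average of linearly rescaled component positions, monotonised by isotonic
#' regression and anchored at 0. No weighting is applied across component
#' maps beyond tie-breaks.
#'
#' Markers showing significant segregation distortion in any population, and
#' markers mapped to different chromosomes in different components, must be
#' removed beforehand (`exclude`); a cross-chromosome conflict is an error.
#'
#' @param maps Named list of component map tibbles (`chromosome`,
#'   `marker_id`, `position_cM`); names label the populations.
#' @param exclude Marker ids to drop before merging (e.g. distorted
#'   markers).
#' @param pop_sizes Optional named population sizes used in tie-breaks;
#'   defaults to each map's `n_individuals` attribute, then to 0.
#' @return A `wba_consensus` tibble: `chromosome`, `marker_id`,
#'   `position_cM`, `provenance` (comma-separated contributing populations).
#' @export
merge_consensus <- function(maps, exclude = character(), pop_sizes = NULL) {
  if (length(maps) < 2) abort("need at least two component maps")
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- sprintf("map%d", seq_along(maps))
  }
  sizes <- purrr::map_dbl(names(maps), function(nm) {
    if (!is.null(pop_sizes) && nm %in% names(pop_sizes)) return(pop_sizes[[nm]])
    attr(maps[[nm]], "n_individuals") %||% 0
  })
  names(sizes) <- names(maps)

  comp <- purrr::imap_dfr(maps, function(m, nm) {
    tibble::as_tibble(m)[, c("chromosome", "marker_id", "position_cM")] %>%
      dplyr::mutate(population = nm)
  }) %>%
    dplyr::filter(!(.data$marker_id %in% exclude))

  conflict <- comp %>%
    dplyr::distinct(.data$marker_id, .data$chromosome) %>%
    dplyr::count(.data$marker_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(sprintf("marker \"%s\" is assigned to different chromosomes in different components",
                  conflict$marker_id[1]))
  }

  out <- comp %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::group_map(~ consensus_chromosome(.x, .y$chromosome, sizes)) %>%
    dplyr::bind_rows()
  structure(out, populations = names(maps),
            class = c("wba_consensus", class(out)))
}

consensus_chromosome <- function(comp, chrom, sizes) {
  # rescale each component linearly to the mean component length
  lens <- comp %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(len = max(.data$position_cM) - min(.data$position_cM),
                     lo = min(.data$position_cM), .groups = "drop")
  target <- mean(lens$len)
  comp <- comp %>%
    dplyr::left_join(lens, by = "population") %>%
    dplyr::mutate(pos_scaled = ifelse(.data$len > 0,
                                      (.data$position_cM - .data$lo) * target / .data$len,
                                      0))
  mean_pos <- comp %>%
    dplyr::group_by(.data$marker_id) %>%
    dplyr::summarise(mean_pos = mean(.data$pos_scaled),
                     provenance = paste(sort(unique(.data$population)), collapse = ","),
                     .groups = "drop")

  edges <- comp %>%
    dplyr::group_by(.data$population) %>%
    dplyr::arrange(.data$position_cM, .data$marker_id, .by_group = TRUE) %>%
    dplyr::reframe(from = head(.data$marker_id, -1), to = tail(.data$marker_id, -1)) %>%
    dplyr::group_by(.data$from, .data$to) %>%
    dplyr::summarise(weight = dplyr::n(),
                     max_pop = max(sizes[unique(.data$population)], 0),
                     .groups = "drop")

  # resolve antiparallel edge pairs: majority wins; ties by larger population,
  # then by lexicographic direction
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  drop <- logical(nrow(edges))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    e <- edges[idx, ]
    win <- order(-e$weight, -e$max_pop, e$from)[1]
    drop[idx[-win]] <- TRUE
  }
  edges <- edges[!drop, , drop = FALSE]

  edges <- break_cycles(edges)

  ord <- kahn_order(mean_pos$marker_id, edges, setNames(mean_pos$mean_pos, mean_pos$marker_id))
  y <- mean_pos$mean_pos[match(ord, mean_pos$marker_id)]
  pos <- if (length(y) > 1) isoreg(seq_along(y), y)$yf else y
  pos <- pos - pos[1]
  tibble::tibble(chromosome = chrom, marker_id = ord, position_cM = pos) %>%
    dplyr::left_join(mean_pos[, c("marker_id", "provenance")], by = "marker_id")
}

break_cycles <- function(edges) {
  repeat {
    if (nrow(edges) == 0) return(edges)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
    scc <- igraph::components(g, mode = "strong")
    big <- which(scc$csize > 1)
    if (!length(big)) return(edges)
    members <- names(scc$membership)[scc$membership == big[1]]
    inside <- edges$from %in% members & edges$to %in% members
    idx <- which(inside)
    victim <- idx[order(edges$weight[idx], edges$max_pop[idx],
                        edges$from[idx], edges$to[idx])][1]
    edges <- edges[-victim, , drop = FALSE]
  }
}

kahn_order <- function(nodes, edges, prior_pos) {
  succ <- split(edges$to, factor(edges$from, levels = nodes))
  indeg <- table(factor(edges$to, levels = nodes))
  indeg <- setNames(as.integer(indeg), nodes)
  ready <- nodes[indeg == 0]
  out <- character(0)
  while (length(ready)) {
    ready <- ready[order(prior_pos[ready], ready)]
    v <- ready[1]
    ready <- ready[-1]
    out <- c(out, v)
    for (u in succ[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) ready <- c(ready, u)
    }
  }
  if (length(out) != length(nodes)) abort("internal error: precedence graph still cyclic")
  out
}
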