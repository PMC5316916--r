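#' Cross designs for biparental population simulation
#'
#' Supported designs: doubled haploid (`DH`, fully homozygous, no residual
#' heterozygosity), recombinant inbred lines selfed to F6 or F7 (`RIL_F6`,
#' `RIL_F7`) and single-seed descent to F5 (`SSD_F5`). Residual per-locus
#' heterozygosity halves each selfing generation, so the expected
#' heterozygous fraction at generation g is 0.5^(g-1): 0 for DH, 0.03125 for
#' F6, 0.015625 for F7 and 0.0625 for F5.
#'
#' @param design One of `"DH"`, `"RIL_F6"`, `"RIL_F7"`, `"SSD_F5"`.
#' @return A list with `design`, `selfings` (number of selfing meioses after
#'   the F1) and `expected_het_fraction`.
#' @export
cross_design <- function(design = c("DH", "RIL_F6", "RIL_F7", "SSD_F5")) {
  design <- match.arg(design)
  selfings <- switch(design, DH = 0L, RIL_F6 = 5L, RIL_F7 = 6L, SSD_F5 = 4L)
  list(
    design = design,
    selfings = selfings,
    expected_het_fraction = if (design == "DH") 0 else 0.5^selfings
  )
}

#' Simulated genetic map
#'
#' Describes the chromosomes, marker positions and (optionally) segregation
#' distortion loci used by [simulate_biparental()]. Distortion loci act as
#' viability selection: an individual homozygous for the disfavoured parent's
#' allele at a distortion locus survives with probability `1 - s`.
#'
#' @param chromosomes Tibble with columns `chromosome`, `length_cM`.
#' @param markers Tibble with columns `marker_id`, `chromosome`, `pos_cM`.
#' @param distortion Optional tibble with columns `chromosome`, `pos_cM`,
#'   `s` (selection coefficient in `[0, 1)`) and `favoured` (`"P1"`/`"P2"`).
#' @return A list of class `wba_sim_map`.
#' @export
sim_map <- function(chromosomes, markers, distortion = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  markers <- tibble::as_tibble(markers)
  if (nrow(markers) == 0L) abort("empty map: no markers")
  if (!all(markers$chromosome %in% chromosomes$chromosome)) {
    abort("markers reference chromosomes absent from the chromosome table")
  }
  len <- setNames(chromosomes$length_cM, chromosomes$chromosome)
  if (any(markers$pos_cM < 0 | markers$pos_cM > len[markers$chromosome])) {
    abort("marker positions outside chromosome bounds")
  }
  if (!is.null(distortion) && nrow(distortion)) {
    distortion <- tibble::as_tibble(distortion)
    if (any(distortion$s < 0 | distortion$s >= 1)) abort("selection coefficient s must be in [0, 1)")
    if (any(distortion$pos_cM < 0 | distortion$pos_cM > len[distortion$chromosome])) {
      abort("distortion loci outside chromosome bounds")
    }
    if (!all(distortion$favoured %in% c("P1", "P2"))) abort("favoured parent must be P1 or P2")
  } else {
    distortion <- tibble::tibble(chromosome = character(), pos_cM = double(),
                                 s = double(), favoured = character())
  }
  structure(list(chromosomes = chromosomes,
                 markers = dplyr::arrange(markers, .data$chromosome, .data$pos_cM),
                 distortion = distortion),
            class = "wba_sim_map")
}

#' @rdname sim_map
#' @param n_chromosomes,length_cM,markers_per_chromosome Shape of a regular
#'   map: equally long chromosomes carrying evenly spaced markers (first
#'   marker at 0 cM). Chromosome names follow the wheat convention
#'   (1A, 1B, 1D, 2A, ...).
#' @export
sim_map_regular <- function(n_chromosomes = 3, length_cM = 150,
                            markers_per_chromosome = 50, distortion = NULL) {
  chrn <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  if (n_chromosomes > length(chrn)) {
    chrn <- c(chrn, paste0("chr", seq_len(n_chromosomes - length(chrn)) + 21L))
  }
  chrn <- chrn[seq_len(n_chromosomes)]
  chromosomes <- tibble::tibble(chromosome = chrn, length_cM = length_cM)
  markers <- tidyr::expand_grid(chromosome = chrn, k = seq_len(markers_per_chromosome)) %>%
    dplyr::mutate(
      pos_cM = (.data$k - 1) * length_cM / max(1L, markers_per_chromosome - 1L),
      marker_id = sprintf("AX_%s_%03d", .data$chromosome, .data$k)
    ) %>%
    dplyr::select("marker_id", "chromosome", "pos_cM")
  sim_map(chromosomes, markers, distortion)
}

# One gamete per column under Haldane's model: crossover count ~
# Poisson(L/100), positions uniform, no interference. hap_a/hap_b are
# markers x n 0/1 matrices (parental-origin coded); returns a markers x n
# matrix.
gametes_chr <- function(hap_a, hap_b, pos, length_cM) {
  n <- ncol(hap_a)
  out <- hap_a
  k <- rpois(n, length_cM / 100)
  phase <- sample.int(2L, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {
    seg <- if (k[i] == 0L) integer(length(pos))
           else findInterval(pos, sort(runif(k[i], 0, length_cM)))
    choice <- (phase[i] + seg) %% 2L
    out[, i] <- ifelse(choice == 0L, hap_a[, i], hap_b[, i])
  }
  out
}

# Simulate one batch of individuals at the final generation; returns a
# markers x n integer matrix counting copies of the P2 allele (0, 1, 2),
# with rows following `markers` (which may include hidden distortion loci).
simulate_batch <- function(markers, chromosomes, des, n) {
  len <- setNames(chromosomes$length_cM, chromosomes$chromosome)
  geno <- matrix(0L, nrow = nrow(markers), ncol = n,
                 dimnames = list(markers$marker_id, NULL))
  for (chr in unique(markers$chromosome)) {
    idx <- which(markers$chromosome == chr)
    pos <- markers$pos_cM[idx]
    L <- len[[chr]]
    zero <- matrix(0L, nrow = length(idx), ncol = n)
    one <- matrix(1L, nrow = length(idx), ncol = n)
    if (des$design == "DH") {
      g <- gametes_chr(zero, one, pos, L)
      geno[idx, ] <- 2L * g
    } else {
      hap_a <- zero; hap_b <- one
      for (gen in seq_len(des$selfings)) {
        g1 <- gametes_chr(hap_a, hap_b, pos, L)
        g2 <- gametes_chr(hap_a, hap_b, pos, L)
        hap_a <- g1; hap_b <- g2
      }
      geno[idx, ] <- hap_a + hap_b
    }
  }
  geno
}

#' Simulate a biparental mapping population
#'
#' Generates genotype calls for a biparental population under Haldane
#' (no-interference) recombination: per meiosis the crossover count on a
#' chromosome is Poisson(length/100) with uniform positions. Selfing designs
#' iterate single-seed descent to the design's generation. Segregation
#' distortion is applied as viability selection: final-generation individuals
#' homozygous for the disfavoured allele at a distortion locus are kept with
#' probability `1 - s` (rejection sampling until `n_individuals` accepted).
#'
#' A fraction `dominant_fraction` of markers is made dominant: their true AB
#' calls are collapsed into one (randomly chosen) homozygote class, emulating
#' assays that cannot separate the heterozygote cluster. A fraction
#' `1 - polymorphic_fraction` of markers is monomorphic between the parents
#' (on a breeding array roughly a quarter of markers segregate in any given
#' cross). Calls are then masked to `NC` at `missing_rate`.
#'
#' Parent 1 homozygotes are encoded `AA`, parent 2 homozygotes `BB`.
#'
#' @param map A [sim_map()].
#' @param design Cross design, see [cross_design()].
#' @param n_individuals Population size (>= 2).
#' @param missing_rate Per-call no-call probability, in `[0, 0.2]`.
#' @param dominant_fraction Fraction of markers with a dominant assay.
#' @param polymorphic_fraction Fraction of markers polymorphic between the
#'   parents.
#' @param ts_fraction Fraction of simulated SNPs that are transitions.
#' @param seed Random seed (mandatory).
#' @return A list with elements `geno` (genotype tibble), `info` (marker
#'   metadata tibble) and `truth` (list: per-marker simulation truth,
#'   adjacent-marker Haldane recombination fractions, distortion loci).
#' @export
simulate_biparental <- function(map, design = "DH", n_individuals,
                                missing_rate = 0.05, dominant_fraction = 0.562,
                                polymorphic_fraction = 0.25,
                                ts_fraction = 0.688, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (!inherits(map, "wba_sim_map")) abort("map must be a wba_sim_map")
  if (n_individuals < 2) abort("n_individuals must be >= 2")
  if (missing_rate < 0 || missing_rate > 0.2) abort("missing_rate must be in [0, 0.2]")
  set.seed(seed)
  des <- cross_design(design)

  markers <- map$markers
  dist <- map$distortion
  sim_markers <- markers
  if (nrow(dist)) {
    hidden <- dist %>%
      dplyr::mutate(marker_id = sprintf(".dist%02d", dplyr::row_number())) %>%
      dplyr::select("marker_id", "chromosome", "pos_cM")
    sim_markers <- dplyr::bind_rows(markers, hidden) %>%
      dplyr::arrange(.data$chromosome, .data$pos_cM)
  }

  accepted <- matrix(0L, nrow = nrow(sim_markers), ncol = 0)
  while (ncol(accepted) < n_individuals) {
    need <- n_individuals - ncol(accepted)
    batch_n <- if (nrow(dist)) ceiling(need / prod(1 - dist$s) * 1.2) + 5L else need
    g <- simulate_batch(sim_markers, map$chromosomes, des, batch_n)
    if (nrow(dist)) {
      w <- rep(1, batch_n)
      for (d in seq_len(nrow(dist))) {
        gd <- g[sprintf(".dist%02d", d), ]
        disfavoured_hom <- if (dist$favoured[d] == "P1") 2L else 0L
        w <- w * ifelse(gd == disfavoured_hom, 1 - dist$s[d], 1)
      }
      g <- g[, runif(batch_n) < w, drop = FALSE]
    }
    accepted <- cbind(accepted, g)
  }
  geno_counts <- accepted[markers$marker_id, seq_len(n_individuals), drop = FALSE]

  M <- nrow(markers)
  poly <- runif(M) < polymorphic_fraction
  mono_class <- sample(c(0L, 2L), M, replace = TRUE)
  geno_counts[!poly, ] <- mono_class[!poly]

  dominant <- runif(M) < dominant_fraction
  collapse_to <- ifelse(dominant, sample(c("AA", "BB"), M, replace = TRUE), NA_character_)

  calls <- matrix(c("AA", "AB", "BB")[geno_counts + 1L], nrow = M,
                  dimnames = list(markers$marker_id, NULL))
  het <- calls == "AB"
  coll <- matrix(rep(collapse_to, n_individuals), nrow = M)
  calls[dominant & het] <- coll[dominant & het]
  calls[matrix(runif(M * n_individuals) < missing_rate, nrow = M)] <- "NC"

  samples <- sprintf("IND%04d", seq_len(n_individuals))
  colnames(calls) <- samples
  geno <- matrix_geno(calls)

  is_ts <- runif(M) < ts_fraction
  ref <- sample(.wba_nucleotides, M, replace = TRUE)
  alt <- allele_partner(ref, is_ts)
  info <- markers %>%
    dplyr::mutate(
      contig = sprintf("ctg%05d", ceiling(dplyr::row_number() / 2)),
      allele_ref = ref, allele_alt = alt,
      dominance = ifelse(dominant, "dominant", "codominant"),
      chromosome = .data$chromosome, cM = .data$pos_cM,
      mapped = TRUE, genome = genome_of(.data$chromosome)
    ) %>%
    dplyr::select("marker_id", "contig", "allele_ref", "allele_alt",
                  "dominance", "chromosome", "cM", "mapped", "genome")

  adj <- markers %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::reframe(marker_a = head(.data$marker_id, -1),
                   marker_b = tail(.data$marker_id, -1),
                   d_cM = diff(.data$pos_cM)) %>%
    dplyr::mutate(r_true = haldane_r(.data$d_cM))

  list(
    geno = geno,
    info = info,
    truth = list(
      design = des$design,
      markers = markers %>% dplyr::mutate(polymorphic = poly, dominant = dominant,
                                          collapse_to = collapse_to),
      adjacent_r = adj,
      distortion = dist
    )
  )
}

# transition partner (A<->G, C<->T) or a random transversion partner
allele_partner <- function(ref, is_ts) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  alt <- ts_of[ref]
  tv <- which(!is_ts)
  alt[tv] <- vapply(ref[tv], function(x) sample(tv_of[[x]], 1L), character(1))
  unname(alt)
}

#' Simulate structured germplasm collections
#'
#' Draws, per marker, an ancestral allele frequency and then per-collection
#' frequencies under the Balding–Nichols model: for a collection with
#' differentiation target `F`, the collection frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p(1-p) — so
#' the Weir–Cockerham FST between collections estimates `F`. Individuals are
#' sampled as inbred lines: heterozygous at a small residual rate, otherwise
#' homozygous with probability given by the collection frequency.
#'
#' Subgenome MAF structure is imposed through `genome_multiplier`: ancestral
#' MAFs of D-genome markers in conventional hexaploid germplasm are shrunk
#' (the D genome passed through a domestication bottleneck); a synthetic
#' hexaploid collection scenario would instead use a D multiplier above 1.
#'
#' @param groups Tibble with columns `name`, `n` (samples) and `fst`
#'   (Balding–Nichols `F` in `[0, 1)`).
#' @param n_markers Number of markers.
#' @param seed Random seed (mandatory).
#' @param maf_range Range of the uniform ancestral minor-allele-frequency
#'   distribution.
#' @param genome_multiplier Named multipliers applied to the ancestral MAF of
#'   markers on the A, B and D subgenomes.
#' @param residual_het Residual heterozygosity rate of inbred lines.
#' @param missing_rate Per-call no-call probability.
#' @param dominant_fraction Fraction of markers with a dominant assay (their
#'   AB calls are collapsed into a random homozygote class).
#' @return A list with `geno`, `info`, `partition` (sample metadata tibble)
#'   and `truth` (ancestral and per-group frequencies).
#' @export
simulate_collections <- function(groups, n_markers, seed,
                                 maf_range = c(0.05, 0.5),
                                 genome_multiplier = c(A = 1, B = 1, D = 0.5),
                                 residual_het = 0.01, missing_rate = 0.02,
                                 dominant_fraction = 0) {
  if (missing(seed)) abort("seed is mandatory")
  groups <- tibble::as_tibble(groups)
  if (any(groups$n < 1)) abort("group sizes must be positive")
  if (any(groups$fst < 0 | groups$fst >= 1)) abort("fst targets must be in [0, 1)")
  set.seed(seed)

  chrn <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  chromosome <- rep_len(chrn, n_markers)
  genome <- genome_of(chromosome)
  cm <- round(runif(n_markers, 0, 150), 4)
  maf_anc <- runif(n_markers, maf_range[1], maf_range[2]) * genome_multiplier[genome]
  maf_anc <- pmin(pmax(maf_anc, 0.001), 0.5)
  # counted-allele frequency: random orientation so "allele A" is not always minor
  p_anc <- ifelse(runif(n_markers) < 0.5, maf_anc, 1 - maf_anc)

  marker_id <- sprintf("AXC_%05d", seq_len(n_markers))
  call_mats <- list()
  part <- list()
  group_freq <- matrix(NA_real_, n_markers, nrow(groups),
                       dimnames = list(marker_id, groups$name))
  for (g in seq_len(nrow(groups))) {
    Fg <- groups$fst[g]
    p_g <- if (Fg > 0) {
      rbeta(n_markers, p_anc * (1 - Fg) / Fg, (1 - p_anc) * (1 - Fg) / Fg)
    } else p_anc
    group_freq[, g] <- p_g
    n <- groups$n[g]
    h_eff <- pmin(residual_het, 2 * p_g, 2 * (1 - p_g))
    p_hom_a <- (p_g - h_eff / 2) / (1 - h_eff)
    u_het <- matrix(runif(n_markers * n), n_markers)
    u_hom <- matrix(runif(n_markers * n), n_markers)
    calls <- ifelse(u_het < h_eff, "AB", ifelse(u_hom < p_hom_a, "AA", "BB"))
    sample_id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", groups$name[g]), seq_len(n))
    colnames(calls) <- sample_id
    call_mats[[g]] <- calls
    part[[g]] <- tibble::tibble(sample_id = sample_id, collection = groups$name[g],
                                region = groups$name[g], year = NA_real_)
  }
  calls <- do.call(cbind, call_mats)
  rownames(calls) <- marker_id

  dominant <- runif(n_markers) < dominant_fraction
  if (any(dominant)) {
    collapse_to <- sample(c("AA", "BB"), n_markers, replace = TRUE)
    het <- calls == "AB"
    coll <- matrix(rep(collapse_to, ncol(calls)), nrow = n_markers)
    calls[dominant & het] <- coll[dominant & het]
  }
  calls[matrix(runif(length(calls)) < missing_rate, nrow = n_markers)] <- "NC"

  is_ts <- runif(n_markers) < 0.688
  ref <- sample(.wba_nucleotides, n_markers, replace = TRUE)
  info <- tibble::tibble(
    marker_id = marker_id,
    contig = sprintf("ctg%05d", ceiling(seq_len(n_markers) / 2)),
    allele_ref = ref, allele_alt = allele_partner(ref, is_ts),
    dominance = ifelse(dominant, "dominant", "codominant"),
    chromosome = chromosome, cM = cm, mapped = TRUE, genome = genome
  )

  list(
    geno = matrix_geno(calls),
    info = info,
    partition = dplyr::bind_rows(part),
    truth = list(groups = groups, p_ancestral = p_anc, group_freq = group_freq)
  )
}

#' Simulate probe intensity matrices with copy-number events
#'
#' Each marker gets a lognormal baseline intensity; a sample's intensity is
#' the baseline scaled by `copy_state / 2` (disomic = 2 copies = scale 1)
#' with multiplicative noise `2^N(0, noise_sd)`. Nullisomic regions
#' (`copy_state = 0`) are floored at a relative intensity of `2^floor_log2`
#' rather than zero, mirroring residual background hybridization. A panel of
#' `n_reference` unaffected reference samples (`REF...`) is appended and
#' recorded in the `"reference_samples"` attribute of the result.
#'
#' @param geno Genotype tibble naming the test samples (calls are not used,
#'   only marker and sample ids).
#' @param info Marker metadata with `chromosome` and `cM` for every marker.
#' @param events Tibble of copy-number events: `sample_id`, `chromosome`,
#'   `start_cM`, `end_cM` (both `NA` for a whole-chromosome event) and
#'   `copy_state` (0 = nullisomic, 1 = monosomic, 2 = normal, 3+ = gain).
#' @param noise_sd Standard deviation of the log2-scale noise.
#' @param seed Random seed (mandatory).
#' @param n_reference Size of the reference panel (>= 20).
#' @param baseline_sdlog Spread of marker baseline intensities (log scale).
#' @param floor_log2 Log2 floor for zero-copy relative intensity.
#' @return Intensity tibble (`marker_id` + one numeric column per sample),
#'   with attribute `reference_samples`.
#' @export
simulate_intensities <- function(geno, info, events, noise_sd = 0.1, seed,
                                 n_reference = 25, baseline_sdlog = 0.3,
                                 floor_log2 = -5) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_reference < 20) abort("reference panel must have at least 20 samples")
  if (any(is.na(info$chromosome)) || any(is.na(info$cM))) {
    abort("all markers need chromosome and cM metadata to simulate intensities")
  }
  set.seed(seed)
  events <- tibble::as_tibble(events)
  info <- dplyr::arrange(info, .data$chromosome, .data$cM)
  M <- nrow(info)
  test_samples <- names(geno)[-1]
  samples <- c(test_samples, sprintf("REF%03d", seq_len(n_reference)))

  copy <- matrix(2, M, length(samples), dimnames = list(info$marker_id, samples))
  if (nrow(events)) {
    if (!all(events$sample_id %in% test_samples)) abort("event sample not in genotype table")
    for (e in seq_len(nrow(events))) {
      on_chr <- info$chromosome == events$chromosome[e]
      sel <- if (is.na(events$start_cM[e])) on_chr else {
        on_chr & info$cM >= events$start_cM[e] & info$cM <= events$end_cM[e]
      }
      if (!any(sel)) {
        abort(sprintf("event %d (%s on %s) contains no markers", e,
                      events$sample_id[e], events$chromosome[e]))
      }
      copy[sel, events$sample_id[e]] <- events$copy_state[e]
    }
  }
  base <- exp(rnorm(M, 0, baseline_sdlog))
  scale <- pmax(copy / 2, 2^floor_log2)
  noise <- matrix(2^rnorm(M * length(samples), 0, noise_sd), M)
  intensity <- base * scale * noise
  out <- tibble::as_tibble(as.data.frame(intensity)) %>%
    dplyr::mutate(marker_id = info$marker_id, .before = 1)
  attr(out, "reference_samples") <- sprintf("REF%03d", seq_len(n_reference))
  out
}

#' Haldane map function
#'
#' Converts between recombination fraction and map distance under Haldane's
#' no-interference model: `d = -50 log(1 - 2r)` cM and
#' `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cM Map distance in centiMorgans.
#' @param r Recombination fraction in `[0, 0.5)`.
#' @name map-functions
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' @rdname map-functions
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * pmin(r, 0.4999))

#' @rdname map-functions
#' @export
kosambi_r <- function(d_cM) tanh(2 * d_cM / 100) / 2

#' @rdname map-functions
#' @export
kosambi_d <- function(r) 25 * log((1 + 2 * pmin(r, 0.4999)) / (1 - 2 * pmin(r, 0.4999)))
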