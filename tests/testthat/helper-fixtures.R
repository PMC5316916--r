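# Small in-code fixtures shared across tests.

# random genotype tibble with controllable missingness
random_geno <- function(n_markers, n_samples, seed, missing = 0.1,
                        calls = c("AA", "AB", "BB")) {
  set.seed(seed)
  m <- matrix(sample(calls, n_markers * n_samples, replace = TRUE), n_markers)
  m[matrix(runif(length(m)) < missing, n_markers)] <- "NC"
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(marker_id = sprintf("m%03d", seq_len(n_markers)), .before = 1)
}

# wide pattern tibble from a character matrix of P1/P2/H/NC codes
pattern_tbl <- function(mat, ids = sprintf("m%03d", seq_len(nrow(mat)))) {
  colnames(mat) <- sprintf("I%03d", seq_len(ncol(mat)))
  tibble::as_tibble(as.data.frame(mat)) |>
    dplyr::mutate(marker_id = ids, .before = 1)
}

# distortion fixture: one marker with n1 P1 calls and n2 P2 calls
distortion_pattern <- function(n1, n2, id = "m1") {
  pattern_tbl(matrix(c(rep("P1", n1), rep("P2", n2)), nrow = 1), ids = id)
}

simple_marker_info <- function(geno, chromosome = NA_character_) {
  n <- nrow(geno)
  complete_marker_info(tibble::tibble(
    marker_id = geno$marker_id,
    contig = sprintf("c%03d", seq_len(n)),
    allele_ref = rep(c("A", "C", "G", "T"), length.out = n),
    allele_alt = rep(c("G", "T", "A", "C"), length.out = n),
    dominance = "codominant",
    chromosome = rep(chromosome, length.out = n),
    cM = ifelse(is.na(rep(chromosome, length.out = n)), NA_real_, as.numeric(seq_len(n)))
  ))
}
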