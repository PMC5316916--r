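# Independent brute-force oracle for the per-contig preference lattice,
# written as plain loops against the rule statement.
oracle_select <- function(cand) {
  out <- list()
  for (ct in sort(unique(cand$contig))) {
    cc <- cand[cand$contig == ct, ]
    if (nrow(cc) == 1L) {
      out[[ct]] <- cc$marker_id
      next
    }
    pool <- cc
    if (any(pool$mapped)) pool <- pool[pool$mapped, ]
    if (any(pool$dominance == "codominant")) pool <- pool[pool$dominance == "codominant", ]
    pic <- 1 - (pool$p^2 + (1 - pool$p)^2) - 2 * pool$p^2 * (1 - pool$p)^2
    best <- which(pic == max(pic))
    out[[ct]] <- sort(pool$marker_id[best])[1]
  }
  unlist(out, use.names = FALSE)
}

random_candidates <- function(n_contigs, seed, max_per_contig = 4) {
  set.seed(seed)
  reps <- sample.int(max_per_contig, n_contigs, replace = TRUE)
  tibble::tibble(
    contig = rep(sprintf("c%04d", seq_len(n_contigs)), reps),
    marker_id = sprintf("snp%05d", sample.int(99999, sum(reps))),
    mapped = runif(sum(reps)) < 0.6,
    dominance = ifelse(runif(sum(reps)) < 0.56, "dominant", "codominant"),
    p = round(runif(sum(reps)), 2)  # rounding induces PIC ties
  )
}

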