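#' Polymorphic information content of a biallelic marker
#'
#' Botstein's PIC for a biallelic locus with allele frequency `p`:
#' `1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`. Symmetric in `p` and `q`,
#' maximal (0.375) at `p = 0.5`, zero for a monomorphic locus; monotone in
#' minor allele frequency, so rankings are robust. Vectorised.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @return PIC score in `[0, 0.375]`.
#' @examples
#' pic_score(0.5)  # 0.375
#' pic_score(0.3)  # 0.3318
#' @export
pic_score <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p must be in [0, 1]")
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Select one informative SNP per contig
#'
#' Reduces a candidate set to a panel with exactly one marker per contig by
#' the preference lattice used in array design: a contig's only SNP is taken
#' as is; otherwise candidates are restricted to genetically *mapped* SNPs if
#' any exist, within that set to *codominant* SNPs if any exist, and the
#' highest-PIC marker of the surviving set is selected (PIC ties broken
#' lexicographically by `marker_id`, so selection is invariant to input
#' order). The rule that fired is recorded per contig.
#'
#' @param candidates Tibble with columns `marker_id`, `contig`, `mapped`
#'   (logical), `dominance` (`"codominant"`/`"dominant"`) and `p` (allele
#'   frequency).
#' @return Tibble with one row per contig: the selected `marker_id`, its
#'   `pic`, the number of candidates `n_candidates` and the `rule` fired
#'   (`unique`, `mapped+codominant+maxPIC`, `mapped+maxPIC`,
#'   `codominant+maxPIC` or `maxPIC`).
#' @export
select_panel <- function(candidates) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0L) abort("empty candidate set")
  if (any(is.na(candidates$contig))) abort("every candidate needs a contig")
  candidates %>%
    dplyr::mutate(pic = pic_score(.data$p)) %>%
    dplyr::group_by(.data$contig) %>%
    dplyr::group_modify(~ select_in_contig(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$contig)
}

select_in_contig <- function(cand) {
  if (nrow(cand) == 1L) {
    return(tibble::tibble(marker_id = cand$marker_id, pic = cand$pic,
                          n_candidates = 1L, rule = "unique"))
  }
  pool <- cand
  used_mapped <- FALSE
  if (any(pool$mapped)) {
    pool <- pool[pool$mapped, , drop = FALSE]
    used_mapped <- TRUE
  }
  used_codom <- FALSE
  if (any(pool$dominance == "codominant")) {
    pool <- pool[pool$dominance == "codominant", , drop = FALSE]
    used_codom <- TRUE
  }
  pool <- pool[order(-pool$pic, pool$marker_id), , drop = FALSE]
  rule <- paste0(c(if (used_mapped) "mapped", if (used_codom) "codominant", "maxPIC"),
                 collapse = "+")
  tibble::tibble(marker_id = pool$marker_id[1], pic = pool$pic[1],
                 n_candidates = nrow(cand), rule = rule)
}

#' Tally counts with one-decimal percentages
#'
#' @param counts Tibble with columns `category` and `count`.
#' @param total Denominator; defaults to the summed counts.
#' @return The input with a `pct` column, `round(100 * count / total, 1)`.
#' @export
summarize_counts <- function(counts, total = sum(counts$count)) {
  dplyr::mutate(tibble::as_tibble(counts), total = total,
                pct = round(100 * .data$count / total, 1))
}

#' Summarise a selected panel
#'
#' Tallies the selected markers by dominance class and by substitution type
#' (transition/transversion), with percentages of the panel size rounded to
#' one decimal.
#'
#' @param selected Result of [select_panel()] (or any tibble with a
#'   `marker_id` column giving the panel).
#' @param info Marker metadata with `dominance`, `allele_ref`, `allele_alt`.
#' @return Tibble with columns `category`, `count`, `total`, `pct`.
#' @export
panel_summary <- function(selected, info) {
  panel <- dplyr::semi_join(info, selected, by = "marker_id")
  n <- nrow(panel)
  if (n == 0L) {
    cats <- c("codominant", "dominant", "transition", "transversion")
    return(tibble::tibble(category = cats, count = 0L, total = 0L, pct = 0))
  }
  subst <- classify_substitution(panel$allele_ref, panel$allele_alt)
  counts <- tibble::tibble(
    category = c("codominant", "dominant", "transition", "transversion"),
    count = c(sum(panel$dominance == "codominant"),
              sum(panel$dominance == "dominant"),
              sum(subst == "transition"),
              sum(subst == "transversion"))
  )
  summarize_counts(counts, total = n)
}

#' Thin a panel to a minimum genetic-map spacing
#'
#' Optional greedy thinning along each chromosome: markers are visited in cM
#' order and kept only if at least `min_gap_cM` from the last kept marker.
#' Unmapped markers are always kept. Off by default in the selection
#' workflow; even genome spacing otherwise emerges from one-per-contig
#' selection.
#'
#' @param selected Tibble with a `marker_id` column.
#' @param info Marker metadata with `chromosome` and `cM`.
#' @param min_gap_cM Minimum spacing between kept markers.
#' @return Filtered copy of `selected`.
#' @export
thin_panel <- function(selected, info, min_gap_cM) {
  pos <- dplyr::left_join(selected, info[, c("marker_id", "chromosome", "cM")],
                          by = "marker_id")
  keep <- pos %>%
    dplyr::filter(!is.na(.data$chromosome)) %>%
    dplyr::arrange(.data$chromosome, .data$cM) %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::filter(greedy_gap_keep(.data$cM, min_gap_cM)) %>%
    dplyr::ungroup()
  dplyr::filter(selected, .data$marker_id %in% keep$marker_id |
                  .data$marker_id %in% pos$marker_id[is.na(pos$chromosome)])
}

greedy_gap_keep <- function(cm, gap) {
  keep <- logical(length(cm))
  last <- -Inf
  for (i in seq_along(cm)) {
    if (cm[i] - last >= gap || is.infinite(last)) {
      keep[i] <- TRUE
      last <- cm[i]
    }
  }
  keep
}
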