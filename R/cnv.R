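#' Read/write intensity tables
#'
#' Intensity TSV: `marker_id` plus one positive real column per sample.
#'
#' @param path File path.
#' @export
read_intensity_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_intensity_table
#' @param intensity Intensity tibble.
#' @export
write_intensity_table <- function(intensity, path) {
  readr::write_tsv(tibble::as_tibble(intensity), path, progress = FALSE)
  invisible(path)
}

#' Log2R copy-number profile of one sample
#'
#' Per-marker `Log2R = log2(sample intensity / reference median intensity)`,
#' floored at `floor_log2`, optionally median-centred per sample (absorbing
#' array-level brightness differences so that calls are invariant to a
#' uniform scaling of the sample), and smoothed with a running median of
#' `window` markers along each chromosome (ordered by cM). A marker equal to
#' the reference median has Log2R 0; a single-copy loss from disomy sits
#' near -1 (`log2(1/2)`), a single-copy gain near +0.585 (`log2(3/2)`).
#'
#' @param intensity Intensity tibble (`marker_id` + sample columns).
#' @param info Marker metadata with `chromosome` and `cM`.
#' @param sample_id Sample to profile.
#' @param reference_samples Reference panel column names (>= `min_reference`);
#'   defaults to the tibble's `"reference_samples"` attribute.
#' @param window Running-median window in markers (odd; default 15).
#' @param floor_log2 Lower bound applied to Log2R (default -5).
#' @param center Median-centre the sample's Log2R track (default TRUE).
#' @param min_reference Minimum reference panel size (default 20).
#' @return A `wba_cnv_profile` tibble: `marker_id`, `chromosome`, `cM`,
#'   `log2r`, `smoothed`; attribute `sample_id`.
#' @export
log2r_profile <- function(intensity, info, sample_id,
                          reference_samples = attr(intensity, "reference_samples"),
                          window = 15, floor_log2 = -5, center = TRUE,
                          min_reference = 20) {
  if (is.null(reference_samples)) abort("reference_samples must be declared")
  if (length(reference_samples) < min_reference) {
    abort(sprintf("reference panel too small (%d < %d)",
                  length(reference_samples), min_reference))
  }
  if (!all(c(sample_id, reference_samples) %in% names(intensity))) {
    abort("sample or reference columns missing from the intensity table")
  }
  vals <- as.matrix(intensity[, c(sample_id, reference_samples)])
  if (any(vals <= 0, na.rm = TRUE)) abort("intensities must be positive")
  ref_med <- apply(intensity[, reference_samples], 1, median)
  lr <- pmax(log2(intensity[[sample_id]] / ref_med), floor_log2)
  prof <- tibble::tibble(marker_id = intensity$marker_id, log2r = lr) %>%
    dplyr::inner_join(info[, c("marker_id", "chromosome", "cM")], by = "marker_id") %>%
    dplyr::arrange(.data$chromosome, .data$cM)
  if (any(is.na(prof$chromosome)) || nrow(prof) < nrow(intensity)) {
    abort("profiling needs chromosome/cM metadata for every marker, ordered along the map")
  }
  if (center) prof$log2r <- prof$log2r - median(prof$log2r)
  prof <- prof %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::mutate(smoothed = run_median(.data$log2r, window)) %>%
    dplyr::ungroup() %>%
    dplyr::select("marker_id", "chromosome", "cM", "log2r", "smoothed")
  structure(prof, sample_id = sample_id, window = window,
            class = c("wba_cnv_profile", class(prof)))
}

run_median <- function(x, window) {
  k <- min(window, length(x))
  if (k %% 2 == 0) k <- k - 1
  if (k < 3) return(x)
  as.numeric(runmed(x, k, endrule = "median"))
}

#' Call copy-number loss and gain segments
#'
#' Scans the smoothed Log2R track for maximal runs of consecutive markers
#' below `loss_thresh` or above `gain_thresh` with at least `min_markers`
#' markers. Default thresholds are the midpoints separating the expected
#' Log2R of copy states 1 (-1), 2 (0) and 3 (+0.585). Each call is classed
#' `whole-chromosome` when it covers at least 90% of the chromosome's
#' markers, `arm/telomeric` when anchored at a chromosome end and covering
#' at least 25%, otherwise `segmental`.
#'
#' @param profile A [log2r_profile()].
#' @param loss_thresh,gain_thresh Smoothed Log2R thresholds.
#' @param min_markers Minimum run length in markers.
#' @return Tibble of calls: `sample_id`, `chromosome`, `start_cM`, `end_cM`,
#'   `n_markers`, `direction`, `mean_smoothed`, `class`.
#' @export
call_cnv <- function(profile, loss_thresh = -0.5, gain_thresh = 0.4,
                     min_markers = 10) {
  sample_id <- attr(profile, "sample_id") %||% NA_character_
  calls <- tibble::as_tibble(profile) %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::group_map(function(d, key) {
      state <- ifelse(d$smoothed <= loss_thresh, "loss",
                      ifelse(d$smoothed >= gain_thresh, "gain", "normal"))
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != "normal" & r$lengths >= min_markers
      if (!any(keep)) return(NULL)
      purrr::map_dfr(which(keep), function(i) {
        idx <- starts[i]:ends[i]
        frac <- length(idx) / nrow(d)
        at_end <- starts[i] == 1L || ends[i] == nrow(d)
        tibble::tibble(
          chromosome = key$chromosome,
          start_cM = d$cM[starts[i]], end_cM = d$cM[ends[i]],
          n_markers = length(idx),
          direction = r$values[i],
          mean_smoothed = mean(d$smoothed[idx]),
          class = if (frac >= 0.9) "whole-chromosome"
                  else if (at_end && frac >= 0.25) "arm/telomeric"
                  else "segmental"
        )
      })
    }) %>%
    dplyr::bind_rows()
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(chromosome = character(), start_cM = double(),
                            end_cM = double(), n_markers = integer(),
                            direction = character(), mean_smoothed = double(),
                            class = character())
  }
  dplyr::mutate(calls, sample_id = sample_id, .before = 1)
}
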