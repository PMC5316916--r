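#' Bundled reference tables for the 35K wheat breeders' array
#'
#' Published summary counts for the 35,143-SNP breeders' genotyping array:
#' `array_panel_counts()` returns panel-level marker tallies (candidate pool
#' size, dominance classes, substitution classes, polymorphic markers in the
#' global germplasm screen); `mapping_population_table()` describes the five
#' biparental mapping populations used to build its consensus genetic map
#' (design, size, parent-polymorphic and mapped marker counts).
#'
#' @return A tibble.
#' @export
array_panel_counts <- function() {
  readr::read_tsv(system.file("extdata", "breeders_array_counts.tsv", package = "wbatk"),
                  col_types = "ci", progress = FALSE)
}

#' @rdname array_panel_counts
#' @export
mapping_population_table <- function() {
  readr::read_tsv(system.file("extdata", "mapping_populations.tsv", package = "wbatk"),
                  col_types = "cccciiii", progress = FALSE)
}

#' Anchor linkage groups to named chromosomes
#'
#' Renames each linkage group of a de novo map to the majority chromosome of
#' its markers according to existing marker annotation (e.g. the array's
#' consensus positions), so that component maps from different populations
#' share a nomenclature before consensus merging.
#'
#' @param map A map tibble (`chromosome`, `marker_id`, `position_cM`).
#' @param info Marker metadata with a `chromosome` column.
#' @return The map with renamed chromosomes.
#' @export
anchor_chromosomes <- function(map, info) {
  votes <- tibble::as_tibble(map) %>%
    dplyr::left_join(info[, c("marker_id", "chromosome")], by = "marker_id",
                     suffix = c("", ".known")) %>%
    dplyr::filter(!is.na(.data$chromosome.known)) %>%
    dplyr::count(.data$chromosome, .data$chromosome.known) %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  lookup <- setNames(votes$chromosome.known, votes$chromosome)
  out <- map
  renamed <- unname(lookup[out$chromosome])
  out$chromosome <- ifelse(is.na(renamed), out$chromosome, renamed)
  out
}

#' Default demonstration pipeline configuration
#'
#' A small fully synthetic end-to-end configuration: two biparental
#' populations mapped and merged, three structured collections analysed for
#' diversity, and two copy-number event samples profiled. Every stochastic
#' stage derives its stream from the single `seed`.
#'
#' @param seed Master seed.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 20160101) {
  list(
    seed = seed,
    stages = c("simulate", "panel", "map", "diversity", "cnv"),
    map = list(n_chromosomes = 2, length_cM = 120, markers_per_chromosome = 40),
    populations = list(
      list(name = "popA", design = "DH", n_individuals = 100),
      list(name = "popB", design = "RIL_F6", n_individuals = 80)
    ),
    biparental = list(missing_rate = 0.05, dominant_fraction = 0.3,
                      polymorphic_fraction = 0.8),
    collections = list(groups = tibble::tibble(name = c("elite", "landrace", "synthetic"),
                                               n = c(30, 30, 20),
                                               fst = c(0.05, 0.08, 0.12)),
                       n_markers = 400),
    cnv = list(noise_sd = 0.12,
               events = tibble::tibble(sample_id = c("elite_001", "elite_002"),
                                       chromosome = c("1A", "2B"),
                                       start_cM = c(NA, 40), end_cM = c(NA, 110),
                                       copy_state = c(1, 3)))
  )
}

validate_config <- function(config) {
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    abort("config validation: a numeric `seed` is required for the stochastic stages")
  }
  stages <- config$stages %||% c("simulate", "panel", "map", "diversity", "cnv")
  known <- c("simulate", "panel", "map", "diversity", "cnv")
  if (!all(stages %in% known)) {
    abort(sprintf("unknown stage: %s", setdiff(stages, known)[1]))
  }
  if (any(c("panel", "map", "diversity", "cnv") %in% stages) &&
      !("simulate" %in% stages)) {
    abort("stage dependency violated: analysis stages require the simulate stage")
  }
  stages
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the configured stages (simulate, panel, map, diversity, cnv) in
#' order, writing each stage's tables as TSV files plus a JSON manifest
#' recording the package version, a hash of the configuration and the MD5
#' checksum of every output, so that a rerun with the same configuration is
#' verifiably bit-identical. Logging records marker/sample counts in and out
#' of every filtering step.
#'
#' @param config Configuration list, see [demo_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = demo_config(), out_dir, quiet = TRUE) {
  stages <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }
  seed <- as.integer(config$seed)

  sim <- NULL; coll <- NULL
  if ("simulate" %in% stages) {
    mp <- config$map %||% list()
    map <- sim_map_regular(n_chromosomes = mp$n_chromosomes %||% 2,
                           length_cM = mp$length_cM %||% 120,
                           markers_per_chromosome = mp$markers_per_chromosome %||% 40)
    bp <- config$biparental %||% list()
    sim <- purrr::imap(config$populations %||% list(), function(popcfg, k) {
      s <- simulate_biparental(
        map, design = popcfg$design, n_individuals = popcfg$n_individuals,
        missing_rate = bp$missing_rate %||% 0.05,
        dominant_fraction = bp$dominant_fraction %||% 0.562,
        polymorphic_fraction = bp$polymorphic_fraction %||% 0.25,
        seed = seed + k
      )
      write_genotype_table(s$geno, keep(file.path(out_dir, sprintf("%s_geno.tsv", popcfg$name))))
      say("simulate: population %s, %d markers x %d individuals",
          popcfg$name, nrow(s$geno), ncol(s$geno) - 1L)
      c(s, name = popcfg$name)
    })
    if (length(sim)) {
      write_marker_info(sim[[1]]$info, keep(file.path(out_dir, "biparental_marker_info.tsv")))
    }
    cc <- config$collections %||% list()
    coll <- simulate_collections(cc$groups %||% demo_config()$collections$groups,
                                 n_markers = cc$n_markers %||% 400, seed = seed + 100)
    write_genotype_table(coll$geno, keep(file.path(out_dir, "collections_geno.tsv")))
    write_marker_info(coll$info, keep(file.path(out_dir, "collections_marker_info.tsv")))
    readr::write_tsv(coll$partition, keep(file.path(out_dir, "collections_samples.tsv")),
                     progress = FALSE)
    say("simulate: collections, %d markers x %d samples",
        nrow(coll$geno), ncol(coll$geno) - 1L)
  }

  if ("panel" %in% stages) {
    freq <- allele_frequencies(coll$geno, coll$partition)
    pooled <- dplyr::filter(freq, .data$collection == ".pooled")
    candidates <- coll$info %>%
      dplyr::transmute(.data$marker_id, contig = .data$contig, mapped = .data$mapped,
                       dominance = .data$dominance,
                       p = pooled$p[match(.data$marker_id, pooled$marker_id)]) %>%
      dplyr::filter(!is.na(.data$p))
    selected <- select_panel(candidates)
    readr::write_tsv(selected, keep(file.path(out_dir, "panel_selected.tsv")), progress = FALSE)
    readr::write_tsv(panel_summary(selected, coll$info),
                     keep(file.path(out_dir, "panel_summary.tsv")), progress = FALSE)
    say("panel: %d candidates -> %d selected (one per contig)",
        nrow(candidates), nrow(selected))
  }

  if ("map" %in% stages) {
    maps <- list(); distorted <- character(0)
    for (s in sim) {
      lm <- build_linkage_map(s$geno, design = s$truth$design, population = s$name)
      lm_anchored <- anchor_chromosomes(lm, s$info)
      write_linkage_map(lm_anchored, keep(file.path(out_dir, sprintf("map_%s.tsv", s$name))))
      kept_geno <- s$geno[s$geno$marker_id %in% lm$marker_id, , drop = FALSE]
      scan <- distortion_scan(as_seg_patterns(kept_geno), map = lm_anchored)
      readr::write_tsv(scan, keep(file.path(out_dir, sprintf("distortion_%s.tsv", s$name))),
                       progress = FALSE)
      distorted <- union(distorted, scan$marker_id[scan$significant])
      attr(lm_anchored, "n_individuals") <- attr(lm, "n_individuals")
      maps[[s$name]] <- lm_anchored
      say("map: %s placed %d markers (%d dropped), %d distorted",
          s$name, nrow(lm), nrow(attr(lm, "dropped")), sum(scan$significant))
    }
    if (length(maps) >= 2) {
      ambiguous <- ambiguous_markers(maps)
      say("map: excluding %d distorted and %d ambiguous markers before consensus",
          length(distorted), length(ambiguous))
      cons <- merge_consensus(maps, exclude = union(distorted, ambiguous))
      write_linkage_map(cons, keep(file.path(out_dir, "map_consensus.tsv")))
      readr::write_tsv(tibble::as_tibble(cons)[, c("marker_id", "provenance")],
                       keep(file.path(out_dir, "consensus_provenance.tsv")), progress = FALSE)
      say("map: consensus of %d maps places %d markers", length(maps), nrow(cons))
    }
  }

  if ("diversity" %in% stages) {
    freq <- allele_frequencies(coll$geno, coll$partition)
    readr::write_tsv(diversity_summary(freq),
                     keep(file.path(out_dir, "diversity_summary.tsv")), progress = FALSE)
    dm <- differentiation_matrix(coll$geno, coll$partition)
    readr::write_tsv(tidy(dm), keep(file.path(out_dir, "differentiation.tsv")), progress = FALSE)
    readr::write_tsv(maf_by_genome(freq, coll$info),
                     keep(file.path(out_dir, "maf_by_genome.tsv")), progress = FALSE)
    pcoa <- classical_mds(ibs_similarity(coll$geno), n_axes = 2)
    readr::write_tsv(dplyr::left_join(tidy(pcoa), coll$partition, by = "sample_id"),
                     keep(file.path(out_dir, "pcoa_coordinates.tsv")), progress = FALSE)
    sizes <- unique(pmin(c(2, 5, 10, 20), max(table(coll$partition$collection))))
    rar <- polymorphism_rarefaction(coll$geno, coll$partition, sizes = sizes,
                                    n_reps = 10, seed = seed + 200)
    readr::write_tsv(rar, keep(file.path(out_dir, "rarefaction.tsv")), progress = FALSE)
    say("diversity: %d collections summarised", dplyr::n_distinct(coll$partition$collection))
  }

  if ("cnv" %in% stages) {
    cnv_cfg <- config$cnv %||% list()
    events <- cnv_cfg$events %||% demo_config()$cnv$events
    intensity <- simulate_intensities(coll$geno, coll$info, events,
                                      noise_sd = cnv_cfg$noise_sd %||% 0.12,
                                      seed = seed + 300)
    write_intensity_table(intensity, keep(file.path(out_dir, "intensities.tsv")))
    calls <- purrr::map_dfr(unique(events$sample_id), function(sid) {
      prof <- log2r_profile(intensity, coll$info, sid)
      readr::write_tsv(prof, keep(file.path(out_dir, sprintf("cnv_profile_%s.tsv", sid))),
                       progress = FALSE)
      call_cnv(prof)
    })
    readr::write_tsv(calls, keep(file.path(out_dir, "cnv_calls.tsv")), progress = FALSE)
    say("cnv: %d calls across %d samples", nrow(calls), dplyr::n_distinct(events$sample_id))
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "wbatk",
    version = as.character(utils::packageVersion("wbatk")),
    stages = stages,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = unname(tools::md5sum(tf)),
    files = lapply(sort(unique(files)), function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' Builds a human-readable markdown report of a [run_pipeline()] output
#' directory: panel tallies, per-population and consensus map sizes, the
#' diversity summary table and copy-number calls. Regeneration is
#' idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param file Output file (default `report.md` inside `run_dir`).
#' @return The report lines, invisibly.
#' @export
report_summary <- function(run_dir, file = file.path(run_dir, "report.md")) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) abort(sprintf("%s: not a completed run (no manifest)", run_dir))
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c("# Pipeline run summary", "",
             sprintf("Package wbatk %s; config hash %s.", manifest$version, manifest$config_md5), "")
  tsv <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE, progress = FALSE) else NULL
  }
  fmt <- function(df) c(paste(names(df), collapse = " | "),
                        paste(rep("---", ncol(df)), collapse = " | "),
                        apply(df, 1, paste, collapse = " | "))
  ps <- tsv("panel_summary.tsv")
  if (!is.null(ps)) lines <- c(lines, "## Panel selection", "", fmt(ps), "")
  for (f in list.files(run_dir, pattern = "^map_.*\\.tsv$")) {
    mp <- tsv(f)
    bychr <- mp %>% dplyr::group_by(.data$chromosome) %>%
      dplyr::summarise(n_markers = dplyr::n(),
                       length_cM = round(max(.data$position_cM), 1), .groups = "drop")
    lines <- c(lines, sprintf("## %s", sub("\\.tsv$", "", f)), "", fmt(bychr), "")
  }
  ds <- tsv("diversity_summary.tsv")
  if (!is.null(ds)) {
    ds <- dplyr::mutate(ds, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
    lines <- c(lines, "## Diversity", "", fmt(ds), "")
  }
  cnv <- tsv("cnv_calls.tsv")
  if (!is.null(cnv)) lines <- c(lines, "## Copy-number calls", "", fmt(cnv), "")
  writeLines(lines, file)
  invisible(lines)
}
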