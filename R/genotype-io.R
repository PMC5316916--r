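#' Genotype tables
#'
#' A genotype table is a wide tibble: first column `marker_id`, one further
#' column per sample, cells holding calls in `AA`, `AB`, `BB`, `NC`
#' (`NC` = no-call). `NC` is excluded from every frequency computation in the
#' package. Marker metadata travels in a sidecar tibble (see
#' [read_marker_info()]).
#'
#' @param geno A genotype tibble.
#' @return `validate_genotypes()` returns its input invisibly, or errors.
#' @name genotype-table
NULL

#' @rdname genotype-table
#' @export
validate_genotypes <- function(geno) {
  if (!is.data.frame(geno) || ncol(geno) < 1L || names(geno)[1] != "marker_id") {
    abort("genotype table must be a data frame whose first column is `marker_id`")
  }
  if (anyDuplicated(geno$marker_id)) {
    abort(paste0("duplicate marker ids: ",
                 paste(unique(geno$marker_id[duplicated(geno$marker_id)]), collapse = ", ")))
  }
  samples <- names(geno)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  for (s in samples) {
    bad <- which(!(geno[[s]] %in% .wba_calls))
    if (length(bad)) {
      abort(sprintf("unknown call token \"%s\" at marker \"%s\", sample \"%s\"",
                    geno[[s]][bad[1]], geno$marker_id[bad[1]], s))
    }
  }
  invisible(geno)
}

# markers x samples character matrix, rownames = marker ids
geno_matrix <- function(geno) {
  m <- as.matrix(geno[, -1, drop = FALSE])
  rownames(m) <- geno$marker_id
  m
}

matrix_geno <- function(m) {
  tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE)) %>%
    dplyr::mutate(marker_id = rownames(m), .before = 1)
}

#' Read and write genotype tables
#'
#' The genotype TSV dialect is UTF-8, tab-separated, with a header row
#' `marker_id` followed by sample ids, and one row per marker. On read, the
#' missing tokens `NC`, `NoCall`, `NN` and `-` are all mapped to `NC`; any
#' other token outside `AA`/`AB`/`BB` is an error naming the offending row and
#' column (never a silent no-call). On write the single canonical missing
#' token `NC` is used, so write–read round-trips are the identity.
#'
#' @param path Path to a genotype TSV file.
#' @return A genotype tibble (see [genotype-table]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' g <- tibble::tibble(marker_id = c("m1", "m2"), S1 = c("AA", "AB"), S2 = c("BB", "NC"))
#' write_genotype_table(g, tf)
#' identical(read_genotype_table(tf), g)
#' @export
read_genotype_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 1L || names(tab)[1] != "marker_id") {
    abort(sprintf("%s: first column must be named `marker_id`", path))
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: ragged or malformed rows (e.g. row %d)", path, prob$row[1]))
  }
  for (s in names(tab)[-1]) {
    x <- tab[[s]]
    x[x %in% .wba_missing_tokens] <- "NC"
    tab[[s]] <- x
  }
  validate_genotypes(tab)
  tab
}

#' @rdname read_genotype_table
#' @param geno A genotype tibble.
#' @export
write_genotype_table <- function(geno, path) {
  validate_genotypes(geno)
  readr::write_tsv(geno, path, progress = FALSE)
  invisible(path)
}

#' Read marker metadata
#'
#' The marker metadata sidecar TSV has columns `marker_id`, `contig`,
#' `allele_ref`, `allele_alt`, `dominance` (`codominant`/`dominant`),
#' `chromosome` and `cM` (the last two may be empty for unmapped markers).
#' A `genome` column (`A`/`B`/`D` subgenome) is derived from the chromosome
#' name (e.g. `"5B"` -> `"B"`) when absent, and a logical `mapped` column from
#' the presence of a chromosome.
#'
#' @param path Path to a marker metadata TSV.
#' @return A tibble of marker metadata.
#' @export
read_marker_info <- function(path) {
  info <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    contig = readr::col_character(),
    allele_ref = readr::col_character(),
    allele_alt = readr::col_character(),
    dominance = readr::col_character(),
    chromosome = readr::col_character(),
    cM = readr::col_double()
  ), progress = FALSE)
  complete_marker_info(info)
}

#' @rdname read_marker_info
#' @param info A marker metadata tibble.
#' @export
complete_marker_info <- function(info) {
  if (anyDuplicated(info$marker_id)) abort("duplicate marker ids in marker info")
  bad <- !is.na(info$allele_ref) & !is.na(info$allele_alt) &
    info$allele_ref == info$allele_alt
  if (any(bad)) {
    abort(sprintf("marker \"%s\": allele_ref equals allele_alt", info$marker_id[which(bad)[1]]))
  }
  if (any(!is.na(info$cM) & is.na(info$chromosome))) {
    abort("cM position present for a marker without a chromosome")
  }
  info %>%
    dplyr::mutate(
      mapped = !is.na(.data$chromosome),
      genome = genome_of(.data$chromosome)
    )
}

#' @rdname read_marker_info
#' @export
write_marker_info <- function(info, path) {
  cols <- intersect(c("marker_id", "contig", "allele_ref", "allele_alt",
                      "dominance", "chromosome", "cM"), names(info))
  readr::write_tsv(info[, cols], path, progress = FALSE)
  invisible(path)
}

# Subgenome letter from a wheat chromosome name such as "5B" or "chr3D".
genome_of <- function(chromosome) {
  g <- sub("^.*([ABD])$", "\\1", chromosome)
  ifelse(g %in% c("A", "B", "D"), g, NA_character_)
}

#' Read sample metadata
#'
#' Sample metadata TSV: columns `sample_id`, `collection`, `region`, `year`.
#'
#' @param path Path to a sample metadata TSV.
#' @return A tibble of sample metadata.
#' @export
read_sample_info <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    collection = readr::col_character(),
    region = readr::col_character(),
    year = readr::col_double()
  ), progress = FALSE)
}

#' Per-sample call-rate and heterozygosity statistics
#'
#' For each sample, `call_rate` is the fraction of markers with a call other
#' than `NC`, and `het_rate` the fraction of called markers with an `AB`
#' call. `het_rate` is `NA` for a sample with no calls at all. On good array
#' data call rates cluster near 0.98; samples pairing a low call rate with an
#' elevated het rate are the classic signature of poor-quality DNA.
#'
#' @param geno A genotype tibble.
#' @return A tibble with columns `sample_id`, `n_called`, `call_rate`,
#'   `het_rate`.
#' @export
sample_qc <- function(geno) {
  validate_genotypes(geno)
  m <- geno_matrix(geno)
  if (nrow(m) == 0L) abort("empty genotype table")
  called <- colSums(m != "NC")
  het <- colSums(m == "AB")
  tibble::tibble(
    sample_id = colnames(m),
    n_called = as.integer(unname(called)),
    call_rate = unname(called) / nrow(m),
    het_rate = unname(ifelse(called > 0, het / called, NA_real_))
  )
}

#' Classify a nucleotide substitution
#'
#' A&harr;G and C&harr;T pairs are transitions; all other distinct nucleotide
#' pairs are transversions. Vectorised.
#'
#' @param allele_ref,allele_alt Nucleotides in `A`, `C`, `G`, `T`.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("A", "C")  # transversion
#' @export
classify_substitution <- function(allele_ref, allele_alt) {
  ok <- allele_ref %in% .wba_nucleotides & allele_alt %in% .wba_nucleotides
  if (!all(ok)) abort("alleles must be nucleotides in A, C, G, T")
  if (any(allele_ref == allele_alt)) abort("alleles must be distinct")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[allele_ref] == purine[allele_alt], "transition", "transversion"))
}

#' Export genotypes to a minimal VCF 4.2 file
#'
#' Genetic-map coordinates are not physical coordinates, so `POS` is the
#' *rank* of the marker within its chromosome (ordered by cM, ties and
#' unmapped markers by input order); the cM position itself is carried in the
#' `CM` INFO key. This is stated loudly in the header. Unmapped markers are
#' written on the pseudo-chromosome `un`. Genotypes map as AA&rarr;`0/0`,
#' AB&rarr;`0/1`, BB&rarr;`1/1`, NC&rarr;`./.`.
#'
#' @param geno A genotype tibble.
#' @param info Marker metadata (needs `allele_ref`/`allele_alt`; `chromosome`
#'   and `cM` used when present).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, info, path) {
  validate_genotypes(geno)
  samples <- names(geno)[-1]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=wbatk",
    "##WARNING=POS is the marker rank within its chromosome on the genetic map, NOT a physical base-pair coordinate",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in centiMorgans\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
  if (nrow(geno) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ord <- dplyr::left_join(geno["marker_id"], info, by = "marker_id")
  if (any(is.na(ord$allele_ref) | is.na(ord$allele_alt))) {
    abort(sprintf("marker \"%s\" lacks alleles; cannot export to VCF",
                  ord$marker_id[which(is.na(ord$allele_ref) | is.na(ord$allele_alt))[1]]))
  }
  chrom <- ifelse(is.na(ord$chromosome), "un", ord$chromosome)
  cm <- if ("cM" %in% names(ord)) ord$cM else rep(NA_real_, nrow(ord))
  o <- order(chrom, ifelse(is.na(cm), Inf, cm), seq_len(nrow(ord)))
  pos <- integer(nrow(ord))
  pos[o] <- stats::ave(seq_along(o), chrom[o], FUN = seq_along)
  gt_of <- c(AA = "0/0", AB = "0/1", BB = "1/1", NC = "./.")
  m <- geno_matrix(geno)
  gt <- matrix(gt_of[m], nrow = nrow(m))
  body <- paste(
    chrom, pos, ord$marker_id, ord$allele_ref, ord$allele_alt, ".", ".",
    ifelse(is.na(cm), ".", sprintf("CM=%.4f", cm)), "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body[o]), path)
  invisible(path)
}
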