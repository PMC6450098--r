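#' G+C content of a nucleotide sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T), case-insensitive. Ambiguity
#' codes (N, R, Y, ...) are excluded from both numerator and denominator,
#' the usual convention for reporting the G+C content of a sequenced
#' genome.
#'
#' @param seq Nucleotide sequence: a single string or a
#'   [Biostrings::DNAString].
#' @return G+C fraction in \[0, 1\].
#' @examples
#' gc_content("ACGT") # 0.5
#' gc_content("ACGTN") # 0.5, N excluded
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1, nchar(seq) > 0)
  chars <- strsplit(seq, "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  if (gc + at == 0) rlang::abort("no unambiguous A/C/G/T residues in sequence.")
  gc / (gc + at)
}

#' Windowed G+C track
#'
#' Tiles the sequence with non-overlapping windows (default 2.5 kb, the
#' window used for the genome-plot G+C ring) and computes the G+C
#' fraction of each. A trailing partial window is kept iff its length is
#' at least `min_partial` (default `window / 2`); the kept span is
#' reported so the length-weighted mean of window values equals the
#' global G+C of the covered span.
#'
#' @param seq Nucleotide sequence (string or DNAString).
#' @param window Window size in bp (default 2500).
#' @param step Step size in bp; only `step == window` (tiling) is
#'   supported.
#' @param min_partial Minimum trailing window length to keep.
#' @return A tibble (`gc_track`) with 1-based `start`, `end`,
#'   `window_length`, `gc_fraction`.
#' @export
windowed_gc <- function(seq, window = 2500, step = window,
                        min_partial = ceiling(window / 2)) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1, window >= 1, step == window)
  n <- nchar(seq)
  if (window > n) {
    rlang::warn("window longer than sequence; returning one whole-sequence window.")
    window <- n
  }
  starts <- seq.int(1, n, by = window)
  ends <- pmin(starts + window - 1, n)
  lens <- ends - starts + 1
  keep <- lens == window | lens >= min_partial
  starts <- starts[keep]; ends <- ends[keep]; lens <- lens[keep]
  gc <- vapply(seq_along(starts), function(i) {
    gc_content(substring(seq, starts[i], ends[i]))
  }, numeric(1))
  out <- tibble::tibble(
    start = as.integer(starts), end = as.integer(ends),
    window_length = as.integer(lens), gc_fraction = gc
  )
  class(out) <- c("gc_track", class(out))
  out
}

#' Write a G+C track as a BED-like TSV
#'
#' Four columns: chrom, 0-based start, end, gc fraction.
#'
#' @param track A [windowed_gc()] result.
#' @param path Output path.
#' @param chrom Chromosome/contig name to use (default "genome").
#' @return `path`, invisibly.
#' @export
write_gc_track <- function(track, path, chrom = "genome") {
  bed <- tibble::tibble(
    chrom = chrom,
    start0 = track$start - 1L,
    end = track$end,
    gc = track$gc_fraction
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Theoretical coding density
#'
#' Fraction of the genome covered by at least one annotated ORF, both
#' strands projected to a single axis; overlapping bases are counted
#' once (interval union). `method = "sum"` instead sums ORF lengths
#' without merging, for sensitivity analysis.
#'
#' @param orfs Data frame with 1-based inclusive `start`, `end` columns.
#' @param genome_length Genome length in bp.
#' @param method `"union"` (default) or `"sum"`.
#' @return Coding density fraction.
#' @examples
#' coding_density(data.frame(start = c(1, 401), end = c(500, 600)), 1000)
#' @export
coding_density <- function(orfs, genome_length, method = c("union", "sum")) {
  method <- match.arg(method)
  stopifnot(genome_length >= 1)
  if (nrow(orfs) == 0) return(0)
  stopifnot(all(orfs$start <= orfs$end), all(orfs$start >= 1),
            all(orfs$end <= genome_length))
  covered <- if (method == "union") {
    ir <- IRanges::IRanges(start = orfs$start, end = orfs$end)
    sum(IRanges::width(IRanges::reduce(ir)))
  } else {
    sum(orfs$end - orfs$start + 1)
  }
  covered / genome_length
}

#' Proportion of basic residues in a protein
#'
#' Count of residues in `basic_set` divided by protein length. Core
#' histones are enriched in basic residues (K, R, H) that contact the
#' negatively charged DNA backbone; `basic_set = c("K", "R")` is offered
#' for the stricter definition.
#'
#' @param protein Protein sequence (single string).
#' @param basic_set Residues counted as basic (default K, R, H).
#' @return Fraction in \[0, 1\].
#' @examples
#' basic_fraction("KKRR") # 1
#' basic_fraction("KRHG", basic_set = c("K", "R")) # 0.5
#' @export
basic_fraction <- function(protein, basic_set = c("K", "R", "H")) {
  stopifnot(length(protein) == 1, nchar(protein) > 0)
  chars <- strsplit(toupper(protein), "")[[1]]
  sum(chars %in% basic_set) / length(chars)
}

#' Closest-homolog taxonomy tally
#'
#' Partitions a set of ORFs by the taxonomy of their closest (best-hit)
#' homolog; ORFs with no retained hit are ORFans. Percentages are
#' reported to the nearest integer.
#'
#' @param assignments Data frame with columns `orf_id` and `taxonomy`
#'   (one of eukaryotic/viral/prokaryotic/unclassified, or `NA` for an
#'   ORFan).
#' @return Tibble with one row per class: `class`, `n`, `percent`.
#' @export
taxonomy_tally <- function(assignments) {
  classes <- c("eukaryotic", "viral", "prokaryotic", "unclassified", "ORFan")
  tax <- as.character(assignments$taxonomy)
  tax[is.na(tax)] <- "ORFan"
  stopifnot(all(tax %in% classes))
  n_total <- length(tax)
  tibble::tibble(class = factor(tax, levels = classes)) |>
    dplyr::count(.data$class, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      class = as.character(.data$class),
      percent = if (n_total > 0) round(100 * .data$n / n_total) else 0
    )
}

#' Group summaries of G+C percentages
#'
#' Per-group max, min, mean, median and sample (n-1 denominator)
#' standard deviation of G+C percentages, as in genome-census
#' comparisons across virus families. `sd` is `NA` for single-genome
#' groups. `display` columns round to 2 decimals.
#'
#' @param values Data frame with columns `group` and `gc_percent`.
#' @return Tibble, one row per group: `group`, `n`, `max`, `min`,
#'   `mean`, `median`, `sd`.
#' @examples
#' gc_summary_by_group(data.frame(
#'   group = "Pandoraviruses", gc_percent = c(63.66, 61.72, 60.66)
#' ))
#' @export
gc_summary_by_group <- function(values) {
  stopifnot(all(c("group", "gc_percent") %in% names(values)))
  if (any(is.na(values$gc_percent))) rlang::abort("NA G+C values not allowed.")
  values |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      max = max(.data$gc_percent),
      min = min(.data$gc_percent),
      mean = mean(.data$gc_percent),
      median = stats::median(.data$gc_percent),
      sd = if (dplyr::n() > 1) stats::sd(.data$gc_percent) else NA_real_,
      .groups = "drop"
    )
}

#' NCLDV core-gene census
#'
#' Counts distinct ORFs and distinct NCVOGs (Nucleo-Cytoplasmic Virus
#' Orthologous Groups) in a core-gene annotation table, plus per
#' functional-category NCVOG counts. Rows may list several
#' comma-separated ORF ids per NCVOG (paralogs assigned to the same
#' orthologous group).
#'
#' @param annotation Data frame with columns `ncvog_id`, `orf_id`
#'   (possibly comma-separated), `functional_category`.
#' @return List with `n_core_orfs`, `n_ncvogs` and a `by_category`
#'   tibble (`functional_category`, `n_ncvogs`).
#' @export
core_gene_census <- function(annotation) {
  if (nrow(annotation) == 0) {
    return(list(n_core_orfs = 0L, n_ncvogs = 0L,
                by_category = tibble::tibble(functional_category = character(),
                                             n_ncvogs = integer())))
  }
  stopifnot(all(c("ncvog_id", "orf_id", "functional_category") %in%
                  names(annotation)))
  orf_long <- annotation |>
    tibble::as_tibble() |>
    tidyr::separate_longer_delim("orf_id", delim = ",") |>
    dplyr::mutate(orf_id = stringr::str_trim(.data$orf_id))
  dup <- orf_long |>
    dplyr::distinct(.data$orf_id, .data$ncvog_id) |>
    dplyr::count(.data$orf_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::warn(sprintf("ORF(s) %s assigned to more than one NCVOG; counted once.",
                        paste(dup$orf_id, collapse = ", ")))
  }
  by_cat <- annotation |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$ncvog_id, .data$functional_category) |>
    dplyr::count(.data$functional_category, name = "n_ncvogs")
  list(
    n_core_orfs = dplyr::n_distinct(orf_long$orf_id),
    n_ncvogs = dplyr::n_distinct(annotation$ncvog_id),
    by_category = by_cat
  )
}

#' Reverse complement helper used by composition invariants
#' @param seq Nucleotide string.
#' @return Reverse-complemented string.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
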