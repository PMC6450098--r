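#' Read a tagged protein FASTA
#'
#' Reads protein records whose headers may carry `key=value` tags, e.g.
#' `>orf001 src=virus tax=viral`. Tags `src` and `tax` become the
#' `source` and `taxonomy` columns; absent tags default to `db` /
#' `unclassified`. Parsing goes through [Biostrings::readAAStringSet()].
#'
#' @param path FASTA file path.
#' @return A tibble (`protein_records`) with columns `id`, `sequence`,
#'   `source`, `taxonomy`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    rlang::warn(sprintf("empty FASTA: %s", path))
    return(protein_tbl(character(), character(), character(), character()))
  }
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    rlang::abort(sprintf("duplicate record id '%s' in %s", dup, path))
  }
  src <- stringr::str_match(headers, "\\bsrc=(\\S+)")[, 2]
  tax <- stringr::str_match(headers, "\\btax=(\\S+)")[, 2]
  protein_tbl(
    id = id,
    sequence = as.character(set),
    source = dplyr::coalesce(src, "db"),
    taxonomy = dplyr::coalesce(tax, "unclassified")
  )
}

protein_tbl <- function(id, sequence, source, taxonomy) {
  tibble::tibble(id = unname(id), sequence = unname(sequence),
                 source = unname(source), taxonomy = unname(taxonomy))
}

#' Write a tagged protein FASTA
#'
#' Inverse of [read_fasta()]: headers are `id src=<source> tax=<taxonomy>`.
#'
#' @param records Tibble with `id`, `sequence`, `source`, `taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence", "source", "taxonomy") %in% names(records)))
  if (anyDuplicated(records$id)) {
    rlang::abort(sprintf("duplicate record id '%s'",
                         records$id[duplicated(records$id)][1]))
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- sprintf("%s src=%s tax=%s",
                        records$id, records$source, records$taxonomy)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

HIT_COLS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_openings", "q_start", "q_end", "s_start",
              "s_end", "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' The standard tab-separated output dialect of protein similarity
#' search tools (qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore). Rows are filtered at
#' the E-value threshold with a strict inequality — only hits with
#' `evalue < max_evalue` are retained, the threshold used for the
#' genome annotation homology searches.
#'
#' @param path Hit file path (no header row).
#' @param max_evalue Strict E-value cutoff (default `1e-5`).
#' @param proteins Optional `protein_records` tibble supplying
#'   source/taxonomy labels for subjects (joined on `subject_id`).
#' @return A tibble (`hit_table`); if `proteins` is given, with
#'   `subject_source` and `subject_taxonomy` columns.
#' @export
read_hit_table <- function(path, max_evalue = 1e-5, proteins = NULL) {
  raw <- readr::read_tsv(path, col_names = HIT_COLS,
                         col_types = "ccddiiiiiidd", na = character())
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf("malformed hit row at line %d of %s", prob$row[1], path))
  }
  n_in <- nrow(raw)
  out <- dplyr::filter(raw, .data$evalue < max_evalue)
  rlang::inform(sprintf("read %d hit rows, retained %d at E < %g",
                        n_in, nrow(out), max_evalue))
  annotate_hits(out, proteins)
}

#' Attach subject source/taxonomy labels to a hit table
#'
#' @param hits Hit tibble with a `subject_id` column.
#' @param proteins Optional `protein_records` tibble; every subject must
#'   resolve to a record.
#' @return Hit tibble, with `subject_source`/`subject_taxonomy` when
#'   `proteins` is supplied.
#' @export
annotate_hits <- function(hits, proteins = NULL) {
  hits <- tibble::as_tibble(hits)
  if (is.null(proteins)) return(hits)
  lab <- dplyr::select(proteins, subject_id = "id",
                       subject_source = "source",
                       subject_taxonomy = "taxonomy")
  out <- dplyr::left_join(hits, lab, by = "subject_id")
  if (anyNA(out$subject_source)) {
    bad <- out$subject_id[is.na(out$subject_source)][1]
    rlang::abort(sprintf("subject '%s' not resolvable to a protein record", bad))
  }
  out
}

#' Best hit of a query
#'
#' Among the query's hits whose subject source is not excluded, the hit
#' with maximal bitscore; ties broken by minimal E-value, then by
#' lexicographically smallest subject id — a deterministic chain that is
#' invariant to input row order. Absence of an eligible hit is a value
#' (zero-row tibble), not an error.
#'
#' @param query_id Query identifier.
#' @param hits Hit tibble (annotated with `subject_source` if
#'   `exclude_sources` is non-empty).
#' @param exclude_sources Character vector of subject sources to ignore.
#' @return Zero- or one-row tibble.
#' @export
best_hit <- function(query_id, hits, exclude_sources = character()) {
  cand <- dplyr::filter(hits, .data$query_id == !!query_id)
  if (length(exclude_sources) > 0) {
    stopifnot("subject_source" %in% names(cand))
    cand <- dplyr::filter(cand, !.data$subject_source %in% exclude_sources)
  }
  if (nrow(cand) == 0) return(cand)
  cand |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject_id) |>
    dplyr::slice(1)
}

#' Best hit per query, vectorised
#'
#' [best_hit()] applied to every query in the table at once.
#'
#' @inheritParams best_hit
#' @return Tibble with one row per query that has an eligible hit.
#' @export
best_hits_per_query <- function(hits, exclude_sources = character()) {
  cand <- hits
  if (length(exclude_sources) > 0) {
    stopifnot("subject_source" %in% names(cand))
    cand <- dplyr::filter(cand, !.data$subject_source %in% exclude_sources)
  }
  cand |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                   .data$evalue, .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits Hit tibble (extra columns dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, HIT_COLS], path, col_names = FALSE)
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ncldvtools")
  if (p == "") rlang::abort(sprintf("fixture %s not found", file))
  p
}

read_fixture <- function(file, required, col_types = NULL) {
  tab <- readr::read_tsv(fixture_path(file), col_types = col_types,
                         show_col_types = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(sprintf("fixture %s missing column(s): %s", file,
                         paste(missing, collapse = ", ")))
  }
  tab
}

#' Curated tables from the published medusavirus characterisation
#'
#' Accessors for the plain-TSV fixtures shipped with the package,
#' transcribed verbatim from the printed study tables:
#' \describe{
#'   \item{`fixture_gc_table()`}{Per-family G+C content summaries of the
#'     NCLDV groups (14 rows).}
#'   \item{`fixture_proteome()`}{The 80-protein virion proteome with
#'     molecular weights and emPAI values, in printed (emPAI-descending)
#'     order.}
#'   \item{`fixture_core_genes()`}{The 15 NCVOG core-gene rows with
#'     their ORF assignments and functional categories.}
#'   \item{`fixture_lgt()`}{The 57 LGT candidate gene pairs with their
#'     inferred directions.}
#'   \item{`fixture_taxonomy_tally()`}{Closest-homolog taxonomy counts
#'     over the 461 predicted ORFs, plus the count of ORFs whose closest
#'     homolog is in the host amoeba.}
#' }
#' @return A tibble typed per fixture.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_gc_table <- function() {
  read_fixture("table_gc_ncldv.tsv",
               c("group", "n_species", "max", "min", "mean", "median", "sd"),
               col_types = "ciddddd")
}

#' @rdname fixtures
#' @export
fixture_proteome <- function() {
  read_fixture("table_virion_proteome.tsv",
               c("orf_id", "putative_function", "mw_kda", "empai"),
               col_types = "ccdd")
}

#' @rdname fixtures
#' @export
fixture_core_genes <- function() {
  read_fixture("table_core_genes.tsv",
               c("ncvog_id", "orf_id", "ncvog_annotation",
                 "functional_category"),
               col_types = "cccc")
}

#' @rdname fixtures
#' @export
fixture_lgt <- function() {
  read_fixture("table_lgt_candidates.tsv",
               c("virus_orf_id", "putative_function", "host_gene_id",
                 "direction"),
               col_types = "cccc")
}

#' @rdname fixtures
#' @export
fixture_taxonomy_tally <- function() {
  read_fixture("table_taxonomy_tally.tsv", c("class", "n"),
               col_types = "ci")
}
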