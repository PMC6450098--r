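DIRECTIONS <- c("VtoA", "AtoV", "undetermined")

#' Reciprocal-best-hit LGT candidate detection
#'
#' A virus gene `v` and a host gene `a` form a lateral-gene-transfer
#' candidate when `a` is the overall best hit of `v` in the virus-query
#' table and, reciprocally, `v` is the overall best hit of `a` in the
#' host-query table. Both tables must have been searched with the
#' query's own genome excluded: the virus-query table may not contain
#' virus subjects, nor the host-query table host subjects.
#'
#' Because best hits are unique after deterministic tie-breaking
#' (bitscore, then E-value, then subject id), each gene appears in at
#' most one candidate pair.
#'
#' @param virus_hits Annotated hit tibble, virus genes as queries.
#' @param host_hits Annotated hit tibble, host genes as queries.
#' @return Tibble with `virus_orf_id`, `host_gene_id` and an unset
#'   `direction` column.
#' @export
find_rbh_candidates <- function(virus_hits, host_hits) {
  check_no_self_genome(virus_hits, "virus")
  check_no_self_genome(host_hits, "host")
  empty <- tibble::tibble(virus_orf_id = character(0),
                          host_gene_id = character(0),
                          direction = character(0))
  if (nrow(virus_hits) == 0 || nrow(host_hits) == 0) return(empty)
  bv <- best_hits_per_query(virus_hits) |>
    dplyr::select(virus_orf_id = "query_id", host_gene_id = "subject_id",
                  best_source = "subject_source")
  bh <- best_hits_per_query(host_hits) |>
    dplyr::select(host_gene_id = "query_id", virus_orf_id = "subject_id",
                  best_source_rev = "subject_source")
  out <- dplyr::inner_join(
    dplyr::filter(bv, .data$best_source == "host"),
    dplyr::filter(bh, .data$best_source_rev == "virus"),
    by = c("virus_orf_id", "host_gene_id")
  )
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::transmute(.data$virus_orf_id, .data$host_gene_id,
                     direction = NA_character_) |>
    dplyr::arrange(.data$virus_orf_id)
}

check_no_self_genome <- function(hits, own_source) {
  if (nrow(hits) == 0) return(invisible(NULL))
  stopifnot("subject_source" %in% names(hits))
  if (any(hits$subject_source == own_source)) {
    rlang::abort(sprintf(
      "%s-query hit table contains %s subjects; searches must exclude the query genome.",
      own_source, own_source))
  }
  invisible(NULL)
}

#' Direction classification rule for one closest-gene class pair
#'
#' Applies the exclusion-based rule: with `closest_1` the taxonomy class
#' of the virus query's best non-host hit and `closest_2` that of the
#' host query's best non-virus hit (either may be `NA` when no such hit
#' exists), the transfer is virus-to-amoeba (`VtoA`) if at least one
#' closest gene is viral, else amoeba-to-virus (`AtoV`) if at least one
#' is eukaryotic, else `undetermined`. The prose rule fires both clauses
#' when one closest gene is viral and the other eukaryotic; under the
#' default `conservative` policy that conflict is classified
#' `undetermined` with a warning, under `vtoa_precedence` the viral
#' clause wins.
#'
#' @param closest_1,closest_2 Taxonomy classes (or `NA` for absent).
#' @param policy `"conservative"` or `"vtoa_precedence"`.
#' @return One of `"VtoA"`, `"AtoV"`, `"undetermined"`.
#' @export
classify_direction <- function(closest_1, closest_2,
                               policy = c("conservative", "vtoa_precedence")) {
  policy <- match.arg(policy)
  cls <- c(closest_1, closest_2)
  cls <- cls[!is.na(cls)]
  stopifnot(all(cls %in% TAX_CLASSES))
  has_viral <- "viral" %in% cls
  has_euk <- "eukaryotic" %in% cls
  if (has_viral && has_euk) {
    if (policy == "conservative") {
      rlang::warn("conflicting closest genes (viral and eukaryotic); undetermined under conservative policy.")
      return("undetermined")
    }
    return("VtoA")
  }
  if (has_viral) return("VtoA")
  if (has_euk) return("AtoV")
  "undetermined"
}

#' Infer transfer directions for RBH candidates
#'
#' For each candidate pair, finds the virus query's best hit excluding
#' host subjects and the host query's best hit excluding virus subjects
#' (the two "closest genes"), then classifies the direction with
#' [classify_direction()]. Evidence columns record the closest-gene ids
#' and taxonomy classes.
#'
#' @param candidates Output of [find_rbh_candidates()].
#' @param virus_hits,host_hits Annotated hit tibbles (with
#'   `subject_source` and `subject_taxonomy`).
#' @inheritParams classify_direction
#' @return The candidates tibble with `direction`,
#'   `closest_virus_query`, `closest_virus_query_tax`,
#'   `closest_host_query`, `closest_host_query_tax` filled in.
#' @export
infer_direction <- function(candidates, virus_hits, host_hits,
                            policy = c("conservative", "vtoa_precedence")) {
  policy <- match.arg(policy)
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates,
                         closest_virus_query = character(0),
                         closest_virus_query_tax = character(0),
                         closest_host_query = character(0),
                         closest_host_query_tax = character(0)))
  }
  rows <- purrr::pmap(candidates, function(virus_orf_id, host_gene_id, ...) {
    c1 <- best_hit(virus_orf_id, virus_hits, exclude_sources = "host")
    c2 <- best_hit(host_gene_id, host_hits, exclude_sources = "virus")
    tibble::tibble(
      virus_orf_id = virus_orf_id,
      host_gene_id = host_gene_id,
      closest_virus_query = if (nrow(c1)) c1$subject_id else NA_character_,
      closest_virus_query_tax = if (nrow(c1)) c1$subject_taxonomy else NA_character_,
      closest_host_query = if (nrow(c2)) c2$subject_id else NA_character_,
      closest_host_query_tax = if (nrow(c2)) c2$subject_taxonomy else NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$direction <- purrr::map2_chr(out$closest_virus_query_tax,
                                   out$closest_host_query_tax,
                                   classify_direction, policy = policy)
  out[, c("virus_orf_id", "host_gene_id", "direction",
          "closest_virus_query", "closest_virus_query_tax",
          "closest_host_query", "closest_host_query_tax")]
}

#' Tally an LGT candidate table
#'
#' Counts candidates by direction. Direction labels are matched
#' case-insensitively (`"Undetermined"` and `"undetermined"` are the
#' same class), so tables transcribed from publications tally directly.
#'
#' @param candidates Tibble with a `direction` column.
#' @return An `lgt_report`: one-row tibble with `n_total`, `n_vtoa`,
#'   `n_atov`, `n_undetermined`; the candidate list is attached as the
#'   `"candidates"` attribute.
#' @export
lgt_summary <- function(candidates) {
  dir <- canonical_direction(candidates$direction)
  out <- tibble::tibble(
    n_total = length(dir),
    n_vtoa = sum(dir == "VtoA"),
    n_atov = sum(dir == "AtoV"),
    n_undetermined = sum(dir == "undetermined")
  )
  attr(out, "candidates") <- tibble::as_tibble(candidates)
  class(out) <- c("lgt_report", class(out))
  out
}

canonical_direction <- function(x) {
  idx <- match(tolower(x), tolower(DIRECTIONS))
  if (anyNA(idx)) {
    rlang::abort(sprintf("unknown direction label '%s'", x[is.na(idx)][1]))
  }
  DIRECTIONS[idx]
}

#' @export
tidy.lgt_report <- function(x, ...) {
  attr(x, "candidates")
}

#' @export
glance.lgt_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Run the full LGT detection and direction inference
#'
#' Convenience wrapper: [find_rbh_candidates()], [infer_direction()],
#' [lgt_summary()].
#'
#' @inheritParams infer_direction
#' @return An `lgt_report`.
#' @export
detect_lgt <- function(virus_hits, host_hits,
                       policy = c("conservative", "vtoa_precedence")) {
  candidates <- find_rbh_candidates(virus_hits, host_hits)
  lgt_summary(infer_direction(candidates, virus_hits, host_hits,
                              policy = match.arg(policy)))
}
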