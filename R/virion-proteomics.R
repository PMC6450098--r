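# Residue mass tables. Monoisotopic masses are used for the observable-
# peptide mass window; average masses for reported molecular weights.
# Water (18.0106 Da monoisotopic / 18.0153 Da average) is added per chain.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528

#' Exponentially modified protein abundance index (emPAI)
#'
#' \eqn{\mathrm{emPAI} = 10^{N_{observed}/N_{observable}} - 1}, a
#' semiquantitative protein abundance estimate from the ratio of observed
#' to in-silico observable peptides.
#'
#' If `n_observed > n_observable` a warning is issued but the value is
#' computed as-is: real spectra can identify peptides that the in-silico
#' digestion model deems unobservable.
#'
#' @param n_observed Number of distinct observed peptides (vectorised).
#' @param n_observable Number of distinct observable peptides (>= 1).
#' @return Numeric emPAI value(s), >= 0.
#' @examples
#' empai(3, 10) # 0.995...
#' empai(10, 10) # 9
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) {
    rlang::abort("`n_observable` must be >= 1.")
  }
  if (any(n_observed < 0)) {
    rlang::abort("`n_observed` must be >= 0.")
  }
  if (any(n_observed > n_observable)) {
    rlang::warn("some proteins have n_observed > n_observable; computing as-is.")
  }
  10^(n_observed / n_observable) - 1
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after K or R, except when the following
#' residue is P. With `missed_cleavages = m`, all concatenations of up to
#' `m + 1` adjacent fully-cleaved fragments are returned as well.
#'
#' @param protein Protein sequence (single string, canonical residues).
#' @param missed_cleavages Maximum number of missed cleavage sites
#'   (default 0).
#' @return Character vector of peptides, in order of start position then
#'   span; may contain duplicate sequences if the protein does.
#' @examples
#' tryptic_peptides("AAAKGGGRCCC")
#' tryptic_peptides("AKRG", missed_cleavages = 1)
#' @export
tryptic_peptides <- function(protein, missed_cleavages = 0) {
  stopifnot(length(protein) == 1, nchar(protein) > 0, missed_cleavages >= 0)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  # cleave after position i if chars[i] is K/R and chars[i+1] is not P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1] != "P"]
  bounds <- c(0, cut_after, n)
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1]
  frags <- substring(protein, starts, ends)
  if (missed_cleavages == 0) return(frags)
  nf <- length(frags)
  out <- character(0)
  for (i in seq_len(nf)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nf) break
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  out
}

#' Peptide monoisotopic mass
#'
#' Sum of monoisotopic residue masses plus one water.
#'
#' @param peptide Peptide sequence(s).
#' @return Numeric mass(es) in Da.
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    chars <- strsplit(p, "")[[1]]
    m <- MONO_MASS[chars]
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      rlang::abort(sprintf("unknown residue '%s' at position %d", chars[bad], bad))
    }
    sum(m) + WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count observable peptides
#'
#' Number of distinct peptide sequences whose monoisotopic mass lies in
#' the closed `mass_range` — the denominator of the emPAI ratio. The
#' default window of 500-5000 Da reflects the typically detectable range
#' of an LC-MS/MS run.
#'
#' @param peptides Character vector of peptides (e.g. from
#'   [tryptic_peptides()]).
#' @param mass_range Length-2 numeric, closed mass window in Da.
#' @return Integer count of distinct observable peptides.
#' @export
observable_count <- function(peptides, mass_range = c(500, 5000)) {
  stopifnot(length(mass_range) == 2, mass_range[1] <= mass_range[2])
  peptides <- unique(peptides)
  if (length(peptides) == 0) return(0L)
  m <- peptide_mass(peptides)
  sum(m >= mass_range[1] & m <= mass_range[2])
}

#' Protein molecular weight
#'
#' Average residue masses plus one water, reported in kDa.
#'
#' @param protein Protein sequence (single string).
#' @return Molecular weight in kDa.
#' @examples
#' molecular_weight("G") # 0.07507 kDa
#' @export
molecular_weight <- function(protein) {
  stopifnot(length(protein) == 1)
  if (nchar(protein) == 0) rlang::abort("empty protein chain.")
  chars <- strsplit(protein, "")[[1]]
  m <- AVG_MASS[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    rlang::abort(sprintf("unknown residue '%s' at position %d", chars[bad], bad))
  }
  (sum(m) + WATER_AVG) / 1000
}

#' Abundance relative to the most abundant protein
#'
#' Expresses each emPAI value as a percentage of the reference (by
#' default the maximum emPAI in the table, i.e. the major capsid protein
#' for the medusavirus virion proteome). Display rounding follows the
#' convention of the published comparison: percentages >= 10 are rounded
#' to the nearest integer, percentages < 10 to one decimal (28%, 21%,
#' 9%, 2.7% for H3, H2B, H4, H2A).
#'
#' @param table Data frame with at least an `empai` column; an `orf_id`
#'   column is carried through if present.
#' @param reference Reference emPAI value (default: the table maximum).
#' @return The input as a tibble with `relative_percent` (exact) and
#'   `relative_percent_display` (rounded per the display rule) appended.
#' @export
relative_percent <- function(table, reference = max(table$empai)) {
  stopifnot(nrow(table) > 0, "empai" %in% names(table))
  if (!is.finite(reference) || reference <= 0) {
    rlang::abort("reference emPAI must be positive (all-zero table?).")
  }
  tibble::as_tibble(table) |>
    dplyr::mutate(
      relative_percent = 100 * .data$empai / reference,
      relative_percent_display = display_round_percent(.data$relative_percent)
    )
}

# >= 10 -> nearest integer; < 10 -> one decimal
display_round_percent <- function(p) {
  ifelse(p >= 10, round(p), round(p, 1))
}

#' Rank a virion proteome by emPAI
#'
#' Sorts descending by emPAI, appends rank and relative-percent columns.
#'
#' @param table Data frame with an `empai` column.
#' @inheritParams relative_percent
#' @return Tibble ordered by decreasing emPAI with `rank` and relative
#'   percent columns.
#' @export
rank_proteome <- function(table, reference = max(table$empai)) {
  relative_percent(table, reference) |>
    dplyr::arrange(dplyr::desc(.data$empai)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
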