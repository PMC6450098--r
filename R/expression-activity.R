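#' RPKM normalisation
#'
#' Reads per kilobase of gene per million mapped reads:
#' `rpkm[g, r] = counts[g, r] * 1e9 / (lengths[g] * library_sizes[r])`.
#'
#' @param counts Gene-by-run matrix of non-negative integer counts.
#' @param lengths Gene lengths in bp (> 0), one per row.
#' @param library_sizes Per-run total mapped reads; defaults to the
#'   column sums of `counts`.
#' @return Numeric matrix of RPKM values, same dimensions as `counts`.
#' @examples
#' rpkm(matrix(10), lengths = 1000, library_sizes = 1e6) # 10
#' @export
rpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(library_sizes) == ncol(counts), all(lengths > 0))
  if (any(library_sizes <= 0)) rlang::abort("zero or negative library size.")
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(library_sizes))
}

#' RPKM for a tidy expression table
#'
#' @param expr Tibble with `gene_id`, `length` and one column per run.
#' @inheritParams rpkm
#' @return Tibble of the same shape with counts replaced by RPKM.
#' @export
expression_rpkm <- function(expr, library_sizes = NULL) {
  run_cols <- setdiff(names(expr), c("gene_id", "length"))
  mat <- as.matrix(expr[, run_cols])
  if (is.null(library_sizes)) library_sizes <- colSums(mat)
  vals <- rpkm(mat, expr$length, library_sizes)
  dplyr::bind_cols(expr[, c("gene_id", "length")], tibble::as_tibble(vals))
}

#' Aggregate per-run activity to one value per gene
#'
#' The study pooled 14 RNA-seq runs without stating the aggregation;
#' the default here is the mean RPKM across runs, with the median as a
#' robust alternative.
#'
#' @param rpkm_tbl Tibble from [expression_rpkm()] (`gene_id`, `length`,
#'   run columns).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return Tibble with `gene_id`, `activity`.
#' @export
gene_activity <- function(rpkm_tbl, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  run_cols <- setdiff(names(rpkm_tbl), c("gene_id", "length"))
  mat <- as.matrix(rpkm_tbl[, run_cols])
  f <- if (aggregator == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  tibble::tibble(gene_id = rpkm_tbl$gene_id, activity = f(mat))
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. For small problems
#' (`n * m <= exact_limit`, default 64) the two-sided p-value is exact,
#' by full enumeration of the `choose(n + m, n)` assignments of the
#' pooled (mid-)ranks to the first sample; ties are handled naturally by
#' enumerating the actual midranks. Above the limit a normal
#' approximation with tie correction and continuity correction is used.
#' `U` is reported for the first sample, so
#' `U(x, y) + U(y, x) = n * m`.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_limit Largest `n * m` for which the exact enumeration is
#'   used.
#' @return List with `statistic` (U for `x`), `p.value` (two-sided),
#'   and `method` (`"exact"` or `"normal_approximation"`).
#' @examples
#' mann_whitney_u(c(1), c(2)) # exact p = 1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 64) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both samples must be non-empty.")
  }
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n * m <= exact_limit) {
    idx <- utils::combn(N, n)
    stat <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(stat - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p.value = p, method = "exact"))
  }
  # normal approximation with tie and continuity corrections
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
  if (sigma == 0) return(list(statistic = u_obs, p.value = 1,
                              method = "normal_approximation"))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u_obs, p.value = p, method = "normal_approximation")
}

#' Compare transcriptional activity between LGT classes
#'
#' Runs the two planned comparisons of the silencing analysis:
#' (i) all LGT candidate genes (`VtoA`, `AtoV`, `undetermined`) versus
#' the vertically inherited genes conserved among Amoebozoa
#' (`AC_conserved`), and (ii) the putatively silenced classes
#' (`VtoA` and `undetermined` pooled) versus `AtoV`. Each comparison
#' reports group sizes, medians, the direction of the median difference,
#' U and the two-sided p-value. P-values are reported raw; no
#' multiple-testing correction is applied across the two tests.
#'
#' @param activity Tibble with `gene_id`, `activity`.
#' @param groups Tibble with `gene_id`, `group` (labels among `VtoA`,
#'   `AtoV`, `undetermined`, `AC_conserved`, `other`).
#' @inheritParams mann_whitney_u
#' @return An `activity_comparison` tibble, one row per comparison:
#'   `comparison`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `median_direction`, `U`, `p.value`, `method`.
#' @export
compare_lgt_activity <- function(activity, groups, exact_limit = 64) {
  d <- dplyr::inner_join(activity, groups, by = "gene_id")
  lgt_groups <- c("VtoA", "AtoV", "undetermined")
  sets <- list(
    "LGT_vs_AC_conserved" = list(
      a = d$activity[d$group %in% lgt_groups],
      b = d$activity[d$group == "AC_conserved"],
      need = c("LGT candidates", "AC_conserved")
    ),
    "VtoA_undetermined_vs_AtoV" = list(
      a = d$activity[d$group %in% c("VtoA", "undetermined")],
      b = d$activity[d$group == "AtoV"],
      need = c("VtoA/undetermined", "AtoV")
    )
  )
  rows <- purrr::imap(sets, function(s, nm) {
    if (length(s$a) == 0) rlang::abort(sprintf("group '%s' is empty.", s$need[1]))
    if (length(s$b) == 0) rlang::abort(sprintf("group '%s' is empty.", s$need[2]))
    test <- mann_whitney_u(s$a, s$b, exact_limit = exact_limit)
    ma <- stats::median(s$a); mb <- stats::median(s$b)
    tibble::tibble(
      comparison = nm, n_a = length(s$a), n_b = length(s$b),
      median_a = ma, median_b = mb,
      median_direction = if (ma < mb) "a<b" else if (ma > mb) "a>b" else "a=b",
      U = test$statistic, p.value = test$p.value, method = test$method
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("activity_comparison", class(out))
  out
}

#' @export
glance.activity_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c("comparison", "p.value", "median_direction")]
}
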