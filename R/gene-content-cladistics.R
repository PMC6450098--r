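#' Build a membership matrix from a long (taxon, cluster) table
#'
#' @param tbl Data frame with `taxon` and `cluster` columns.
#' @return Binary integer matrix, taxa as rownames, clusters sorted as
#'   colnames.
#' @export
membership_matrix <- function(tbl) {
  stopifnot(all(c("taxon", "cluster") %in% names(tbl)))
  taxa <- unique(tbl$taxon)
  clusters <- sort(unique(tbl$cluster))
  m <- matrix(0L, length(taxa), length(clusters),
              dimnames = list(taxa, clusters))
  m[cbind(match(tbl$taxon, taxa), match(tbl$cluster, clusters))] <- 1L
  m
}

check_membership <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2, !is.null(rownames(m)))
  if (any(rowSums(m) == 0)) {
    bad <- rownames(m)[rowSums(m) == 0][1]
    rlang::abort(sprintf("taxon '%s' has an empty gene set.", bad))
  }
  invisible(m)
}

#' Pairwise gene-content similarity and distance
#'
#' Similarity between the gene-cluster sets A and B of two taxa:
#' \describe{
#'   \item{dice}{\eqn{2|A \cap B| / (|A| + |B|)}}
#'   \item{jaccard}{\eqn{|A \cap B| / |A \cup B|}}
#'   \item{min_norm}{\eqn{|A \cap B| / \min(|A|, |B|)}}
#' }
#' All lie in \[0, 1\]; the distance is \eqn{d = 1 - s}.
#'
#' @param m Binary taxa-by-cluster membership matrix.
#' @param method Similarity score (default `"dice"`).
#' @return List with `similarity` (matrix), `distance` (a
#'   [stats::dist]), and `method`.
#' @export
gene_content_similarity <- function(m, method = c("dice", "jaccard", "min_norm")) {
  method <- match.arg(method)
  check_membership(m)
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  s <- switch(method,
    dice = 2 * inter / outer(sizes, sizes, "+"),
    jaccard = inter / (outer(sizes, sizes, "+") - inter),
    min_norm = inter / outer(sizes, sizes, pmin)
  )
  diag(s) <- 1
  list(similarity = s, distance = stats::as.dist(1 - s), method = method)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to
#' zero with a warning.
#'
#' @param d A [stats::dist] or symmetric matrix over >= 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) rlang::abort("neighbor joining needs >= 3 taxa.")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    rlang::warn("negative branch length(s) clamped to 0.")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Gene-content tree with bootstrap support
#'
#' Builds the neighbor-joining tree from the full membership matrix,
#' then resamples gene-cluster columns with replacement `n_reps` times,
#' rebuilds the tree per replicate, and reports for each internal
#' bipartition of the full-data tree the percentage of replicates that
#' contain it (stored in `node.label`). A replicate that leaves some
#' taxon with an empty gene set is redrawn (at most 10 retries).
#'
#' @param m Binary membership matrix.
#' @param method Similarity score, see [gene_content_similarity()].
#' @param n_reps Number of bootstrap replicates (default 100, as in the
#'   study); 0 returns the tree without support values.
#' @param seed RNG seed.
#' @return An [ape::phylo] tree; internal node labels hold integer
#'   percent support (root label empty).
#' @export
gene_content_tree <- function(m, method = "dice", n_reps = 100, seed = 1) {
  check_membership(m)
  full <- nj_tree(gene_content_similarity(m, method)$distance)
  if (n_reps == 0) return(full)
  boot <- with_seed(seed, {
    purrr::map(seq_len(n_reps), function(i) {
      for (try in 1:10) {
        cols <- sample(ncol(m), ncol(m), replace = TRUE)
        mb <- m[, cols, drop = FALSE]
        if (all(rowSums(mb) > 0)) {
          return(nj_tree(suppressWarnings(
            gene_content_similarity(mb, method)$distance)))
        }
        rlang::inform("bootstrap replicate left an empty taxon; redrawn.")
      }
      rlang::abort("could not draw a valid bootstrap replicate in 10 tries.")
    })
  })
  counts <- ape::prop.clades(full, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""  # root of the unrooted representation
  full
}

newick_quote <- function(label) {
  needs <- grepl("[][ \t(){}:;,'\"]", label)
  ifelse(needs,
         paste0("'", gsub("'", "''", label), "'"),
         label)
}

#' Serialise a tree to newick text
#'
#' Writes branch lengths and internal node labels (bootstrap support) in
#' the standard positions. Labels containing newick metacharacters
#' (spaces, brackets, quotes, `:;,`) are single-quoted, with embedded
#' quotes doubled.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional file path; if `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(i) {
    if (is.null(tree$edge.length)) "" else sprintf(":%.10g", tree$edge.length[i])
  }
  recurse <- function(node, edge_i) {
    if (node <= n_tip) {
      return(paste0(newick_quote(tree$tip.label[node]), fmt_len(edge_i)))
    }
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, function(e) {
      recurse(tree$edge[e, 2], e)
    }, character(1)), collapse = ",")
    lab <- if (!is.null(tree$node.label)) {
      lb <- tree$node.label[node - n_tip]
      if (is.na(lb) || lb == "") "" else newick_quote(lb)
    } else ""
    paste0("(", inner, ")", lab, if (is.null(edge_i)) "" else fmt_len(edge_i))
  }
  text <- paste0(recurse(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Parse newick text
#'
#' Thin wrapper over [ape::read.tree()] that strips the single quotes
#' [write_newick()] adds around labels containing metacharacters (ape
#' retains them verbatim).
#'
#' @param text Newick string, or `NULL` when reading from `path`.
#' @param path Optional file to read.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tree <- if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}
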