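mk_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  m
}

test_that("similarity scores match hand-enumerated set sizes", {
  # A = {1,2,3}, B = {2,3,4,5}
  m <- mk_matrix(list(A = c(1, 1, 1, 0, 0), B = c(0, 1, 1, 1, 1)))
  expect_equal(gene_content_similarity(m, "dice")$similarity["A", "B"],
               2 * 2 / 7)
  expect_equal(gene_content_similarity(m, "jaccard")$similarity["A", "B"],
               2 / 5)
  expect_equal(gene_content_similarity(m, "min_norm")$similarity["A", "B"],
               2 / 3)

  ident <- mk_matrix(list(A = c(1, 0, 1), B = c(1, 0, 1)))
  disj <- mk_matrix(list(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1)))
  for (meth in c("dice", "jaccard", "min_norm")) {
    expect_equal(gene_content_similarity(ident, meth)$similarity["A", "B"], 1)
    expect_equal(gene_content_similarity(disj, meth)$similarity["A", "B"], 0)
    d <- as.matrix(gene_content_similarity(disj, meth)$distance)
    expect_equal(d["A", "B"], 1)
  }
  expect_error(
    gene_content_similarity(mk_matrix(list(A = c(1, 0), B = c(0, 0)))),
    "empty gene set"
  )
})

test_that("all methods coincide for equal sizes and intersections", {
  # every taxon has 4 clusters, every pairwise intersection is 2
  m <- mk_matrix(list(
    A = c(1, 1, 1, 1, 0, 0, 0, 0, 0),
    B = c(1, 1, 0, 0, 1, 1, 0, 0, 0),
    C = c(1, 1, 0, 0, 0, 0, 1, 1, 0)
  ))
  dice <- gene_content_similarity(m, "dice")$similarity
  jac <- gene_content_similarity(m, "jaccard")$similarity
  # dice = 2*2/8 = 0.5; jaccard = 2/6; min_norm = 2/4 -- they coincide
  # only where the formulas do (dice == min_norm at equal sizes)
  minn <- gene_content_similarity(m, "min_norm")$similarity
  expect_equal(dice["A", "B"], minn["A", "B"])
  expect_equal(dice["A", "B"], dice["B", "C"])
  expect_equal(jac["A", "B"], jac["B", "C"])
})

test_that("membership_matrix pivots a long table", {
  tbl <- tibble::tibble(
    taxon = c("A", "A", "B"),
    cluster = c("c1", "c2", "c2")
  )
  m <- membership_matrix(tbl)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["A", "c1"], 1L)
  expect_equal(m["B", "c1"], 0L)
  expect_equal(m["B", "c2"], 1L)
})

test_that("NJ recovers additive distances exactly", {
  # 4-taxon tree with internal edge 1: A,B on one side (1, 2), C,D (3, 4)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d <- ape::cophenetic.phylo(ref)
  # make C,D the other cherry explicitly: dCD must come from the tree
  tree <- nj_tree(d[order(rownames(d)), order(colnames(d))])
  expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
               ignore_attr = TRUE)
  # branch lengths: cophenetic distances of the NJ tree reproduce input
  got <- ape::cophenetic.phylo(tree)
  expect_equal(got[rownames(d), colnames(d)], d, tolerance = 1e-12)

  # 3-taxon closed form
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  g3 <- ape::cophenetic.phylo(t3)
  expect_equal(g3[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)

  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3")
})

test_that("NJ recovers random additive topologies up to n = 8", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(ref)
    tree <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                 ignore_attr = TRUE)
  }
})

test_that("taxa order does not change the unrooted topology", {
  m <- generate_membership(paste0("a", 1:3), paste0("b", 1:3), seed = 6,
                           noise_flip = 0.05)
  d <- gene_content_similarity(m)$distance
  t1 <- nj_tree(d)
  perm <- sample(rownames(m))
  d2 <- gene_content_similarity(m[perm, ])$distance
  t2 <- nj_tree(d2)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap support is maximal for a perfectly separated clade", {
  m <- generate_membership(paste0("a", 1:4), paste0("b", 1:4),
                           n_shared = 5, n_clade = 10, n_private = 2,
                           seed = 3)
  tree <- gene_content_tree(m, n_reps = 50, seed = 9)
  support <- suppressWarnings(as.numeric(tree$node.label))
  # the a/b split must be a branch with 100% support
  split_node <- ape::getMRCA(ape::root(tree, "b1"), paste0("a", 1:4))
  expect_true(any(support == 100, na.rm = TRUE))
  expect_true(all(support >= 0 & support <= 100, na.rm = TRUE))

  # duplicating every column cannot decrease the perfect support
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("OG%04d", seq_len(ncol(m2)))
  tree2 <- gene_content_tree(m2, n_reps = 50, seed = 9)
  expect_true(any(as.numeric(tree2$node.label) == 100, na.rm = TRUE))
})

test_that("bootstrap is reproducible and optional", {
  m <- generate_membership(paste0("a", 1:3), paste0("b", 1:3), seed = 2,
                           noise_flip = 0.1)
  t1 <- gene_content_tree(m, n_reps = 30, seed = 5)
  t2 <- gene_content_tree(m, n_reps = 30, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  t0 <- gene_content_tree(m, n_reps = 0)
  expect_null(t0$node.label)
})

test_that("newick round-trips preserve topology, lengths and support", {
  txt <- write_newick(ape::read.tree(text = "(a:1,b:2,c:3);"))
  back <- read_newick(txt)
  expect_setequal(back$tip.label, c("a", "b", "c"))
  expect_equal(sort(back$edge.length), c(1, 2, 3))

  tree <- ape::read.tree(text = "((a:1,b:2)100:0.5,c:3,d:4);")
  txt2 <- write_newick(tree)
  expect_match(txt2, "\\)100:")
  back2 <- read_newick(txt2)
  expect_equal(ape::dist.topo(tree, back2), 0, ignore_attr = TRUE)
  expect_equal(back2$node.label[2], "100")

  # metacharacter labels are quoted and survive the round trip
  tree$tip.label[1] <- "a b"
  txt3 <- write_newick(tree)
  expect_match(txt3, "'a b'", fixed = TRUE)
  back3 <- read_newick(txt3)
  expect_true("a b" %in% back3$tip.label)
})
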