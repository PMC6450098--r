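test_that("rpkm evaluates the formula and its homogeneity", {
  expect_equal(rpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(rpkm(matrix(0), 500, 1e6)[1, 1], 0)

  counts <- matrix(rpois(20, 50), nrow = 5)
  lens <- c(500, 1000, 1500, 2000, 800)
  base <- rpkm(counts, lens, rep(1e6, 4))
  halved <- rpkm(counts, lens, rep(2e6, 4))
  expect_equal(halved, base / 2)
  expect_error(rpkm(matrix(1), 100, 0), "library size")
})

test_that("gene_activity aggregates per gene as requested", {
  tbl <- tibble::tibble(
    gene_id = c("g1", "g2"), length = c(100L, 100L),
    run_01 = c(1, 10), run_02 = c(3, 10), run_03 = c(20, 10)
  )
  expect_equal(gene_activity(tbl)$activity, c(8, 10))
  # median is robust to the outlier column
  expect_equal(gene_activity(tbl, "median")$activity, c(3, 10))
  # identical columns: activity equals any single column
  same <- tibble::tibble(gene_id = "g", length = 1L,
                         run_01 = 7, run_02 = 7)
  expect_equal(gene_activity(same)$activity, 7)
})

# Independent oracle: count-based U over all label assignments.
mw_oracle <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_obs <- u_of(x, y)
  mu <- n * (N - n) / 2
  idx <- utils::combn(N, n)
  stats <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p <- mean(abs(stats - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

test_that("exact Mann-Whitney agrees with the permutation oracle", {
  expect_equal(mann_whitney_u(1, 2)$p.value, 1.0)

  set.seed(101)
  for (rep in 1:5) {
    x <- sample(1:100, 4); y <- sample(101:200, 4) - sample(0:150, 4)
    res <- mann_whitney_u(x, y)
    orc <- mw_oracle(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$statistic, orc$U)
    expect_equal(res$p.value, orc$p)
  }
  # with ties
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  res <- mann_whitney_u(x, y)
  orc <- mw_oracle(x, y)
  expect_equal(res$statistic, orc$U)
  expect_equal(res$p.value, orc$p)
})

test_that("the normal approximation is close to exact at the crossover", {
  # at n = m = 8 the approximation tracks the exact p to within 10%
  # relative error away from the extreme tail (where any normal
  # approximation degrades); exercised on exchangeable draws
  set.seed(11)
  for (rep in 1:6) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- mann_whitney_u(x, y)
    approx <- mann_whitney_u(x, y, exact_limit = 0)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_approximation")
    expect_lt(abs(approx$p.value - exact$p.value) / exact$p.value, 0.10)
  }
})

test_that("both p-value routes agree with the reference implementation", {
  set.seed(13)
  for (rep in 1:6) {
    x <- rnorm(8); y <- rnorm(8, mean = 0.5)
    expect_equal(mann_whitney_u(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(mann_whitney_u(x, y, exact_limit = 0)$p.value,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(mann_whitney_u(x, y)$statistic,
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("U is complementary between the two sample orders", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    x <- sample(1:50, n, replace = TRUE)
    y <- sample(1:50, m, replace = TRUE)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$statistic + b$statistic, n * m)
    expect_equal(a$p.value, b$p.value)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("the exact test keeps its nominal type-I error", {
  set.seed(33)
  n_rej <- 0L
  n_rep <- 10000
  for (i in seq_len(n_rep)) {
    x <- rnorm(4); y <- rnorm(4)
    if (mann_whitney_u(x, y)$p.value <= 0.05) n_rej <- n_rej + 1L
  }
  expect_lte(n_rej / n_rep, 0.05)
})

test_that("silenced synthetic genes show reduced activity", {
  groups <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    group = rep(c("VtoA", "AtoV", "undetermined", "AC_conserved"),
                times = c(20, 20, 20, 60)),
    length = 900L
  )
  sim <- simulate_count_matrix(groups, mean_count = 200,
                               silencing_multiplier = 0.1, n_runs = 5,
                               seed = 17)
  act <- sim$counts |> expression_rpkm() |> gene_activity()
  cmp <- compare_lgt_activity(act, sim$groups)
  first <- cmp[cmp$comparison == "LGT_vs_AC_conserved", ]
  expect_equal(first$median_direction, "a<b")
  expect_lt(first$p.value, 0.01)
  second <- cmp[cmp$comparison == "VtoA_undetermined_vs_AtoV", ]
  expect_equal(second$median_direction, "a<b")
})

test_that("identical distributions are rarely called significant", {
  groups <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:90),
    group = rep(c("VtoA", "AtoV", "AC_conserved"), each = 30),
    length = 1000L
  )
  n_sig <- 0L
  for (s in 1:100) {
    sim <- simulate_count_matrix(groups, silencing_multiplier = 1,
                                 n_runs = 3, seed = s)
    act <- sim$counts |> expression_rpkm() |> gene_activity()
    cmp <- compare_lgt_activity(act, sim$groups)
    if (cmp$p.value[cmp$comparison == "LGT_vs_AC_conserved"] < 0.05) {
      n_sig <- n_sig + 1L
    }
  }
  expect_gte(100 - n_sig, 90)
})

test_that("degenerate one-gene groups are handled without error", {
  act <- tibble::tibble(gene_id = c("a", "b", "c"), activity = c(1, 2, 3))
  grp <- tibble::tibble(gene_id = c("a", "b", "c"),
                        group = c("VtoA", "AtoV", "AC_conserved"))
  cmp <- compare_lgt_activity(act, grp)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$method == "exact"))
  second <- cmp[cmp$comparison == "VtoA_undetermined_vs_AtoV", ]
  expect_equal(second$p.value, 1.0)

  # a required group missing is a named error
  grp2 <- tibble::tibble(gene_id = c("a", "b", "c"),
                         group = c("VtoA", "AtoV", "other"))
  expect_error(compare_lgt_activity(act, grp2), "AC_conserved")
})
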