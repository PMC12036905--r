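test_that("unexpressed genes are dropped exactly", {
  x <- random_expression(6, 5, seed = 31)
  x[, 3] <- 0
  got <- drop_unexpressed_genes(x)
  expect_equal(ncol(got), 4)
  expect_false("gene_3" %in% colnames(got))
  # no zero column: identity
  x2 <- random_expression(6, 5, seed = 32, zero_frac = 0)
  expect_equal(drop_unexpressed_genes(x2), x2)
  # brute-force column scan oracle on a random binary matrix
  set.seed(33)
  b <- matrix(rbinom(200, 1, 0.2), 10, 20)
  keep <- vapply(seq_len(20), function(j) any(b[, j] != 0), logical(1))
  if (any(keep))
    expect_equal(unname(drop_unexpressed_genes(expression_matrix(b * 1))),
                 unname(b[, keep, drop = FALSE]))
  expect_error(drop_unexpressed_genes(expression_matrix(matrix(0, 3, 3))),
               "unexpressed")
})

test_that("L2 row normalization yields unit rows and is idempotent", {
  expect_equal(l2_normalize_rows(matrix(c(3, 4), 1, 2)),
               matrix(c(0.6, 0.8), 1, 2))
  x <- random_expression(5, 7, seed = 34)
  xn <- l2_normalize_rows(x)
  expect_equal(unname(sqrt(rowSums(xn^2))), rep(1, 5), tolerance = 1e-12)
  expect_equal(l2_normalize_rows(xn), xn, tolerance = 1e-12)
  bad <- x; bad[2, ] <- 0
  expect_error(l2_normalize_rows(bad), "cell_2")
})

test_that("similarity graphs are symmetric, non-negative, zero-diagonal", {
  x <- l2_normalize_rows(random_expression(8, 12, seed = 35))
  graphs <- similarity_graphs(x)
  expect_named(graphs, c("sparse", "pearson", "spearman", "cosine"))
  for (w in graphs) {
    expect_equal(w, t(w), tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_equal(diag(w), rep(0, 8))
  }
})

test_that("identical cells get correlation 1; orthogonal cells cosine 0", {
  x <- l2_normalize_rows(random_expression(6, 10, seed = 36, zero_frac = 0))
  x[2, ] <- x[1, ]
  g <- similarity_graphs(x)
  expect_equal(g$pearson[1, 2], 1, tolerance = 1e-12)
  expect_equal(g$spearman[1, 2], 1, tolerance = 1e-12)
  expect_equal(g$cosine[1, 2], 1, tolerance = 1e-12)
  y <- matrix(0, 4, 6)
  y[1, 1:3] <- c(1, 2, 3); y[2, 4:6] <- c(2, 1, 1)
  y[3, 1:2] <- 1; y[4, 5:6] <- 1
  gy <- similarity_graphs(l2_normalize_rows(y))
  expect_equal(gy$cosine[1, 2], 0, tolerance = 1e-12)
})

test_that("Spearman graph equals the rank-transform-then-Pearson oracle", {
  x <- l2_normalize_rows(random_expression(6, 4, seed = 37, zero_frac = 0.2))
  g <- similarity_graphs(x)
  ranks <- t(apply(x, 1, rank))  # midranks for ties
  oracle <- abs(stats::cor(t(ranks)))
  diag(oracle) <- 0
  expect_equal(g$spearman, unname(oracle), tolerance = 1e-12)
})

test_that("constant cell profiles zero their correlation rows with a warning", {
  x <- random_expression(5, 6, seed = 38, zero_frac = 0)
  x[3, ] <- 2  # constant profile
  expect_warning(g <- similarity_graphs(l2_normalize_rows(x)), "constant")
  expect_equal(g$pearson[3, ], rep(0, 5))
})

test_that("the sparse graph reconstructs cells from their duplicates", {
  # cell 2 duplicates cell 1: its best L1 self-representation uses cell 1
  set.seed(39)
  x <- l2_normalize_rows(random_expression(8, 20, seed = 39, zero_frac = 0))
  x[2, ] <- x[1, ]
  g <- similarity_graphs(x)
  expect_gt(g$sparse[1, 2], max(g$sparse[1, -c(1, 2)]))
})

test_that("Laplacian score matches the dense quadratic-form oracle", {
  set.seed(40)
  m <- 8
  w <- matrix(runif(m * m), m, m); w <- (w + t(w)) / 2; diag(w) <- 0
  for (rep in 1:5) {
    f <- rnorm(m)
    d <- rowSums(w)
    dd <- diag(d)
    lap <- dd - w
    ft <- f - as.numeric(f %*% d / sum(d))
    oracle <- as.numeric(t(ft) %*% lap %*% ft / (t(ft) %*% dd %*% ft))
    expect_equal(laplace_score(w, f), oracle, tolerance = 1e-8)
    expect_gte(laplace_score(w, f), 0)
  }
})

test_that("Laplacian score on a two-node graph matches the closed form", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  f <- c(2, 5)
  # d = (1,1); weighted mean = 3.5; ft = (-1.5, 1.5)
  # num = ft' L ft = sum_ij w_ij (f_i - f_j)^2 / 2 = (3)^2 = 9
  # den = ft' D ft = 2 * 1.5^2 = 4.5
  expect_equal(laplace_score(w, f), 2)
})

test_that("Laplacian score is scale-invariant and flags constant features", {
  set.seed(41)
  m <- 7
  w <- matrix(runif(m * m), m, m); w <- (w + t(w)) / 2; diag(w) <- 0
  f <- rnorm(m)
  s0 <- laplace_score(w, f)
  expect_equal(laplace_score(w, 3.7 * f), s0, tolerance = 1e-10)
  expect_equal(laplace_score(w, f + 11), s0, tolerance = 1e-8)
  expect_identical(laplace_score(w, rep(4, m)), Inf)
})

test_that("top-gene selection agrees with a full-sort oracle and breaks ties stably", {
  x <- l2_normalize_rows(random_expression(10, 20, seed = 42))
  sel <- select_top_genes(x, 5)
  hm <- sel$scores$harmonic_mean
  oracle <- sort(order(-hm, seq_along(hm))[1:5])
  expect_equal(colnames(sel$matrix), colnames(x)[oracle])
  expect_equal(sum(sel$scores$selected), 5)
  # t = n keeps every gene; t = 1 keeps the argmax
  expect_equal(ncol(select_top_genes(x, 20)$matrix), 20)
  one <- select_top_genes(x, 1)
  expect_equal(colnames(one$matrix), colnames(x)[which.max(hm)])
  expect_error(select_top_genes(x, 21), "exceeds")
})

test_that("selection commutes with gene permutation up to the tie rule", {
  x <- l2_normalize_rows(random_expression(9, 12, seed = 43))
  set.seed(44)
  perm <- sample(12)
  sel1 <- select_top_genes(x, 4)
  sel2 <- select_top_genes(x[, perm], 4)
  expect_setequal(colnames(sel1$matrix), colnames(sel2$matrix))
})

test_that("harmonic mean is zeroed for degenerate scores", {
  x <- random_expression(8, 6, seed = 45, zero_frac = 0)
  x[, 4] <- 5  # constant gene: Inf sentinel on every graph
  sel <- select_top_genes(x, 5)
  expect_equal(sel$scores$harmonic_mean[4], 0)
  expect_false("gene_4" %in% colnames(sel$matrix))
})
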