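test_that("rank_transform produces average ranks and flags constants", {
  vals <- rbind(a = c(0.1, 0.5, 0.3),
                b = c(2, 2, 5),
                c = c(7, 7, 7))
  colnames(vals) <- c("s1", "s2", "s3")
  x <- expression_matrix(vals)
  expect_warning(r <- rank_transform(x), "constant")
  expect_equal(unname(r["a", ]), c(1, 3, 2))
  expect_equal(unname(r["b", ]), c(1.5, 1.5, 3))
  expect_identical(attr(r, "constant_genes"), "c")
  # every row sums to m(m+1)/2
  expect_true(all(rowSums(r) == 6))
  # rank invariance under a monotone transform
  y <- x
  y["a", ] <- exp(y["a", ])
  expect_equal(suppressWarnings(rank_transform(y))["a", ], r["a", ])
})

test_that("spearman_correlation matches the classic no-ties formula", {
  expect_equal(spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  x <- rnorm(20)
  expect_equal(spearman_correlation(rank(x), rank(x^3 + 5)), 1.0)
  expect_equal(spearman_correlation(rank(x), rank(-x)), -1.0)
  expect_error(spearman_correlation(rep(2, 5), rank(rnorm(5))),
               class = "ganet_numeric_error")
})

test_that("mi_from_correlation implements -1/2 log(1 - rho^2) with clamping", {
  expect_identical(mi_from_correlation(0), 0)
  expect_equal(mi_from_correlation(0.8), 0.510826, tolerance = 1e-6)
  expect_equal(mi_from_correlation(-0.8), mi_from_correlation(0.8))
  expect_true(is.finite(mi_from_correlation(1)))
  expect_equal(mi_from_correlation(1), -0.5 * log1p(-(1 - 1e-12)^2))
  expect_error(mi_from_correlation(1.01), class = "ganet_numeric_error")
  expect_equal(mi_from_correlation(0.8, units = "bits"),
               0.510826 / log(2), tolerance = 1e-6)
})

test_that("pairwise_mi agrees with the scalar path and is symmetric-canonical", {
  x <- rand_expr(3, 12, seed = 5)
  es <- pairwise_mi(x)
  expect_equal(nrow(es), 3L)
  for (e in seq_len(3)) {
    expect_equal(es$mi[e], scalar_spearman_mi(x[es$gene_a[e], ],
                                              x[es$gene_b[e], ]))
  }
  expect_true(all(es$gene_a < es$gene_b))
})

test_that("pairwise_mi drops constant genes and errors below 2 usable", {
  vals <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(4, 2, 1, 3))
  colnames(vals) <- sprintf("s%d", 1:4)
  es <- suppressWarnings(pairwise_mi(expression_matrix(vals)))
  expect_equal(nrow(es), 1L)
  expect_setequal(c(es$gene_a, es$gene_b), c("b", "c"))
  vals2 <- rbind(a = c(1, 1, 1, 1), b = c(2, 2, 2, 2), c = c(4, 2, 1, 3))
  colnames(vals2) <- sprintf("s%d", 1:4)
  expect_error(suppressWarnings(pairwise_mi(expression_matrix(vals2))),
               "usable", class = "ganet_data_error")
})

test_that("pairwise_mi is invariant to workers and monotone transforms", {
  x <- rand_expr(20, 30, seed = 9)
  base <- pairwise_mi(x)
  expect_identical(base, pairwise_mi(x, workers = 3L))
  y <- x
  y[4, ] <- exp(y[4, ])          # strictly increasing
  y[7, ] <- y[7, ]^3             # strictly increasing (odd power)
  y[9, ] <- 2 * y[9, ] + 10      # affine
  expect_identical(pairwise_mi(y), base)
})

test_that("planted dependent pair dominates the null pairs (oracle rate)", {
  # Monte-Carlo oracle, seeds 1:100: measured winning fraction 0.84
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(10 * 50), 10, 50)
    X[2, ] <- 0.5 * X[1, ] + sqrt(0.75) * rnorm(50)
    dimnames(X) <- list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:50))
    es <- pairwise_mi(expression_matrix(X))
    top <- es[which.max(es$mi), ]
    top$gene_a == "g01" && top$gene_b == "g02"
  }, NA)
  expect_gte(mean(hits), 0.75)
})

test_that("gaussian_kernel_mi tracks the analytic Gaussian MI", {
  set.seed(31)
  x <- rnorm(2000)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(2000)
  expect_equal(gaussian_kernel_mi(x, y), 0.5108, tolerance = 0.08)
  expect_lt(gaussian_kernel_mi(runif(2000), runif(2000)), 0.05)
  # identical vectors score above any noisy pair on the same data
  expect_gt(gaussian_kernel_mi(x, x), gaussian_kernel_mi(x, y))
  expect_error(gaussian_kernel_mi(rep(1, 50), rnorm(50)),
               class = "ganet_numeric_error")
})

test_that("permutation p-values: floor, determinism, type-I calibration", {
  x <- sort(rnorm(100)); y <- x^3
  cfg <- threshold_config(n_permutations = 999L, permutation_seed = 7L)
  expect_equal(permutation_pvalue(x, y, config = cfg), 1 / 1000)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  p1 <- permutation_pvalue(a, b, config = cfg)
  expect_identical(p1, permutation_pvalue(a, b, config = cfg))
  # type-I error over 200 seeded noise pairs at the 0.05 level
  ps <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    permutation_pvalue(rnorm(50), rnorm(50),
                       config = threshold_config(n_permutations = 499L,
                                                 permutation_seed = s))
  }, 0)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.04)
})

test_that("select_threshold implements the descending keep-top rule", {
  cfg <- threshold_config(0.10)
  expect_equal(select_threshold(sample(1:100), cfg), 91)
  expect_equal(select_threshold(rep(3.5, 40), cfg), 3.5)
  expect_equal(select_threshold(c(5, 1, 9, 4), threshold_config(1.0)), 1)
  expect_error(select_threshold(numeric(0), cfg), class = "ganet_data_error")
  # keep MI >= threshold retains the top decile (plus ties)
  v <- c(1:100)
  thr <- select_threshold(v, cfg)
  expect_equal(sum(v >= thr), 10L)
})

test_that("edge list serialization round-trips in canonical order", {
  es <- edge_set(data.frame(gene_a = c("b", "c"), gene_b = c("a", "a"),
                            rho = c(0.5, -0.2), mi = c(0.25, 0.75)))
  expect_equal(es$gene_a, c("a", "a"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edges(es, f, header_lines = "provenance")
  back <- read_edges(f)
  expect_equal(back$gene_a, es$gene_a)
  expect_equal(back$gene_b, es$gene_b)
  expect_equal(back$mi, es$mi, tolerance = 1e-6)
  expect_error(edge_set(data.frame(gene_a = "x", gene_b = "x",
                                   rho = NA_real_, mi = 1)),
               "self-loop", class = "ganet_data_error")
})
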