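test_that("leave_one_out_mi matches per-removal scalar recomputation (m = 5)", {
  vals <- rbind(gA = c(0.2, 1.4, 0.9, 2.2, 0.5),
                gB = c(1.1, 2.0, 0.7, 2.5, 0.4),
                gC = rnorm(5))
  colnames(vals) <- sprintf("s%d", 1:5)
  x <- expression_matrix(vals)
  loo <- leave_one_out_mi(c("gA", "gB"), x)
  for (c in 1:5)
    expect_equal(unname(loo[c]),
                 scalar_spearman_mi(vals["gA", -c], vals["gB", -c]))
  expect_equal(attr(loo, "mi_full"),
               scalar_spearman_mi(vals["gA", ], vals["gB", ]))
  expect_error(leave_one_out_mi(c("gA", "nope"), x), "nope",
               class = "ganet_data_error")
})

test_that("perfectly monotone pairs are degenerate; duplicated chips exchangeable", {
  v <- seq(0.1, 2, length.out = 10)
  vals <- rbind(gA = v, gB = v^2, gC = rnorm(10))
  colnames(vals) <- sprintf("s%02d", 1:10)
  loo <- leave_one_out_mi(c("gA", "gB"), expression_matrix(vals))
  expect_equal(diff(range(loo)), 0)              # removal cannot break perfection
  zt <- condition_ztest(loo)
  expect_true(attr(zt, "degenerate"))
  expect_true(all(zt$p == 0.5))

  vals2 <- rbind(gA = c(1, 5, 3, 3, 2), gB = c(2, 4, 1, 1, 5))
  colnames(vals2) <- sprintf("s%d", 1:5)
  loo2 <- leave_one_out_mi(c("gA", "gB"), expression_matrix(vals2))
  expect_equal(unname(loo2[3]), unname(loo2[4]))  # identical chips
})

test_that("condition_ztest is a lower-tail z-test consistent with pnorm", {
  set.seed(5)
  loo <- c(rnorm(30, 1, 0.05), 0.2)  # one strong-reduction entry
  names(loo) <- sprintf("chip%02d", 1:31)
  zt <- condition_ztest(loo)
  expect_equal(zt$p, stats::pnorm(zt$z), tolerance = 1e-9)
  expect_equal(zt$sample_id[which.min(zt$p)], "chip31")
  expect_equal(zt$z, (loo - mean(loo)) / stats::sd(loo),
               ignore_attr = TRUE)
  expect_error(condition_ztest(c(1, 2, NA, NA, NA)),
               class = "ganet_data_error")
})

test_that("planted chips occupy the smallest p-values; reporting honors alpha/top_k", {
  f <- planted_condition_fixture(2024)
  edge <- data.frame(gene_a = "gA", gene_b = "gB")
  loo <- leave_one_out_mi(edge, f$expr)
  zt <- condition_ztest(loo)
  expect_setequal(zt$sample_id[order(zt$p)][1:10], f$planted)

  # no filtering: alpha ~ 1, top_k = m reports every chip, ranked
  all_recs <- significant_conditions(edge, f$expr,
                                     condition_config(alpha = 1 - 1e-12,
                                                      top_k = 200L))
  expect_equal(nrow(all_recs), 200L)
  expect_true(!is.unsorted(all_recs$p))
  expect_equal(unique(all_recs$mi_full), attr(loo, "mi_full"))

  # cap at top_k
  top3 <- significant_conditions(edge, f$expr,
                                 condition_config(alpha = 0.5, top_k = 3L))
  expect_equal(nrow(top3), 3L)
  expect_identical(top3$sample_id, all_recs$sample_id[1:3])
})

test_that("pure-noise edges yield empty reports at stringent alpha", {
  empties <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    vals <- rbind(gA = rnorm(150), gB = rnorm(150), gC = rnorm(150))
    colnames(vals) <- sprintf("s%03d", 1:150)
    recs <- significant_conditions(data.frame(gene_a = "gA", gene_b = "gB"),
                                   expression_matrix(vals),
                                   condition_config(alpha = 1e-6))
    nrow(recs) == 0L
  }, NA)
  expect_gte(mean(empties), 0.99)
})

test_that("significant_conditions warns below min_samples and is worker-invariant", {
  x <- rand_expr(4, 30, seed = 6)
  edges <- data.frame(gene_a = c("g001", "g002"), gene_b = c("g002", "g003"))
  expect_warning(r1 <- significant_conditions(edges, x,
                                              condition_config(alpha = 0.9,
                                                               top_k = 30L)),
                 "chips")
  r2 <- suppressWarnings(significant_conditions(edges, x,
                                                condition_config(alpha = 0.9,
                                                                 top_k = 30L),
                                                workers = 3L))
  expect_identical(r1, r2)
  expect_error(suppressWarnings(
    significant_conditions(data.frame(gene_a = "g001", gene_b = "zz"), x)),
    "zz", class = "ganet_data_error")
})

test_that("grouped removal treats chip groups as single conditions", {
  f <- planted_condition_fixture(9)
  groups <- list(planted = f$planted,
                 rest1 = sprintf("chip%03d", 1:95),
                 rest2 = sprintf("chip%03d", 96:190))
  loo <- ganet:::leave_group_out_mi(c("gA", "gB"), f$expr, groups)
  expect_length(loo, 3L)
  # removing the whole planted block erases the signal
  expect_lt(loo[["planted"]], loo[["rest1"]])
  expect_lt(loo[["planted"]], loo[["rest2"]])
})

test_that("rank-sum conservation holds inside every leave-one-out recomputation", {
  x <- rand_expr(2, 12, seed = 13)
  m <- n_samples(x)
  for (c in seq_len(m)) {
    r <- rank(x[1, -c], ties.method = "average")
    expect_equal(sum(r), (m - 1) * m / 2)
  }
})
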