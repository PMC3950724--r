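test_that("topology generation is seeded, calibrated, and validates pass-through", {
  cfg <- simulation_config(n_genes = 400L, seed = 99L)
  g1 <- generate_topology(cfg)
  g2 <- generate_topology(cfg)
  expect_identical(g1$interactions, g2$interactions)
  expect_false(any(g1$interactions$regulator == g1$interactions$target))

  mean_in <- vapply(1:20, function(s) {
    g <- generate_topology(simulation_config(n_genes = 400L,
                                             mean_in_degree = 1.5, seed = s))
    nrow(g$interactions) / 400
  }, 0)
  expect_equal(mean(mean_in), 1.5, tolerance = 0.3)

  toy <- data.frame(regulator = c("A", "B", "C", "A", "D"),
                    target = c("B", "C", "D", "E", "E"),
                    sign = c("activation", "repression", "activation",
                             "activation", "repression"))
  gold <- generate_topology(simulation_config(n_genes = 5L,
                                              topology_source = toy))
  expect_identical(gold$interactions, toy)
  bad <- rbind(toy, data.frame(regulator = "B", target = "A",
                               sign = "activation"))
  expect_error(generate_topology(simulation_config(n_genes = 5L,
                                                   topology_source = bad)),
               "duplicate", class = "ganet_data_error")
  expect_error(generate_topology(simulation_config(
    n_genes = 3L, topology_source = data.frame(regulator = "A",
                                               target = "A"))),
    "self-regulation", class = "ganet_data_error")
})

test_that("noise-free transfer functions are perfectly monotone", {
  mk <- function(sign) {
    topo <- data.frame(regulator = "A", target = "B", sign = sign)
    cfg <- simulation_config(n_genes = 2L, n_samples = 100L,
                             topology_source = topo,
                             biological_noise_sd = 0,
                             experimental_noise_sd = 0, seed = 5L)
    ds <- simulate_expression(generate_topology(cfg), cfg)
    cor(ds$expression["A", ], ds$expression["B", ], method = "spearman")
  }
  expect_equal(mk("activation"), 1)
  expect_equal(mk("repression"), -1)
})

test_that("simulated matrices validate and true edges carry more MI than non-edges", {
  cfg <- simulation_config(n_genes = 60L, n_samples = 300L, seed = 17L)
  gold <- generate_topology(cfg)
  ds <- simulate_expression(gold, cfg)
  expect_s3_class(ds$expression, "ExpressionMatrix")
  expect_true(all(ds$expression > 0))
  es <- pairwise_mi(ds$expression)
  gold_key <- unique(ganet:::pair_key(gold$interactions$regulator,
                                      gold$interactions$target))
  is_true <- ganet:::pair_key(es$gene_a, es$gene_b) %in% gold_key
  wt <- stats::wilcox.test(es$mi[is_true], es$mi[!is_true],
                           alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
  # same seed -> same dataset
  ds2 <- simulate_expression(gold, cfg)
  expect_identical(unclass(ds$expression), unclass(ds2$expression))
})

test_that("cyclic user topologies are resolved by fixed-point iteration", {
  topo <- data.frame(regulator = c("A", "B", "C"),
                     target = c("B", "C", "A"),
                     sign = c("activation", "activation", "repression"))
  cfg <- simulation_config(n_genes = 3L, n_samples = 50L,
                           topology_source = topo, seed = 8L)
  ds <- simulate_expression(generate_topology(cfg), cfg)
  expect_true(all(is.finite(ds$expression)))
})

test_that("evaluate_scores: perfect, null and worked micro-example", {
  gold <- generate_topology(simulation_config(
    n_genes = 4L,
    topology_source = data.frame(regulator = c("A", "C"),
                                 target = c("B", "D"))))
  perfect <- data.frame(gene_a = c("A", "A", "A", "B", "B", "C"),
                        gene_b = c("B", "C", "D", "C", "D", "D"),
                        score = c(1, 0, 0, 0, 0, 1))
  res <- evaluate_scores(perfect, gold)
  expect_equal(res$auroc, 1.0)
  expect_equal(res$f_score, 1.0)

  micro <- data.frame(gene_a = c("A", "A", "B", "C"),
                      gene_b = c("B", "C", "C", "D"),
                      score = c(0.9, 0.8, 0.3, 0.1))
  gold2 <- generate_topology(simulation_config(
    n_genes = 4L,
    topology_source = data.frame(regulator = c("A", "B"),
                                 target = c("B", "C"))))
  expect_equal(evaluate_scores(micro, gold2)$auroc, 0.75)

  # AUROC invariant under strictly increasing score transforms
  micro2 <- micro
  micro2$score <- exp(5 * micro2$score)
  expect_equal(evaluate_scores(micro2, gold2)$auroc, 0.75)

  # confusion conservation at every threshold
  cm <- evaluate_scores(micro, gold2)$confusion
  expect_true(all(cm$TP + cm$FP + cm$TN + cm$FN == 4L))

  expect_error(evaluate_scores(micro,
                               structure(list(interactions =
                                                data.frame(regulator = character(0),
                                                           target = character(0)),
                                              genes = character(0)),
                                         class = "GoldStandardNetwork")),
               class = "ganet_data_error")
})

test_that("null scorers give chance-level AUROC", {
  aurocs <- vapply(1:50, function(s) {
    set.seed(s)
    ids <- sprintf("g%03d", 1:46)
    pairs <- t(combn(46, 2))[1:1000, ]
    scored <- data.frame(gene_a = ids[pairs[, 1]], gene_b = ids[pairs[, 2]],
                         score = runif(1000))
    truth <- sample(1000, 60)
    gold <- generate_topology(simulation_config(
      n_genes = 46L,
      topology_source = data.frame(regulator = ids[pairs[truth, 1]],
                                   target = ids[pairs[truth, 2]])))
    evaluate_scores(scored, gold)$auroc
  }, 0)
  expect_gte(mean(aurocs), 0.46)
  expect_lte(mean(aurocs), 0.54)
})

test_that("zero-noise tree topologies: DPI at eps = 0 removes no gold edge", {
  chain <- data.frame(regulator = c("A", "B", "C", "B"),
                      target = c("B", "C", "D", "E"),
                      sign = "activation")
  cfg <- simulation_config(n_genes = 5L, n_samples = 80L,
                           topology_source = chain,
                           biological_noise_sd = 0,
                           experimental_noise_sd = 0, seed = 21L)
  ds <- simulate_expression(generate_topology(cfg), cfg)
  es <- pairwise_mi(ds$expression)
  kept <- apply_dpi(es, dpi_config(0))
  gold_key <- ganet:::pair_key(chain$regulator, chain$target)
  removed <- setdiff(ganet:::pair_key(es$gene_a, es$gene_b),
                     ganet:::pair_key(kept$gene_a, kept$gene_b))
  expect_length(intersect(removed, gold_key), 0L)
})

test_that("benchmark_methods is deterministic and rejects unknown methods", {
  cfg <- simulation_config(n_genes = 30L, seed = 4L)
  t1 <- benchmark_methods(cfg, methods = "spearman_mi_dpi",
                          sample_sizes = 100L)
  t2 <- benchmark_methods(cfg, methods = "spearman_mi_dpi",
                          sample_sizes = 100L)
  expect_identical(t1$per_size, t2$per_size)
  expect_error(benchmark_methods(cfg, methods = "genenet"),
               "unknown method", class = "ganet_config_error")
})

test_that("gold standard files round-trip", {
  cfg <- simulation_config(n_genes = 20L, seed = 3L)
  gold <- generate_topology(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(gold, f)
  back <- read_gold_standard(f)
  expect_identical(back$interactions, gold$interactions)
})
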