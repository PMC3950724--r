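#' Evaluate scored gene pairs against a gold standard
#'
#' Collapses gold directions to undirected pairs (the scorers are
#' symmetric), sweeps a threshold over the unique score values and
#' computes the confusion counts, ROC curve (sensitivity vs
#' 1-specificity), trapezoidal AUROC, precision-recall curve, and an
#' F-score at a stated operating point.  The negative set is every scored
#' non-gold pair (negatives are not subsampled).
#'
#' @param scored_pairs Data frame with `gene_a`, `gene_b` and a `score`
#'   column (an `EdgeSet` is accepted; `mi` is used as the score).
#' @param gold A `GoldStandardNetwork`.
#' @param called Optional operating point: an edge data frame (the
#'   pairs predicted positive) or a logical vector along
#'   `scored_pairs` rows.  When `NULL`, the operating point is the
#'   sweep threshold maximizing F.
#' @return A `BenchmarkResult` list: `confusion` (per-threshold data
#'   frame), `roc_points`, `auroc`, `pr_points`, `f_score`,
#'   `operating_point`.
#' @export
evaluate_scores <- function(scored_pairs, gold, called = NULL) {
  stopifnot(inherits(gold, "GoldStandardNetwork"))
  if (!nrow(gold$interactions)) data_error("gold standard has no interactions")
  df <- as.data.frame(scored_pairs)
  if (!"score" %in% names(df)) {
    if ("mi" %in% names(df)) df$score <- df$mi
    else data_error("scored_pairs needs a 'score' (or 'mi') column")
  }
  key <- pair_key(df$gene_a, df$gene_b)
  if (anyDuplicated(key)) data_error("duplicate scored pair")
  gold_key <- unique(pair_key(gold$interactions$regulator,
                              gold$interactions$target))
  truth <- key %in% gold_key
  P <- sum(truth)
  N <- sum(!truth)
  if (P == 0L) data_error("no gold interaction among the scored pairs")
  ord <- order(df$score, decreasing = TRUE)
  s <- df$score[ord]
  t_sorted <- truth[ord]
  cum_tp <- cumsum(t_sorted)
  cum_fp <- cumsum(!t_sorted)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index per unique score
  thr <- s[last]
  TP <- cum_tp[last]; FP <- cum_fp[last]
  FN <- P - TP; TN <- N - FP
  sens <- TP / P
  fpr <- FP / N
  prec <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  f <- ifelse(is.finite(prec) & prec + sens > 0,
              2 * prec * sens / (prec + sens), 0)
  xs <- c(0, fpr, 1)
  ys <- c(0, sens, 1)
  auroc <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
  confusion <- data.frame(threshold = thr, TP = TP, FP = FP, TN = TN, FN = FN)
  if (is.null(called)) {
    best <- which.max(f)
    f_score <- f[best]
    operating_point <- thr[best]
  } else {
    pos <- if (is.logical(called)) key[called]
           else pair_key(called$gene_a, called$gene_b)
    tp <- sum(pos %in% gold_key)
    fp <- length(pos) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- tp / P
    f_score <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    operating_point <- NA_real_
  }
  structure(list(confusion = confusion,
                 roc_points = data.frame(fpr = c(0, fpr, 1),
                                         sensitivity = c(0, sens, 1)),
                 auroc = auroc,
                 pr_points = data.frame(recall = sens, precision = prec),
                 f_score = f_score,
                 operating_point = operating_point),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat(sprintf("BenchmarkResult: AUROC %.4f, F %.4f (%d thresholds)\n",
              x$auroc, x$f_score, nrow(x$confusion)))
  invisible(x)
}

# Score all pairs for one method; returns list(scores, called).
score_method <- function(method, expr, threshold, dpi, workers) {
  switch(method,
    spearman_mi_dpi = {
      es <- pairwise_mi(expr, workers = workers)
      mi_dpi_scores(es, threshold, dpi, workers)
    },
    gaussian_kernel_mi_dpi = {
      es <- pairwise_gaussian_mi(expr, workers = workers)
      mi_dpi_scores(es, threshold, dpi, workers)
    },
    coexpression_spearman = {
      es <- pairwise_mi(expr, workers = workers)
      es$score <- abs(es$rho)
      thr <- select_threshold(es$score, threshold)
      list(scores = es, called = es[es$score >= thr, , drop = FALSE])
    },
    config_error(sprintf("unknown method '%s'", method)))
}

# MI scoring with DPI folded in: edges of the thresholded relevance graph
# that DPI judges indirect are demoted to score 0; survivors keep their MI
# and form the operating point.
mi_dpi_scores <- function(es, threshold, dpi, workers) {
  thr <- select_threshold(es$mi, threshold)
  rel <- es[es$mi >= thr, , drop = FALSE]
  class(rel) <- class(es)
  kept <- apply_dpi(rel, dpi, workers = workers)
  removed_key <- setdiff(pair_key(rel$gene_a, rel$gene_b),
                         pair_key(kept$gene_a, kept$gene_b))
  es$score <- es$mi
  es$score[pair_key(es$gene_a, es$gene_b) %in% removed_key] <- 0
  list(scores = es, called = kept)
}

#' Benchmark inference methods on synthetic datasets
#'
#' Reproduces the published evaluation protocol at configurable scale:
#' one gold topology per `config`, a fresh expression draw per sample
#' size, each method scoring all gene pairs (MI methods apply the
#' keep-top threshold and DPI; co-expression uses plain `|rho_s|` with
#' the same keep-top rule and no DPI), and AUROC / F computed per sample
#' size then averaged.  Fully seeded and deterministic.
#'
#' @param config A [simulation_config()].
#' @param methods Subset of `"spearman_mi_dpi"`,
#'   `"gaussian_kernel_mi_dpi"`, `"coexpression_spearman"`.
#' @param sample_sizes Integer vector of chip counts (default
#'   `c(200, 400, 600, 800, 1000)`).
#' @param threshold A [threshold_config()] (keep-top rule).
#' @param dpi A [dpi_config()] used by the MI methods (default
#'   tolerance 0.15).
#' @param workers Worker count (result-invariant).
#' @return A `BenchmarkTable`: list with `per_size` (method, sample_size,
#'   auroc, f_score) and `summary` (method, auroc, average_f).
#' @export
benchmark_methods <- function(config,
                              methods = c("spearman_mi_dpi",
                                          "coexpression_spearman"),
                              sample_sizes = c(200L, 400L, 600L, 800L, 1000L),
                              threshold = threshold_config(),
                              dpi = dpi_config(0.15),
                              workers = 1L) {
  known <- c("spearman_mi_dpi", "gaussian_kernel_mi_dpi",
             "coexpression_spearman")
  bad <- setdiff(methods, known)
  if (length(bad))
    config_error(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  gold <- generate_topology(config)
  if (!nrow(gold$interactions)) data_error("gold standard has no interactions")
  rows <- list()
  for (si in seq_along(sample_sizes)) {
    cfg_s <- config
    cfg_s$n_samples <- as.integer(sample_sizes[si])
    ds <- simulate_expression(gold, cfg_s,
                              seed = (config$seed + 7919L * si) %% 2147483647L)
    for (method in methods) {
      sc <- score_method(method, ds$expression, threshold, dpi, workers)
      res <- evaluate_scores(sc$scores, gold, called = sc$called)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, sample_size = sample_sizes[si],
                   auroc = res$auroc, f_score = res$f_score,
                   stringsAsFactors = FALSE)
    }
  }
  per_size <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(unique(per_size$method), function(mth) {
    sub <- per_size[per_size$method == mth, ]
    data.frame(method = mth, auroc = mean(sub$auroc),
               average_f = mean(sub$f_score), stringsAsFactors = FALSE)
  }))
  structure(list(per_size = per_size, summary = summary),
            class = "BenchmarkTable")
}

#' @export
print.BenchmarkTable <- function(x, ...) {
  cat("Benchmark summary (averaged across sample sizes):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
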