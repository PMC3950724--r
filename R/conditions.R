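#' Condition-removing test configuration
#'
#' The condition-removing test asks, for each inferred edge, which chips
#' (experimental conditions) the association depends on: if a gene pair
#' interacts under a specific condition, removing that chip from the
#' compendium reduces the pair's MI.  Leave-one-chip-out MI values are
#' approximately normal across chips for large compendia, so a one-sided
#' z-test flags chips whose removal significantly lowers MI.
#'
#' @param alpha One-sided significance cutoff on p (default 1e-4).
#' @param top_k Maximum conditions reported per edge (default 10).
#' @param min_samples Minimum chips for reliable MI estimation; fewer
#'   triggers a warning, not an error (default 100).
#' @param grouped Optional named list mapping group label -> chip names;
#'   when supplied, whole groups are removed instead of single chips
#'   (experiment-level conditions).
#' @return A `ConditionTestConfig` list.
#' @export
condition_config <- function(alpha = 1e-4, top_k = 10L,
                             min_samples = 100L, grouped = NULL) {
  if (alpha <= 0 || alpha >= 1) config_error("alpha must be in (0, 1)")
  if (top_k < 1L) config_error("top_k must be >= 1")
  structure(list(alpha = alpha, top_k = as.integer(top_k),
                 min_samples = as.integer(min_samples), grouped = grouped),
            class = "ConditionTestConfig")
}

#' Leave-one-chip-out MI series for one edge
#'
#' Entry `c` is the Spearman-transform MI of the pair recomputed on the
#' `m - 1` chips excluding chip `c`; ranks are fully recomputed on the
#' reduced sample each time (correctness over micro-optimization).  A
#' removal that leaves either gene constant yields `NA` for that entry
#' (excluded from the downstream z-distribution).
#'
#' @param edge Character vector of two gene identifiers, or a one-row
#'   edge data frame with `gene_a`/`gene_b`.
#' @param matrix An [expression_matrix()] with m >= 4 chips.
#' @return Named numeric vector (names = `sample_ids(matrix)`) of MI
#'   values in nats, with attribute `"mi_full"` (all-chips MI).
#' @export
leave_one_out_mi <- function(edge, matrix) {
  ge <- if (is.data.frame(edge)) c(edge$gene_a[1L], edge$gene_b[1L])
        else as.character(edge)
  missing <- setdiff(ge, rownames(matrix))
  if (length(missing))
    data_error(sprintf("unknown gene(s) in edge: %s",
                       paste(missing, collapse = ", ")))
  m <- ncol(matrix)
  if (m < 4L) data_error("leave-one-out MI needs at least 4 chips")
  x <- matrix[ge[1L], ]
  y <- matrix[ge[2L], ]
  loo <- vapply(seq_len(m), function(c) {
    xs <- x[-c]; ys <- y[-c]
    if (all(xs == xs[1L]) || all(ys == ys[1L])) return(NA_real_)
    mi_from_correlation(stats::cor(rank(xs, ties.method = "average"),
                                   rank(ys, ties.method = "average")))
  }, 0)
  names(loo) <- colnames(matrix)
  attr(loo, "mi_full") <- mi_from_correlation(
    stats::cor(rank(x, ties.method = "average"),
               rank(y, ties.method = "average")))
  loo
}

#' One-sided z-test on a leave-one-out MI series
#'
#' Standardizes each defined entry against the mean and standard
#' deviation of the whole series (the tested value included) and returns
#' the lower-tail normal p-value: a chip whose removal strongly reduces
#' MI gets a very negative z and a small p.  A zero-variance series (e.g.
#' a perfectly monotone pair) is degenerate: all p are set to 0.5 and the
#' result is flagged.
#'
#' @param loo_values Vector from [leave_one_out_mi()] (NAs allowed; at
#'   least 4 defined entries required).
#' @return Data frame with `sample_id`, `mi_loo`, `z`, `p` (rows ordered
#'   as the input), with attribute `"degenerate"`.
#' @export
condition_ztest <- function(loo_values) {
  ok <- is.finite(loo_values)
  if (sum(ok) < 4L)
    data_error("condition z-test needs >= 4 defined leave-one-out values")
  mu <- mean(loo_values[ok])
  sdev <- stats::sd(loo_values[ok])
  degenerate <- !is.finite(sdev) || sdev < 1e-13
  z <- rep(NA_real_, length(loo_values))
  p <- rep(NA_real_, length(loo_values))
  if (degenerate) {
    z[ok] <- 0
    p[ok] <- 0.5
  } else {
    z[ok] <- (loo_values[ok] - mu) / sdev
    p[ok] <- stats::pnorm(z[ok])
  }
  out <- data.frame(sample_id = names(loo_values) %||%
                      as.character(seq_along(loo_values)),
                    mi_loo = as.numeric(loo_values), z = z, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Condition annotation for a set of edges
#'
#' Runs the leave-one-chip-out z-test for every edge and reports, per
#' edge, the chips with `p <= alpha` (at most `top_k`, ordered by
#' ascending p; ties keep chip order).  With `config$grouped`, chips are
#' removed group-wise and `sample_id` names the group.  Deterministic and
#' independent of `workers`.
#'
#' @param edges `EdgeSet` or data frame with `gene_a`/`gene_b`.
#' @param matrix An [expression_matrix()].
#' @param config A [condition_config()].
#' @param workers Positive integer; chunks the per-edge loop
#'   (result-invariant).
#' @return Data frame of condition-impact records: `gene_a`, `gene_b`,
#'   `sample_id`, `mi_full`, `mi_loo`, `z`, `p`, sorted by (edge input
#'   order, ascending p).
#' @export
significant_conditions <- function(edges, matrix,
                                   config = condition_config(),
                                   workers = 1L) {
  stopifnot(is.data.frame(edges))
  genes <- unique(c(edges$gene_a, edges$gene_b))
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    data_error(sprintf("edge references unknown gene(s): %s",
                       paste(missing, collapse = ", ")))
  if (ncol(matrix) < config$min_samples)
    warning(sprintf(
      "only %d chips: MI is estimated accurately from >%d chips; condition p-values may be unreliable",
      ncol(matrix), config$min_samples), call. = FALSE)
  per_edge <- function(e) {
    loo <- if (is.null(config$grouped))
      leave_one_out_mi(c(edges$gene_a[e], edges$gene_b[e]), matrix)
    else
      leave_group_out_mi(c(edges$gene_a[e], edges$gene_b[e]), matrix,
                         config$grouped)
    zt <- condition_ztest(loo)
    zt <- zt[is.finite(zt$p) & zt$p <= config$alpha, , drop = FALSE]
    zt <- zt[order(zt$p), , drop = FALSE]
    zt <- utils::head(zt, config$top_k)
    if (!nrow(zt)) return(NULL)
    data.frame(gene_a = edges$gene_a[e], gene_b = edges$gene_b[e],
               sample_id = zt$sample_id,
               mi_full = attr(loo, "mi_full"),
               mi_loo = zt$mi_loo, z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  }
  chunks <- chunk_indices(nrow(edges), workers)
  parts <- ordered_lapply(chunks, function(es)
    do.call(rbind, lapply(es, per_edge)), workers = workers)
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      sample_id = character(0), mi_full = numeric(0),
                      mi_loo = numeric(0), z = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ConditionImpactTable", "data.frame")
  out
}

# Group-wise variant: remove all chips of a group at once.
leave_group_out_mi <- function(pair, matrix, groups) {
  x <- matrix[pair[1L], ]
  y <- matrix[pair[2L], ]
  loo <- vapply(groups, function(chips) {
    idx <- match(chips, colnames(matrix))
    xs <- x[-idx]; ys <- y[-idx]
    if (length(xs) < 3L || all(xs == xs[1L]) || all(ys == ys[1L]))
      return(NA_real_)
    mi_from_correlation(stats::cor(rank(xs, ties.method = "average"),
                                   rank(ys, ties.method = "average")))
  }, 0)
  names(loo) <- names(groups)
  attr(loo, "mi_full") <- mi_from_correlation(
    stats::cor(rank(x, ties.method = "average"),
               rank(y, ties.method = "average")))
  loo
}

#' Write a condition-impact table
#'
#' Tab-delimited `geneA geneB chip mi_full mi_loo z p`, sorted by
#' (edge, p), with `#`-prefixed provenance header lines.
#'
#' @param records A `ConditionImpactTable`.
#' @param path Output path.
#' @param header_lines Optional provenance lines.
#' @return `path`, invisibly.
#' @export
write_conditions <- function(records, path, header_lines = NULL) {
  out <- character(0)
  if (length(header_lines)) out <- paste0("# ", header_lines)
  out <- c(out,
           paste(c("# gene_a", "gene_b", "chip", "mi_full", "mi_loo",
                   "z", "p"), collapse = "\t"),
           sprintf("%s\t%s\t%s\t%.6f\t%.6f\t%.4f\t%.3e",
                   records$gene_a, records$gene_b, records$sample_id,
                   records$mi_full, records$mi_loo, records$z, records$p))
  writeLines(out, path, sep = "\n")
  invisible(path)
}
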