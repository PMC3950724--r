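#' Weighted undirected gene association network
#'
#' A `Network` holds the surviving MI-weighted edges plus, for
#' coarse-to-fine refinement, the *relevance* edge set (all pairs passing
#' the MI threshold before DPI) and the settings that produced it.
#' Isolated genes are not carried: nodes are exactly the endpoints of the
#' surviving edges.
#'
#' @param edges An `EdgeSet`.
#' @param relevance_edges The post-threshold, pre-DPI `EdgeSet`
#'   (defaults to `edges`).
#' @param threshold Effective MI threshold that produced
#'   `relevance_edges`.
#' @param dpi_tolerance DPI epsilon applied to obtain `edges`.
#' @param nodes Optional extra node identifiers (e.g. isolated genes a
#'   caller wants carried); endpoints of `edges` are always included.
#' @return A `Network` object.
#' @export
network <- function(edges, relevance_edges = edges,
                    threshold = -Inf, dpi_tolerance = 1.0,
                    nodes = character(0)) {
  stopifnot(inherits(edges, "EdgeSet"))
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b, nodes))),
                 edges = edges,
                 relevance_edges = relevance_edges,
                 threshold = threshold,
                 dpi_tolerance = dpi_tolerance),
            class = "Network")
}

#' @export
print.Network <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges (MI threshold %.4g, DPI tolerance %.3g)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$dpi_tolerance))
  invisible(x)
}

#' Build a network from an expression matrix
#'
#' The coarse-pass pipeline: all-pairs Spearman-transform MI ->
#' keep-top-fraction threshold -> DPI.  At the defaults (keep top 10%,
#' DPI tolerance 1.0) the result is the relevance network with no indirect
#' edges removed; tighter settings are reached with [refine()].
#' Deterministic given `(matrix, threshold, dpi)` and any `workers`.
#'
#' @param matrix An [expression_matrix()].
#' @param threshold A [threshold_config()].
#' @param dpi A [dpi_config()].
#' @param workers Positive integer worker count (result-invariant).
#' @return A [network()].
#' @export
build_network <- function(matrix, threshold = threshold_config(),
                          dpi = dpi_config(), workers = 1L) {
  all_edges <- pairwise_mi(matrix, workers = workers)
  thr <- select_threshold(all_edges$mi, threshold)
  rel <- all_edges[all_edges$mi >= thr, , drop = FALSE]
  rownames(rel) <- NULL
  class(rel) <- class(all_edges)
  kept <- apply_dpi(rel, dpi, workers = workers)
  network(kept, relevance_edges = rel, threshold = thr,
          dpi_tolerance = dpi$tolerance)
}

#' Coarse-to-fine refinement
#'
#' Re-thresholds the stored relevance edges at a tighter MI cutoff and
#' recomputes DPI on that subgraph (rather than subsetting previously
#' surviving edges), so a refinement chain A -> B -> C yields the same
#' network as refining A directly at C's settings.  Loosening either
#' parameter is refused: rebuild from the matrix instead.
#'
#' @param network A [network()].
#' @param new_threshold MI threshold, `>=` the network's current one.
#' @param new_dpi A [dpi_config()] with tolerance `<=` the current one.
#' @param workers Worker count (result-invariant).
#' @return The refined [network()]; its edges are a subset of the input's.
#' @export
refine <- function(network, new_threshold = network$threshold,
                   new_dpi = dpi_config(network$dpi_tolerance),
                   workers = 1L) {
  stopifnot(inherits(network, "Network"))
  if (new_threshold < network$threshold - 1e-12)
    config_error("new MI threshold is looser than the current one; rebuild from the expression matrix")
  if (new_dpi$tolerance > network$dpi_tolerance + 1e-12)
    config_error("new DPI tolerance is looser than the current one; rebuild from the expression matrix")
  rel <- network$relevance_edges
  rel2 <- rel[rel$mi >= new_threshold, , drop = FALSE]
  rownames(rel2) <- NULL
  class(rel2) <- class(rel)
  kept <- apply_dpi(rel2, new_dpi, workers = workers)
  network(kept, relevance_edges = rel2, threshold = new_threshold,
          dpi_tolerance = new_dpi$tolerance)
}

#' Degree distribution of a network
#'
#' @param network A [network()] (non-empty).
#' @return Named integer vector mapping degree to node count; counts sum
#'   to the number of nodes.
#' @export
degree_distribution <- function(network) {
  stopifnot(inherits(network, "Network"))
  if (!length(network$nodes)) data_error("empty network")
  deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                      levels = network$nodes))
  tab <- table(as.integer(deg))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Fit a power law to a degree distribution
#'
#' Scale-free degree distributions follow `P(k) ~ k^(-gamma)`.  The
#' default estimator is ordinary least squares on `(log k, log count)`
#' over degrees >= 1 with nonzero counts (`exponent = -slope`), matching
#' the usual log-log plot presentation; it is adequate for noiseless or
#' binned data but known to be biased on raw sampled tails, for which the
#' `"ml"` method (maximum likelihood under a truncated zeta distribution,
#' Clauset-style) should be preferred.
#'
#' @param dist Named count vector as returned by [degree_distribution()]
#'   (names are degrees), or a raw integer vector of degrees.
#' @param method `"ols"` (default) or `"ml"`.
#' @param k_min Minimum degree included (default 1).
#' @return A `DegreeFit` list with `exponent`, `intercept`, `r_squared`
#'   and `method` (`intercept`/`r_squared` are `NA` for `"ml"`).
#' @export
fit_powerlaw <- function(dist, method = c("ols", "ml"), k_min = 1L) {
  method <- match.arg(method)
  if (is.null(names(dist))) {
    degrees <- as.integer(dist)
    tab <- table(degrees)
    k <- as.integer(names(tab)); cnt <- as.numeric(tab)
  } else {
    k <- as.integer(names(dist)); cnt <- as.numeric(dist)
    degrees <- rep.int(k, cnt)
  }
  keep <- k >= k_min & cnt > 0
  k <- k[keep]; cnt <- cnt[keep]
  if (length(k) < 3L)
    data_error("power-law fit needs at least 3 distinct degrees >= k_min")
  if (method == "ols") {
    fit <- stats::lm(log(cnt) ~ log(k))
    slope <- unname(stats::coef(fit)[2L])
    y <- log(cnt)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    structure(list(exponent = -slope,
                   intercept = unname(stats::coef(fit)[1L]),
                   r_squared = r2,
                   method = "ols"),
              class = "DegreeFit")
  } else {
    d <- degrees[degrees >= k_min]
    kmax <- max(1e5, max(d))
    ks <- seq.int(k_min, kmax)
    sld <- sum(log(d))
    nll <- function(g) g * sld + length(d) * log(sum(ks^(-g)))
    est <- stats::optimize(nll, c(1.01, 10))$minimum
    structure(list(exponent = est, intercept = NA_real_,
                   r_squared = NA_real_, method = "ml"),
              class = "DegreeFit")
  }
}

#' @export
print.DegreeFit <- function(x, ...) {
  cat(sprintf("Power-law degree fit (%s): exponent %.4f", x$method, x$exponent))
  if (is.finite(x$r_squared)) cat(sprintf(" (log-log R^2 = %.3f)", x$r_squared))
  cat("\n")
  invisible(x)
}
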