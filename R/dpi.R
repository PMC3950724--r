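#' DPI configuration
#'
#' The data processing inequality says that for a Markov chain X -> Y -> Z,
#' `MI(X, Z) <= min(MI(X, Y), MI(Y, Z))`; the weakest edge of a triangle is
#' therefore a candidate indirect interaction.  The tolerance `epsilon`
#' relaxes the test multiplicatively: an edge is removed only when it is
#' weaker than `(1 - epsilon)` times *both* alternative-path edges, so
#' `epsilon = 1` removes nothing (the coarse-pass default: the thresholded
#' graph is reported as a relevance network) while small values such as the
#' refined-run 0.155 prune aggressively.
#'
#' @param tolerance Epsilon in \[0, 1\]; default 1.0 (coarse pass).
#' @return A `DPIConfig` list.
#' @export
dpi_config <- function(tolerance = 1.0) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance < 0 || tolerance > 1)
    config_error("DPI tolerance must be in [0, 1]")
  structure(list(tolerance = tolerance), class = "DPIConfig")
}

#' Remove indirect edges with the data processing inequality
#'
#' Mark-then-sweep semantics: edge `(i, j)` is marked iff some node `k`
#' adjacent to both endpoints satisfies
#' `MI(i,j) < (1 - eps) * MI(i,k)` and `MI(i,j) < (1 - eps) * MI(j,k)`
#' (strict inequalities, so exact ties are kept); all marked edges are then
#' removed simultaneously.  A single simultaneous sweep makes the result
#' independent of edge/triangle enumeration order and of `workers`.
#'
#' @param edges An `EdgeSet` with finite MI weights.
#' @param config A [dpi_config()].
#' @param workers Positive integer; chunks the per-edge marking loop.
#'   Output is identical for any value.
#' @return The surviving `EdgeSet` (a subset of `edges`, original row
#'   order preserved).
#' @export
apply_dpi <- function(edges, config = dpi_config(), workers = 1L) {
  stopifnot(inherits(edges, "EdgeSet"))
  eps <- config$tolerance
  ne <- nrow(edges)
  if (ne == 0L || eps >= 1) return(edges)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  M <- matrix(0, n, n)
  M[cbind(ia, ib)] <- edges$mi
  M[cbind(ib, ia)] <- edges$mi
  fac <- 1 - eps
  chunks <- chunk_indices(ne, workers)
  marked <- unlist(ordered_lapply(chunks, function(es) {
    vapply(es, function(e) {
      w <- edges$mi[e]
      any(w < fac * M[ia[e], ] & w < fac * M[ib[e], ])
    }, NA)
  }, workers = workers), use.names = FALSE)
  out <- edges[!marked, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(edges)
  out
}

#' Count edges removed by a DPI pass
#'
#' @param edges_before,edges_after Edge sets; `edges_after` must be a
#'   subset of `edges_before` (checked by unordered pair key).
#' @return Integer count `|before| - |after|`.
#' @export
dpi_removal_count <- function(edges_before, edges_after) {
  kb <- pair_key(edges_before$gene_a, edges_before$gene_b)
  ka <- pair_key(edges_after$gene_a, edges_after$gene_b)
  if (!all(ka %in% kb))
    data_error("edges_after is not a subset of edges_before")
  length(kb) - length(ka)
}
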