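#' Threshold and permutation-null configuration
#'
#' Controls edge selection: the default keeps the top 10% of gene-pair MI
#' values (the threshold is the MI of the pair at rank
#' `ceiling(keep_top_fraction * N)` when all `N` values are ordered from
#' largest to smallest) and assigns permutation p-values from
#' `n_permutations` independent shuffles.
#'
#' @param keep_top_fraction Fraction of largest MI values retained,
#'   in (0, 1]; default 0.10.
#' @param n_permutations Number of permutations for the null; default 1000.
#' @param permutation_seed Integer seed for the shuffles.
#' @return A `ThresholdConfig` list.
#' @export
threshold_config <- function(keep_top_fraction = 0.10,
                             n_permutations = 1000L,
                             permutation_seed = 1L) {
  if (!is.numeric(keep_top_fraction) || length(keep_top_fraction) != 1L ||
      keep_top_fraction <= 0 || keep_top_fraction > 1)
    config_error("keep_top_fraction must be in (0, 1]")
  if (n_permutations < 1L)
    config_error("n_permutations must be >= 1")
  structure(list(keep_top_fraction = keep_top_fraction,
                 n_permutations = as.integer(n_permutations),
                 permutation_seed = as.integer(permutation_seed)),
            class = "ThresholdConfig")
}

#' Per-gene rank transform
#'
#' Converts each gene row to ranks across samples, ties receiving the
#' average of the ranks they span, so every row sums to `m(m+1)/2`.  Ranks
#' are invariant under any strictly increasing per-gene transform, which is
#' what makes the downstream MI estimate capture monotone nonlinear
#' dependence.  Constant rows (rank correlation undefined) are flagged in
#' the `"constant_genes"` attribute; callers skip their pairs.
#'
#' @param matrix An [expression_matrix()].
#' @return Numeric matrix of ranks with the same dimnames, plus a
#'   `"constant_genes"` character attribute naming flagged rows.
#' @export
rank_transform <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  ranks <- t(apply(matrix, 1L, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(matrix)
  const <- rownames(matrix)[apply(matrix, 1L, function(v) all(v == v[1L]))]
  if (length(const))
    warning(sprintf("constant expression for gene(s): %s; their pairs are skipped",
                    paste(const, collapse = ", ")), call. = FALSE)
  attr(ranks, "constant_genes") <- const
  ranks
}

#' Spearman correlation of two rank vectors
#'
#' Computed as the Pearson product-moment correlation of the rank vectors,
#' which is exact under ties (unlike the 6*sum(d^2) shortcut).
#'
#' @param ranks_a,ranks_b Equal-length rank vectors (m >= 3), neither
#'   constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_correlation <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b) || length(ranks_a) < 3L)
    data_error("rank vectors must have equal length >= 3")
  if (stats::var(ranks_a) == 0 || stats::var(ranks_b) == 0)
    numeric_error("correlation undefined for a constant vector")
  stats::cor(ranks_a, ranks_b)
}

#' Closed-form MI of a bivariate normal from its correlation
#'
#' Under bivariate normality (which the rank transform induces up to a
#' monotone map), mutual information has the closed form
#' `I = -1/2 * log(1 - rho^2)` nats.  `|rho|` is clamped at `1 - 1e-12`
#' before evaluation so downstream thresholding and DPI always see finite,
#' totally ordered weights.
#'
#' @param rho Correlation value(s), `|rho| <= 1` (tiny numeric overshoot
#'   tolerated).
#' @param units `"nats"` (default) or `"bits"` (display only).
#' @return MI value(s), >= 0.
#' @examples
#' mi_from_correlation(0.8)  # 0.5108256
#' @export
mi_from_correlation <- function(rho, units = c("nats", "bits")) {
  units <- match.arg(units)
  if (any(abs(rho) > 1 + 1e-8))
    numeric_error("|rho| > 1: not a correlation")
  r <- pmin(abs(rho), 1 - 1e-12)
  mi <- -0.5 * log1p(-r^2)
  if (units == "bits") mi <- mi / log(2)
  mi
}

#' All-pairs Spearman-transform mutual information
#'
#' Ranks every gene once (`O(n m log m)`), then scores all `n(n-1)/2`
#' unordered pairs by plugging the Spearman correlation into the
#' bivariate-normal MI formula (`O(n^2 m)` total).  Constant genes are
#' dropped with a warning.  The result is independent of `workers` and of
#' pair-evaluation order: chunks are recombined in index order, each
#' pairwise correlation is computed independently, and no randomness is
#' involved.
#'
#' @param matrix An [expression_matrix()].
#' @param workers Positive integer; chunks the gene-block loop across
#'   forked processes.  Output is bitwise identical for any value.
#' @param copula_adjust If `TRUE`, applies the Gaussian-copula correction
#'   `rho = 2*sin(pi*rho_s/6)` before the MI transform.  Default `FALSE`:
#'   the Spearman coefficient is used directly as a Pearson special case.
#' @return An `EdgeSet` data frame with columns `gene_a`, `gene_b`
#'   (canonically ordered by identifier), `rho` and `mi`.
#' @export
pairwise_mi <- function(matrix, workers = 1L, copula_adjust = FALSE) {
  ranks <- rank_transform(matrix)
  const <- attr(ranks, "constant_genes")
  usable <- setdiff(rownames(ranks), const)
  if (length(usable) < 2L)
    data_error("fewer than 2 usable (non-constant) genes")
  ranks <- ranks[usable, , drop = FALSE]
  n <- nrow(ranks)
  tr <- t(ranks)  # samples x genes; cor() works column-wise
  chunks <- chunk_indices(n - 1L, workers)
  parts <- ordered_lapply(chunks, function(is) {
    cc <- stats::cor(tr[, is, drop = FALSE], tr)
    do.call(rbind, lapply(seq_along(is), function(q) {
      i <- is[q]
      js <- seq.int(i + 1L, n)
      data.frame(a = rep.int(i, length(js)), b = js,
                 rho = cc[q, js])
    }))
  }, workers = workers)
  tab <- do.call(rbind, parts)
  rho <- if (copula_adjust) 2 * sin(pi * tab$rho / 6) else tab$rho
  p <- canonical_pairs(usable[tab$a], usable[tab$b])
  edge_set(data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                      rho = rho, mi = mi_from_correlation(rho),
                      stringsAsFactors = FALSE))
}

#' Edge-set constructor
#'
#' Canonicalizes unordered pairs (smaller identifier first), forbids
#' self-loops and duplicate pairs.
#'
#' @param df Data frame with columns `gene_a`, `gene_b`, `mi` and
#'   optionally `rho`.
#' @return An `EdgeSet` (a data frame).
#' @export
edge_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_a", "gene_b", "mi") %in% names(df)))
  p <- canonical_pairs(as.character(df$gene_a), as.character(df$gene_b))
  df$gene_a <- p$gene_a
  df$gene_b <- p$gene_b
  if (any(df$gene_a == df$gene_b))
    data_error("self-loop edge(s) not allowed")
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key))
    data_error("duplicate edge(s) in edge set")
  if (any(!is.finite(df$mi)) || any(df$mi < 0))
    data_error("MI weights must be finite and >= 0")
  rownames(df) <- NULL
  class(df) <- c("EdgeSet", "data.frame")
  df
}

#' Gaussian-kernel mutual information (ARACNE-compatible baseline)
#'
#' Kernel-density MI estimate
#' `mean(log(f_xy(x_i, y_i) / (f_x(x_i) f_y(y_i))))` with product Gaussian
#' kernels; `"auto"` bandwidth is the Silverman rule-of-thumb
#' `1.06 * sd * m^(-1/5)` per dimension.  Truncated at 0.  `O(m^2)` per
#' pair; m >= 10 recommended.
#'
#' @param x,y Equal-length expression vectors.
#' @param bandwidth Positive scalar used for both dimensions, or `"auto"`.
#' @return MI estimate in nats, >= 0.
#' @export
gaussian_kernel_mi <- function(x, y, bandwidth = "auto") {
  m <- length(x)
  if (length(y) != m || m < 3L)
    data_error("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    numeric_error("Gaussian-kernel MI undefined for constant input")
  hx <- if (identical(bandwidth, "auto")) 1.06 * stats::sd(x) * m^(-0.2)
        else as.numeric(bandwidth)
  hy <- if (identical(bandwidth, "auto")) 1.06 * stats::sd(y) * m^(-0.2)
        else as.numeric(bandwidth)
  if (hx <= 0 || hy <= 0) config_error("bandwidth must be positive")
  Kx <- exp(-(outer(x, x, "-"))^2 / (2 * hx^2))
  Ky <- exp(-(outer(y, y, "-"))^2 / (2 * hy^2))
  fj <- rowSums(Kx * Ky)
  fx <- rowSums(Kx)
  fy <- rowSums(Ky)
  max(0, mean(log(m * fj / (fx * fy))))
}

# All-pairs Gaussian-kernel MI over an expression matrix; kernel matrices
# are computed once per gene.  Intended for benchmark-scale inputs only
# (memory is n * m^2 doubles).
pairwise_gaussian_mi <- function(matrix, workers = 1L) {
  n <- nrow(matrix)
  m <- ncol(matrix)
  if (n * m * m > 5e8)
    numeric_error("all-pairs Gaussian-kernel MI is restricted to benchmark scale")
  ids <- rownames(matrix)
  K <- lapply(seq_len(n), function(i) {
    x <- matrix[i, ]
    h <- 1.06 * stats::sd(x) * m^(-0.2)
    exp(-(outer(x, x, "-"))^2 / (2 * h^2))
  })
  Ksum <- vapply(K, rowSums, numeric(m))
  chunks <- chunk_indices(n - 1L, workers)
  parts <- ordered_lapply(chunks, function(is) {
    do.call(rbind, lapply(is, function(i) {
      js <- seq.int(i + 1L, n)
      mi <- vapply(js, function(j) {
        fj <- rowSums(K[[i]] * K[[j]])
        max(0, mean(log(m * fj / (Ksum[, i] * Ksum[, j]))))
      }, 0)
      data.frame(a = rep.int(i, length(js)), b = js, mi = mi)
    }))
  }, workers = workers)
  tab <- do.call(rbind, parts)
  p <- canonical_pairs(ids[tab$a], ids[tab$b])
  edge_set(data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                      rho = NA_real_, mi = tab$mi, stringsAsFactors = FALSE))
}

#' Permutation p-value for an observed MI
#'
#' Null distribution from independent shuffles of `y` across samples; the
#' MI of each shuffled pair is recomputed through the Spearman path.  Uses
#' the add-one estimator `p = (1 + #{MI_perm >= MI_obs}) / (1 + B)` so p is
#' never exactly zero.
#'
#' @param x,y Expression vectors of equal length.
#' @param observed_mi Observed MI; computed from `(x, y)` if `NULL`.
#' @param config A [threshold_config()] (supplies `n_permutations` and
#'   `permutation_seed`).
#' @return Scalar p-value in (0, 1\].
#' @export
permutation_pvalue <- function(x, y, observed_mi = NULL,
                               config = threshold_config()) {
  m <- length(x)
  ra <- rank(x, ties.method = "average")
  rb <- rank(y, ties.method = "average")
  if (is.null(observed_mi))
    observed_mi <- mi_from_correlation(spearman_correlation(ra, rb))
  za <- as.numeric(scale(ra))
  zb <- as.numeric(scale(rb))
  B <- config$n_permutations
  exceed <- with_seed(config$permutation_seed, {
    perms <- vapply(seq_len(B), function(i) sample.int(m), integer(m))
    rho_p <- colSums(za * matrix(zb[perms], m, B)) / (m - 1)
    sum(mi_from_correlation(rho_p) >= observed_mi)
  })
  (1 + exceed) / (1 + B)
}

#' MI threshold from the keep-top rule
#'
#' Returns the MI of the element at rank `ceiling(keep_top_fraction * N)`
#' when the `N` values are arranged from largest to smallest, so that
#' "keep MI >= threshold" retains the top fraction (plus any exact ties).
#'
#' @param mi_values Non-empty numeric vector of MI values.
#' @param config A [threshold_config()].
#' @return The threshold (same units as `mi_values`).
#' @examples
#' select_threshold(1:100, threshold_config(0.10))  # 91
#' @export
select_threshold <- function(mi_values, config = threshold_config()) {
  if (!length(mi_values)) data_error("empty MI collection")
  k <- ceiling(config$keep_top_fraction * length(mi_values))
  sort(mi_values, decreasing = TRUE)[k]
}

#' Read / write edge lists
#'
#' Tab-delimited, Cytoscape-importable: `geneA<TAB>geneB<TAB>MI`, one edge
#' per line in canonical pair order, MI printed with 6 decimal places.
#' Lines starting with `#` are ignored on read; two-column files load with
#' `mi = NA` replaced by 1 (presence-only gold standards).
#'
#' @param edges An `EdgeSet`.
#' @param path File path.
#' @param header_lines Optional character vector written first, each
#'   prefixed with `"# "`.
#' @return `path` invisibly (write); an `EdgeSet` (read).
#' @export
write_edges <- function(edges, path, header_lines = NULL) {
  stopifnot(inherits(edges, "EdgeSet"))
  out <- character(0)
  if (length(header_lines)) out <- paste0("# ", header_lines)
  out <- c(out, sprintf("%s\t%s\t%.6f", edges$gene_a, edges$gene_b, edges$mi))
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) data_error(sprintf("edge file not found: %s", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    parse_error(sprintf("%s: edge lines must have 2 or 3 tab-separated fields",
                        path))
  mi <- vapply(parts, function(p)
    if (length(p) == 3L) suppressWarnings(as.numeric(p[3L])) else 1, 0)
  if (any(is.na(mi)))
    parse_error(sprintf("%s: non-numeric MI value", path))
  edge_set(data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                      gene_b = vapply(parts, `[[`, "", 2L),
                      rho = NA_real_, mi = mi, stringsAsFactors = FALSE))
}
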