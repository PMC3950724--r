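# Fixtures and independent oracles, all generated in code.

# Random expression matrix with unique ids.
rand_expr <- function(n, m, seed = 1L) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n * m), n, m,
                           dimnames = list(sprintf("g%03d", seq_len(n)),
                                           sprintf("c%03d", seq_len(m)))))
}

write_toy_expression_file <- function(path,
                                      ids = c("g1", "g2", "g3"),
                                      chips = c("c1", "c2", "c3", "c4"),
                                      values = matrix(seq_len(12) / 7, 3, 4)) {
  lines <- c(paste(c("id", chips), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], format(values[i, ], digits = 15)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

# Brute-force DPI oracle: literal triple loop over all node triples.
dpi_oracle <- function(edges, eps) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    W[edges$gene_a[e], edges$gene_b[e]] <- edges$mi[e]
    W[edges$gene_b[e], edges$gene_a[e]] <- edges$mi[e]
  }
  marked <- rep(FALSE, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges$gene_a[e]; j <- edges$gene_b[e]; w <- edges$mi[e]
    for (k in nodes) {
      if (k == i || k == j) next
      if (W[i, k] > 0 && W[j, k] > 0 &&
          w < (1 - eps) * W[i, k] && w < (1 - eps) * W[j, k]) {
        marked[e] <- TRUE
        break
      }
    }
  }
  edges[!marked, , drop = FALSE]
}

# Random weighted graph on <= max_nodes nodes (positive MI weights).
rand_graph <- function(seed, max_nodes = 12L, p_edge = 0.4) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1L)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1L] <- TRUE
  edge_set(data.frame(gene_a = ids[pairs[keep, 1L]],
                      gene_b = ids[pairs[keep, 2L]],
                      rho = NA_real_,
                      mi = runif(sum(keep), 0.01, 1),
                      stringsAsFactors = FALSE))
}

# Clique-union graph: one clique per element of `sizes`, unit weights,
# plus optional bridge edges given as list of c(node_a, node_b).
clique_graph <- function(sizes, bridges = list()) {
  ids <- character(0); ea <- character(0); eb <- character(0)
  offset <- 0L
  for (s in sizes) {
    mem <- sprintf("n%02d", offset + seq_len(s))
    ids <- c(ids, mem)
    if (s > 1L) {
      pr <- t(combn(s, 2L))
      ea <- c(ea, mem[pr[, 1L]])
      eb <- c(eb, mem[pr[, 2L]])
    }
    offset <- offset + s
  }
  for (b in bridges) { ea <- c(ea, b[1L]); eb <- c(eb, b[2L]) }
  network(edge_set(data.frame(gene_a = ea, gene_b = eb, rho = NA_real_,
                              mi = 1, stringsAsFactors = FALSE)),
          nodes = ids)
}

# Planted-partition graph: `b` blocks of `size` nodes; returns network +
# true block labels.
planted_partition <- function(seed, b = 5L, size = 20L,
                              p_in = 0.5, p_out = 0.02) {
  set.seed(seed)
  n <- b * size
  blocks <- rep(seq_len(b), each = size)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(n, 2L))
  same <- blocks[pairs[, 1L]] == blocks[pairs[, 2L]]
  keep <- runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  e <- pairs[keep, , drop = FALSE]
  net <- network(edge_set(data.frame(gene_a = ids[e[, 1L]],
                                     gene_b = ids[e[, 2L]],
                                     rho = NA_real_, mi = 1,
                                     stringsAsFactors = FALSE)),
                 nodes = ids)
  list(net = net, truth = stats::setNames(blocks, ids))
}

# Condition-removing fixture: 190 N(0,1) noise chips + 10 chips where both
# genes are strongly co-elevated (+5 with 0.1 jitter).
planted_condition_fixture <- function(seed, n_noise = 190L, n_planted = 10L) {
  set.seed(seed)
  x <- c(rnorm(n_noise), 5 + rnorm(n_planted, 0, 0.1))
  y <- c(rnorm(n_noise), 5 + rnorm(n_planted, 0, 0.1))
  m <- n_noise + n_planted
  chips <- sprintf("chip%03d", seq_len(m))
  vals <- rbind(gA = x, gB = y, gC = rnorm(m))
  colnames(vals) <- chips
  list(expr = expression_matrix(vals),
       planted = chips[n_noise + seq_len(n_planted)])
}

# Connected-component labels of a Network (union-find over the edge list).
graph_components <- function(net) {
  nodes <- net$nodes
  parent <- stats::setNames(seq_along(nodes), nodes)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(net$edges))) {
    a <- findp(match(net$edges$gene_a[e], nodes))
    b <- findp(match(net$edges$gene_b[e], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), findp, 0L)
  stats::setNames(match(roots, unique(roots)), nodes)
}

# Exact discrete power-law sampler (truncated zeta inverse CDF).
sample_discrete_powerlaw <- function(n, gamma, kmax = 100000L) {
  p <- (seq_len(kmax))^(-gamma)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

# Independent Spearman-transform MI for a single pair (scalar oracle path).
scalar_spearman_mi <- function(x, y) {
  r <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  -0.5 * log(1 - min(abs(r), 1 - 1e-12)^2)
}
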