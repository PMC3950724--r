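#' Markov clustering configuration
#'
#' MCL simulates flow along a random walk on the graph: *expansion* (a
#' matrix power) spreads flow along paths, *inflation* (an entrywise
#' Hadamard power followed by column renormalization) sharpens it toward
#' attractors; alternating the two until a fixed point yields hard
#' clusters.  Higher inflation gives more, smaller clusters.
#'
#' @param inflation Hadamard-power exponent (> 1, default 2.0).
#' @param expansion Matrix-power exponent (integer >= 2, default 2).
#' @param prune_threshold Transition probabilities below this are zeroed
#'   each iteration (default 1e-5).
#' @param max_iterations Iteration cap (default 100).
#' @param convergence_tol Max absolute change declaring a fixed point
#'   (default 1e-8).
#' @param add_self_loops Add a self-loop per node weighted by its maximum
#'   incident MI (stabilizes convergence; default `TRUE`).
#' @param use_weights Use MI weights as similarities (default `TRUE`);
#'   `FALSE` clusters the unweighted topology.
#' @return An `MCLConfig` list.
#' @export
mcl_config <- function(inflation = 2.0, expansion = 2L,
                       prune_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-8, add_self_loops = TRUE,
                       use_weights = TRUE) {
  if (inflation <= 1) config_error("inflation must be > 1")
  if (expansion < 2L || expansion != as.integer(expansion))
    config_error("expansion must be an integer >= 2")
  if (prune_threshold < 0 || prune_threshold >= 1)
    config_error("prune_threshold must be in [0, 1)")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 add_self_loops = add_self_loops,
                 use_weights = use_weights),
            class = "MCLConfig")
}

#' Partition a network into subnetworks by Markov clustering
#'
#' Builds the column-stochastic transition matrix from the MI weights
#' (plus optional self-loops), iterates expansion -> inflation -> prune ->
#' renormalize until the matrix change drops below `convergence_tol`, and
#' reads clusters from the attractor systems of the limit matrix.  Nodes
#' attracted to more than one system are assigned to the larger cluster,
#' ties broken by the lexicographically smallest member identifier, so the
#' result is deterministic.  Nodes in different connected components are
#' never co-clustered (the transition matrix is block diagonal).
#'
#' @param network A [network()] with nonnegative weights.
#' @param config An [mcl_config()].
#' @return An `MCLPartition`: list with `assignment` (named integer vector,
#'   cluster indices contiguous from 1, clusters ordered by descending
#'   size), `n_clusters`, `sizes`, and `converged`.
#' @export
mcl_cluster <- function(network, config = mcl_config()) {
  stopifnot(inherits(network, "Network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0L) data_error("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e)) {
    w <- if (config$use_weights) e$mi else rep(1, nrow(e))
    ia <- match(e$gene_a, nodes); ib <- match(e$gene_b, nodes)
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  if (config$add_self_loops) {
    loop <- apply(A, 2L, max)
    loop[loop == 0] <- 1
    diag(A) <- loop
  } else if (any(colSums(A) == 0)) {
    diag(A)[colSums(A) == 0] <- 1  # keep isolated columns stochastic
  }
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    E <- M
    for (k in seq_len(config$expansion - 1L)) E <- E %*% M
    E <- E^config$inflation
    E <- sweep(E, 2L, colSums(E), "/")
    # prune on normalized probabilities so high inflation cannot empty
    # a column, then renormalize
    E[E < config$prune_threshold] <- 0
    E <- sweep(E, 2L, colSums(E), "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iterations; interpreting current matrix",
            call. = FALSE)
  interpret_mcl_matrix(M, nodes, config$prune_threshold, converged)
}

# Read attractor systems off a (near-)idempotent MCL matrix and resolve
# overlaps deterministically.
interpret_mcl_matrix <- function(M, nodes, tol, converged) {
  n <- length(nodes)
  attractors <- which(diag(M) > tol)
  if (!length(attractors)) attractors <- seq_len(n)
  members <- lapply(attractors, function(i) which(M[i, ] > tol))
  # merge attractor systems sharing any member (union-find)
  parent <- seq_along(attractors)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- integer(n)
  for (q in seq_along(attractors)) {
    for (v in members[[q]]) {
      if (owner[v] == 0L) owner[v] <- q
      else {
        a <- findp(owner[v]); b <- findp(q)
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_along(attractors), findp, 0L)
  sys_id <- match(root, unique(root))
  clusters <- lapply(seq_along(unique(root)), function(s)
    sort(unique(unlist(members[sys_id == s]))))
  # orphan nodes (numerically unattracted): follow their largest column mass
  assigned <- sort(unique(unlist(clusters)))
  for (v in setdiff(seq_len(n), assigned)) {
    i <- which.max(M[, v])
    s <- which(vapply(clusters, function(cl) i %in% cl, NA))[1L]
    if (is.na(s)) clusters <- c(clusters, list(v))
    else clusters[[s]] <- sort(c(clusters[[s]], v))
  }
  # resolve residual overlaps: larger cluster wins, then smallest member id
  sizes <- lengths(clusters)
  minid <- vapply(clusters, function(cl) min(nodes[cl]), "")
  assignment <- integer(n)
  for (v in seq_len(n)) {
    cand <- which(vapply(clusters, function(cl) v %in% cl, NA))
    if (length(cand) > 1L) {
      cand <- cand[order(-sizes[cand], minid[cand])]
    }
    assignment[v] <- cand[1L]
  }
  # relabel contiguously by descending final size (ties: smallest member id)
  fin_sizes <- tabulate(assignment, nbins = length(clusters))
  keep <- which(fin_sizes > 0L)
  ord <- keep[order(-fin_sizes[keep], minid[keep])]
  relabel <- integer(length(clusters))
  relabel[ord] <- seq_along(ord)
  assignment <- relabel[assignment]
  names(assignment) <- nodes
  structure(list(assignment = assignment,
                 n_clusters = length(ord),
                 sizes = as.integer(sort(tabulate(assignment), decreasing = TRUE)),
                 converged = converged),
            class = "MCLPartition")
}

#' Cluster sizes of a partition
#'
#' @param partition An `MCLPartition`.
#' @return Integer vector of cluster sizes in descending order; sums to
#'   the node count.
#' @export
partition_sizes <- function(partition) {
  stopifnot(inherits(partition, "MCLPartition"))
  partition$sizes
}

#' @export
print.MCLPartition <- function(x, ...) {
  cat(sprintf("MCL partition: %d nodes in %d clusters (sizes: %s%s)%s\n",
              length(x$assignment), x$n_clusters,
              paste(utils::head(x$sizes, 8L), collapse = ", "),
              if (x$n_clusters > 8L) ", ..." else "",
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.  Used to score
#' cluster recovery against a known ground truth.
#'
#' @param a,b Equal-length label vectors (any type coercible to factor).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) data_error("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
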