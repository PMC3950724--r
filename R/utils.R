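# Internal helpers: condition classes, seeded evaluation, pair canonicalisation.

config_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ganet_config_error", "ganet_error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("ganet_data_error", "ganet_error")))
}

parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("ganet_parse_error", "ganet_data_error",
                                     "ganet_error")))
}

numeric_error <- function(msg) {
  stop(errorCondition(msg, class = c("ganet_numeric_error", "ganet_error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so library calls never
#' perturb user-level randomness.
#'
#' @param seed Integer seed (kept below 2^31 by callers).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical unordered pair: gene_a is the lexicographically smaller identifier.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(gene_a = a, gene_b = b)
}

pair_key <- function(a, b) {
  p <- canonical_pairs(a, b)
  paste(p$gene_a, p$gene_b, sep = "\r")
}

# Split 1:n into at most `workers` contiguous chunks (deterministic).
chunk_indices <- function(n, workers) {
  workers <- max(1L, as.integer(workers))
  if (n == 0L) return(list())
  k <- min(workers, n)
  if (k == 1L) return(list(seq_len(n)))
  split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
}

# Ordered parallel map: results identical for any worker count because
# chunk contents are recombined in index order and no RNG runs in workers.
ordered_lapply <- function(X, FUN, workers = 1L) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || length(X) < 2L ||
      .Platform$OS.type == "windows") return(lapply(X, FUN))
  parallel::mclapply(X, FUN, mc.cores = workers, mc.preschedule = TRUE)
}

# 32-bit FNV-1a over a character scalar; provenance hashes for output headers.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
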