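#' Synthetic benchmark configuration
#'
#' Parameters of the steady-state expression simulator.  The generator
#' emulates SynTReN-style data: a known (scale-free) regulatory topology,
#' Hill-type nonlinear transfer functions, multiplicative biological noise
#' propagated through the cascade, and additive experimental noise on the
#' measured values.  Typical benchmark shapes follow the published
#' evaluation protocol: a few hundred genes at 200-1000 samples.
#'
#' @param n_genes Number of genes (>= 10 for generated topologies).
#' @param n_samples Number of samples (chips) to draw.
#' @param topology_source `"scale_free"` (preferential-attachment
#'   surrogate) or a data frame edge list with columns
#'   `regulator`, `target`, `sign` (`"activation"`/`"repression"`).
#' @param mean_in_degree Expected regulators per non-root gene
#'   (default 1.5).
#' @param hill_coefficient Hill cooperativity exponent (default 2).
#' @param basal_expression Basal expression level in \[0, 1)
#'   (default 0.1).
#' @param biological_noise_sd SD of the multiplicative log-normal noise
#'   applied per gene during propagation (default 0.1).
#' @param experimental_noise_sd SD of the additive measurement noise
#'   (default 0.05).
#' @param activation_prob Probability a regulatory edge is an activation
#'   (default 0.7; repression otherwise).
#' @param seed Integer master seed; topology and expression draws are
#'   both derived from it.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 400L, n_samples = 500L,
                              topology_source = "scale_free",
                              mean_in_degree = 1.5, hill_coefficient = 2,
                              basal_expression = 0.1,
                              biological_noise_sd = 0.1,
                              experimental_noise_sd = 0.05,
                              activation_prob = 0.7, seed = 1L) {
  if (n_genes < 2L || n_samples < 3L)
    config_error("n_genes must be >= 2 and n_samples >= 3")
  if (biological_noise_sd < 0 || experimental_noise_sd < 0)
    config_error("noise SDs must be >= 0")
  if (basal_expression < 0 || basal_expression >= 1)
    config_error("basal_expression must be in [0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 topology_source = topology_source,
                 mean_in_degree = mean_in_degree,
                 hill_coefficient = hill_coefficient,
                 basal_expression = basal_expression,
                 biological_noise_sd = biological_noise_sd,
                 experimental_noise_sd = experimental_noise_sd,
                 activation_prob = activation_prob,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate (or validate) a gold-standard regulatory topology
#'
#' In `"scale_free"` mode, genes are added in order and each draws a
#' Poisson(`mean_in_degree`) number of regulators from earlier genes with
#' probability proportional to `out-degree + 1` (preferential attachment,
#' giving a scale-free out-degree tail and an acyclic network).  Signs
#' are activation with probability `activation_prob`.  Deterministic per
#' `config$seed`.  A user-supplied edge list is validated (no
#' self-regulation; pairs unique after direction removal) and returned
#' verbatim.
#'
#' @param config A [simulation_config()].
#' @return A `GoldStandardNetwork`: list with `interactions` (data frame
#'   `regulator`, `target`, `sign`) and `genes`.
#' @export
generate_topology <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.data.frame(config$topology_source)) {
    inter <- config$topology_source
    stopifnot(all(c("regulator", "target") %in% names(inter)))
    if (is.null(inter$sign)) inter$sign <- "activation"
    if (any(inter$regulator == inter$target))
      data_error("self-regulation is not allowed in a gold standard")
    if (anyDuplicated(pair_key(inter$regulator, inter$target)))
      data_error("duplicate interaction (after direction removal) in gold standard")
    genes <- sort(unique(c(inter$regulator, inter$target)))
    return(structure(list(interactions = inter, genes = genes),
                     class = "GoldStandardNetwork"))
  }
  n <- config$n_genes
  if (n < 10L) config_error("generated topologies need n_genes >= 10")
  genes <- sprintf("G%04d", seq_len(n))
  with_seed(config$seed, {
    out_deg <- integer(n)
    reg <- integer(0); tgt <- integer(0)
    for (t in 2:n) {
      k <- min(t - 1L, stats::rpois(1L, config$mean_in_degree))
      if (k == 0L) next
      probs <- out_deg[seq_len(t - 1L)] + 1
      r <- sample.int(t - 1L, k, prob = probs)
      out_deg[r] <- out_deg[r] + 1L
      reg <- c(reg, r); tgt <- c(tgt, rep.int(t, k))
    }
    sign <- ifelse(stats::runif(length(reg)) < config$activation_prob,
                   "activation", "repression")
    structure(list(interactions = data.frame(regulator = genes[reg],
                                             target = genes[tgt],
                                             sign = sign,
                                             stringsAsFactors = FALSE),
                   genes = genes),
              class = "GoldStandardNetwork")
  })
}

#' Simulate steady-state expression over a known topology
#'
#' Root genes (no regulators) model external inputs and are drawn
#' Uniform(0, 1) per sample.  Every regulated gene is
#' `basal + (1 - basal) * mean(f(regulators))`, where `f` is a Hill
#' function with half-saturation 0.5: `x^h / (0.5^h + x^h)` for
#' activation, `0.5^h / (0.5^h + x^h)` for repression.  Multiplicative
#' log-normal biological noise is applied during propagation (so it feeds
#' forward through the cascade); additive Gaussian experimental noise is
#' applied to the final matrix, which is clamped to stay positive.
#' Cyclic (user-supplied) topologies are resolved by bounded fixed-point
#' iteration.
#'
#' @param gold A [generate_topology()] result.
#' @param config A [simulation_config()].
#' @param seed Seed for the expression draw; defaults to
#'   `config$seed + 1` so topology and data use distinct streams.
#' @return A `SimulatedDataset`: list with `expression`
#'   (an [expression_matrix()]), `gold` and `config`.
#' @export
simulate_expression <- function(gold, config, seed = config$seed + 1L) {
  stopifnot(inherits(gold, "GoldStandardNetwork"))
  genes <- gold$genes
  n <- length(genes)
  m <- config$n_samples
  h <- config$hill_coefficient
  Kh <- 0.5^h
  regs <- split(seq_len(nrow(gold$interactions)),
                factor(gold$interactions$target, levels = genes))
  with_seed(seed, {
    X <- matrix(NA_real_, n, m, dimnames = list(genes, sprintf("S%04d", 1:m)))
    order_idx <- topo_order(gold, genes)
    if (!is.null(order_idx)) {
      for (g in order_idx) {
        ridx <- regs[[g]]
        if (!length(ridx)) {
          base <- stats::runif(m)
        } else {
          rg <- match(gold$interactions$regulator[ridx], genes)
          act <- gold$interactions$sign[ridx] == "activation"
          f <- matrix(0, length(ridx), m)
          for (q in seq_along(ridx)) {
            xh <- X[rg[q], ]^h
            f[q, ] <- if (act[q]) xh / (Kh + xh) else Kh / (Kh + xh)
          }
          base <- config$basal_expression +
            (1 - config$basal_expression) * colMeans(f)
        }
        noise <- if (config$biological_noise_sd > 0)
          exp(stats::rnorm(m, 0, config$biological_noise_sd)) else 1
        X[g, ] <- base * noise
      }
    } else {
      X <- simulate_cyclic(gold, config, genes, m, regs)
    }
    if (config$experimental_noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * m, 0, config$experimental_noise_sd),
                      n, m)
    X <- pmax(X, 1e-6)
    structure(list(expression = expression_matrix(X),
                   gold = gold, config = config),
              class = "SimulatedDataset")
  })
}

# Kahn topological order over gene indices; NULL when the graph is cyclic.
topo_order <- function(gold, genes) {
  n <- length(genes)
  rg <- match(gold$interactions$regulator, genes)
  tg <- match(gold$interactions$target, genes)
  indeg <- tabulate(tg, nbins = n)
  out <- split(tg, factor(rg, levels = seq_len(n)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) NULL else ord
}

# Bounded fixed-point iteration for cyclic user-supplied topologies.
simulate_cyclic <- function(gold, config, genes, m, regs) {
  n <- length(genes)
  h <- config$hill_coefficient
  Kh <- 0.5^h
  roots <- which(lengths(regs) == 0L)
  X <- matrix(0.5, n, m, dimnames = list(genes, sprintf("S%04d", 1:m)))
  X[roots, ] <- stats::runif(length(roots) * m)
  bio <- matrix(exp(stats::rnorm(n * m, 0, config$biological_noise_sd)), n, m)
  for (iter in seq_len(200L)) {
    Xold <- X
    for (g in setdiff(seq_len(n), roots)) {
      ridx <- regs[[g]]
      rg <- match(gold$interactions$regulator[ridx], genes)
      act <- gold$interactions$sign[ridx] == "activation"
      f <- matrix(0, length(ridx), m)
      for (q in seq_along(ridx)) {
        xh <- Xold[rg[q], ]^h
        f[q, ] <- if (act[q]) xh / (Kh + xh) else Kh / (Kh + xh)
      }
      X[g, ] <- (config$basal_expression +
                   (1 - config$basal_expression) * colMeans(f)) * bio[g, ]
    }
    if (max(abs(X - Xold)) < 1e-8) return(X)
  }
  numeric_error(sprintf(
    "fixed-point iteration did not converge; offending cycle involves: %s",
    paste(utils::head(genes[setdiff(seq_len(n), roots)], 10L),
          collapse = ", ")))
}

#' Read / write gold-standard interaction lists
#'
#' Three-column tab-delimited text `regulator<TAB>target<TAB>sign`
#' (sign optional on read, defaulting to activation).
#'
#' @param gold A `GoldStandardNetwork`.
#' @param path File path.
#' @return `path` invisibly (write); a `GoldStandardNetwork` (read).
#' @export
write_gold_standard <- function(gold, path) {
  writeLines(sprintf("%s\t%s\t%s", gold$interactions$regulator,
                     gold$interactions$target, gold$interactions$sign),
             path, sep = "\n")
  invisible(path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) data_error(sprintf("gold-standard file not found: %s", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    parse_error(sprintf("%s: gold-standard lines must have 2 or 3 fields", path))
  inter <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                      target = vapply(parts, `[[`, "", 2L),
                      sign = vapply(parts, function(p)
                        if (length(p) == 3L) p[3L] else "activation", ""),
                      stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = max(2L, length(unique(c(inter$regulator,
                                                             inter$target)))),
                           topology_source = inter)
  generate_topology(cfg)
}
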