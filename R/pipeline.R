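#' Parse and validate a run configuration file
#'
#' Flat `key = value` text, `#` comments and optional `[section]` headers
#' ignored.  All problems are collected and reported together; unknown
#' keys produce warnings, invalid values errors.  Omitted keys take the
#' documented defaults (keep top 10%, coarse DPI tolerance 1.0, condition
#' alpha 1e-4, top_k 10).
#'
#' @param path Path to a config file.
#' @return A `RunConfig` list with nested
#'   [threshold_config()]/[dpi_config()]/[mcl_config()]/
#'   [condition_config()] objects; or a config error listing every
#'   problem.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  errs <- character(0)
  bad <- lengths(kv) != 2L
  if (any(bad))
    errs <- c(errs, sprintf("malformed line (expected key = value): '%s'",
                            lines[bad]))
  kv <- kv[!bad]
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- c("input", "edges", "output_dir", "keep_top", "n_permutations",
             "permutation_seed", "mi_threshold", "dpi_tolerance",
             "inflation", "expansion", "prune_threshold", "alpha", "top_k",
             "min_samples", "run_conditions", "workers", "seed",
             "log_level", "n_genes", "n_samples", "mean_in_degree")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    warning(sprintf("unknown config key(s) ignored: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  getv <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  num <- function(key, default) {
    v <- getv(key, NULL)
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) { errs[[length(errs) + 1L]] <<-
      sprintf("key '%s': '%s' is not a number", key, v); return(default) }
    x
  }
  input <- getv("input", NULL)
  if (is.null(input)) errs <- c(errs, "missing required key 'input'")
  keep_top <- num("keep_top", 0.10)
  if (keep_top <= 0 || keep_top > 1)
    errs <- c(errs, "keep_top must be in (0, 1]")
  eps <- num("dpi_tolerance", 1.0)
  if (eps < 0 || eps > 1)
    errs <- c(errs, "dpi_tolerance must be in [0, 1]")
  alpha <- num("alpha", 1e-4)
  if (alpha <= 0 || alpha >= 1) errs <- c(errs, "alpha must be in (0, 1)")
  inflation <- num("inflation", 2.0)
  if (inflation <= 1) errs <- c(errs, "inflation must be > 1")
  workers <- num("workers", 1)
  if (workers < 1) errs <- c(errs, "workers must be >= 1")
  log_level <- getv("log_level", "info")
  if (!log_level %in% c("quiet", "info", "debug"))
    errs <- c(errs, sprintf("log_level '%s' not one of quiet/info/debug",
                            log_level))
  if (length(errs))
    config_error(paste(c("invalid configuration:",
                         paste0("  - ", errs)), collapse = "\n"))
  structure(list(
    input = input,
    edges = getv("edges", NULL),
    output_dir = getv("output_dir", "ganet-out"),
    threshold = threshold_config(keep_top,
                                 as.integer(num("n_permutations", 1000)),
                                 as.integer(num("permutation_seed",
                                                num("seed", 1)))),
    mi_threshold = num("mi_threshold", NA_real_),
    dpi = dpi_config(eps),
    mcl = mcl_config(inflation = inflation,
                     expansion = as.integer(num("expansion", 2)),
                     prune_threshold = num("prune_threshold", 1e-5)),
    conditions = condition_config(alpha, as.integer(num("top_k", 10)),
                                  as.integer(num("min_samples", 100))),
    run_conditions = tolower(getv("run_conditions", "false")) %in%
      c("true", "yes", "1"),
    workers = as.integer(workers),
    seed = as.integer(num("seed", 1)),
    log_level = log_level),
    class = "RunConfig")
}

provenance_header <- function(config, stage) {
  # hash the analysis-relevant settings only (not output locations)
  hashed <- unclass(config)
  hashed$output_dir <- NULL
  cfg_hash <- fnv1a32(paste(deparse(hashed), collapse = ""))
  c(sprintf("ganet %s; stage=%s; seed=%d; config_hash=%s",
            as.character(utils::packageVersion("ganet")), stage,
            config$seed %||% 0L, cfg_hash))
}

#' Run the full analysis pipeline
#'
#' build -> (optional refine to a fixed MI threshold) -> MCL clustering ->
#' summary, plus the condition-removing annotation when requested.  All
#' tabular outputs are tab-delimited with `#`-prefixed provenance headers
#' (package version, config hash, seed) and are Cytoscape-importable.
#'
#' @param config A `RunConfig` from [validate_config()] (or a compatible
#'   list).
#' @return The output-directory manifest: named list of written file
#'   paths, invisibly, with the fitted objects in attributes.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  log_info <- function(fmt, ...) if (config$log_level != "quiet")
    message(sprintf("[ganet %6.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  expr <- read_expression(config$input)
  log_info("loaded %d genes x %d chips from %s", nrow(expr), ncol(expr),
           config$input)
  net <- build_network(expr, config$threshold, config$dpi,
                       workers = config$workers)
  if (is.finite(config$mi_threshold %||% NA_real_) &&
      config$mi_threshold > net$threshold)
    net <- refine(net, config$mi_threshold, config$dpi,
                  workers = config$workers)
  log_info("network: %d nodes, %d edges (threshold %.4g, DPI tolerance %.3g)",
           length(net$nodes), nrow(net$edges), net$threshold,
           net$dpi_tolerance)
  part <- mcl_cluster(net, config$mcl)
  log_info("MCL: %d clusters", part$n_clusters)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config, "pipeline")
  f_edges <- file.path(config$output_dir, "edges.tsv")
  write_edges(net$edges, f_edges, header_lines = hdr)
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  f_nodes <- file.path(config$output_dir, "nodes.tsv")
  writeLines(c(paste0("# ", hdr), "# gene\tdegree\tcluster",
               sprintf("%s\t%d\t%d", net$nodes, as.integer(deg),
                       part$assignment[net$nodes])),
             f_nodes, sep = "\n")
  dd <- degree_distribution(net)
  fit <- tryCatch(fit_powerlaw(dd), error = function(e) NULL)
  f_summary <- file.path(config$output_dir, "summary.tsv")
  writeLines(c(paste0("# ", hdr),
               sprintf("nodes\t%d", length(net$nodes)),
               sprintf("edges\t%d", nrow(net$edges)),
               sprintf("mean_degree\t%.4f",
                       2 * nrow(net$edges) / max(1L, length(net$nodes))),
               sprintf("mi_threshold\t%.6f", net$threshold),
               sprintf("dpi_tolerance\t%.4f", net$dpi_tolerance),
               sprintf("clusters\t%d", part$n_clusters),
               sprintf("degree_exponent\t%s",
                       if (is.null(fit)) "NA" else sprintf("%.4f", fit$exponent))),
             f_summary, sep = "\n")
  manifest <- list(edges = f_edges, nodes = f_nodes, summary = f_summary)
  if (isTRUE(config$run_conditions)) {
    recs <- significant_conditions(net$edges, expr, config$conditions,
                                   workers = config$workers)
    f_cond <- file.path(config$output_dir, "conditions.tsv")
    write_conditions(recs, f_cond, header_lines = hdr)
    manifest$conditions <- f_cond
    log_info("conditions: %d significant (edge, chip) records", nrow(recs))
  }
  f_manifest <- file.path(config$output_dir, "MANIFEST.tsv")
  writeLines(c(paste0("# ", hdr),
               sprintf("%s\t%s", names(manifest), unlist(manifest))),
             f_manifest, sep = "\n")
  manifest$manifest <- f_manifest
  structure(invisible(manifest), network = net, partition = part)
}
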