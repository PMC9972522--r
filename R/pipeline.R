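#' Assemble a pipeline configuration
#'
#' Collects everything [run_pipeline()] needs. Expression inputs and
#' pre-built networks are mutually exclusive per condition; give either
#' `expr_a`/`expr_b` (paths or matrices) or `net_a`/`net_b` (paths or
#' [weighted_network()] objects).
#'
#' @param expr_a,expr_b Expression inputs (TSV paths or matrices).
#' @param net_a,net_b Pre-built network inputs (paths or networks).
#' @param coexpression [coexpression_params()] for network construction.
#' @param c_grid,k,min_objective Mining parameters (see
#'   [top_k_contrast()]).
#' @param direction `"both"`, `"ab"` or `"ba"`.
#' @param gmt Optional GMT path or [gene_set_collection()] for enrichment
#'   of the rank-1 node sets.
#' @param reference_sets Optional named list of gene sets to overlap-test
#'   against the mined subgraphs (Fisher, one-sided).
#' @param out_prefix Output path prefix; `NULL` disables file output.
#' @param write_networks Also write the built networks (matrix TSV).
#' @param seed Integer, logged in the provenance record (the pipeline
#'   itself is deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(expr_a = NULL, expr_b = NULL, net_a = NULL, net_b = NULL,
                       coexpression = coexpression_params(),
                       c_grid = default_c_grid(), k = 2, min_objective = 0,
                       direction = "both", gmt = NULL, reference_sets = NULL,
                       out_prefix = NULL, write_networks = FALSE, seed = 1L) {
  if (is.null(net_a) && is.null(expr_a)) stopf("condition A needs expr_a or net_a")
  if (is.null(net_b) && is.null(expr_b)) stopf("condition B needs expr_b or net_b")
  structure(
    list(expr_a = expr_a, expr_b = expr_b, net_a = net_a, net_b = net_b,
         coexpression = coexpression, c_grid = c_grid, k = k,
         min_objective = min_objective, direction = direction, gmt = gmt,
         reference_sets = reference_sets, out_prefix = out_prefix,
         write_networks = write_networks, seed = seed),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Plain `key: value` YAML mirroring the arguments of [run_config()];
#' coexpression parameters sit under a `coexpression:` block.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- do.call(coexpression_params, y$coexpression %||% list())
  run_config(
    expr_a = y$expr_a, expr_b = y$expr_b, net_a = y$net_a, net_b = y$net_b,
    coexpression = co,
    c_grid = as.numeric(y$c_grid %||% default_c_grid()),
    k = as.integer(y$k %||% 2L),
    min_objective = as.numeric(y$min_objective %||% 0),
    direction = y$direction %||% "both",
    gmt = y$gmt, reference_sets = y$reference_sets,
    out_prefix = y$out_prefix,
    write_networks = isTRUE(y$write_networks),
    seed = as.integer(y$seed %||% 1L)
  )
}

resolve_network <- function(net, expr, params, label) {
  if (!is.null(net)) {
    if (inherits(net, "weighted_network")) return(net)
    return(read_network(net))
  }
  x <- if (is.character(expr)) read_expression(expr) else as_expression_matrix(expr)
  message(sprintf("[%s] building coexpression network (%s) from %d genes x %d samples",
                  label, params$measure, nrow(x), ncol(x)))
  build_network(x, params)
}

#' Run the full comparison workflow
#'
#' The end-to-end pipeline: build (or load) the two networks, mine the
#' top-k contrast subgraphs in the requested direction(s), run the
#' degree-distribution test on each mined set, overlap-test the rank-1
#' sets against any supplied reference sets (universe = shared network
#' genes), and, if a gene-set collection is given, compute functional
#' enrichment of the rank-1 sets. With an `out_prefix`, results are
#' written as TSV/JSON alongside a provenance record (config echo, package
#' version, input checksums). A missing GMT simply skips the enrichment
#' stage with a notice. Deterministic: identical config and inputs give
#' identical results.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return List of class `pipeline_result`: `contrasts` (contrast_tbl),
#'   `degree_tests` (named list), `overlaps` (tibble or NULL),
#'   `enrichment` (named list of enrichment tibbles or NULL), `networks`
#'   (the two networks), `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  net_a <- resolve_network(config$net_a, config$expr_a, config$coexpression, "A")
  net_b <- resolve_network(config$net_b, config$expr_b, config$coexpression, "B")
  shared <- intersect(net_a$nodes, net_b$nodes)
  message(sprintf("[contrast] %d shared nodes; mining top-%d (direction %s)",
                  length(shared), config$k, config$direction))
  contrasts <- top_k_contrast(net_a, net_b, c_grid = config$c_grid, k = config$k,
                              direction = config$direction,
                              min_objective = config$min_objective,
                              keep_trace = TRUE)
  degree_tests <- list()
  for (i in seq_len(nrow(contrasts))) {
    key <- sprintf("%s_rank%d", contrasts$direction[i], contrasts$rank[i])
    degree_tests[[key]] <- degree_distribution_test(contrasts$nodes[[i]], net_a, net_b)
  }
  overlaps <- NULL
  if (!is.null(config$reference_sets) && nrow(contrasts) > 0) {
    r1 <- contrasts[contrasts$rank == 1, , drop = FALSE]
    overlaps <- purrr::map_dfr(seq_len(nrow(r1)), function(i) {
      purrr::map_dfr(names(config$reference_sets), function(nm) {
        ref <- intersect(config$reference_sets[[nm]], shared)
        dplyr::mutate(
          fisher_overlap(r1$nodes[[i]], ref, shared),
          direction = r1$direction[i], reference = nm, .before = 1
        )
      })
    })
  }
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    collection <- if (inherits(config$gmt, "gene_set_collection")) {
      gene_set_collection(config$gmt$sets, universe = shared)
    } else {
      read_gmt(config$gmt, universe = shared)
    }
    r1 <- contrasts[contrasts$rank == 1, , drop = FALSE]
    enrichment <- list()
    for (i in seq_len(nrow(r1))) {
      enrichment[[r1$direction[i]]] <- enrich(r1$nodes[[i]], collection)
    }
  } else {
    message("[enrich] no gene-set collection supplied; enrichment stage skipped")
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("contrastnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    direction = config$direction, k = config$k, c_grid = config$c_grid,
    coexpression = unclass(config$coexpression),
    input_checksums = input_checksums(config),
    shared_nodes = length(shared)
  )
  out <- structure(
    list(contrasts = contrasts, degree_tests = degree_tests, overlaps = overlaps,
         enrichment = enrichment, networks = list(net_a = net_a, net_b = net_b),
         provenance = provenance),
    class = "pipeline_result"
  )
  if (!is.null(config$out_prefix)) write_pipeline_outputs(out, config)
  out
}

input_checksums <- function(config) {
  paths <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                  list(expr_a = config$expr_a, expr_b = config$expr_b,
                       net_a = config$net_a, net_b = config$net_b,
                       gmt = if (is.character(config$gmt)) config$gmt else NULL))
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

write_pipeline_outputs <- function(res, config) {
  prefix <- config$out_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_contrast_results(res$contrasts, paste0(prefix, "_contrasts"))
  if (length(res$degree_tests) > 0) {
    dt <- purrr::map_dfr(names(res$degree_tests), function(nm) {
      x <- res$degree_tests[[nm]]
      tibble::tibble(contrast = nm, n_nodes = nrow(x$degrees),
                     u_statistic = x$u_statistic, p_value = x$p_value,
                     method = x$method)
    })
    readr::write_tsv(dt, paste0(prefix, "_degree_tests.tsv"), progress = FALSE)
  }
  if (!is.null(res$overlaps)) {
    readr::write_tsv(res$overlaps, paste0(prefix, "_overlaps.tsv"), progress = FALSE)
  }
  for (nm in names(res$enrichment %||% list())) {
    write_enrichment(res$enrichment[[nm]], sprintf("%s_enrichment_%s.tsv", prefix, nm))
  }
  if (isTRUE(config$write_networks)) {
    write_network(res$networks$net_a, paste0(prefix, "_net_a.tsv"), format = "matrix")
    write_network(res$networks$net_b, paste0(prefix, "_net_b.tsv"), format = "matrix")
  }
  jsonlite::write_json(res$provenance, paste0(prefix, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d contrast subgraph(s), %d shared nodes\n",
              nrow(x$contrasts), x$provenance$shared_nodes))
  print(tibble::as_tibble(x$contrasts))
  invisible(x)
}
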