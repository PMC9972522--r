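#' Read an expression table
#'
#' Reads a genes-by-samples TSV or CSV (gzip transparent): first column =
#' gene labels, remaining columns numeric sample values. Duplicated gene
#' labels are collapsed by keeping the row with the highest mean expression
#' (the usual most-expressed-probe rule), with a warning stating how many
#' rows were dropped. Non-numeric cells are an error naming the location.
#'
#' @param path File path (`.tsv`, `.csv`, optionally `.gz`).
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stopf("empty or malformed expression file: %s", path)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA" & vals != "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-numeric value '%s' at data row %d, column '%s'",
          vals[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(vals)[bad[1, 2]])
  }
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(num, na.rm = TRUE)
    ord <- order(-means) # best row of each duplicated label first
    num <- num[ord, , drop = FALSE]
    dup <- duplicated(rownames(num))
    warnf("collapsed %d duplicated gene label(s), keeping the row with highest mean",
          sum(dup))
    num <- num[!dup, , drop = FALSE]
    num <- num[order(match(rownames(num), genes)), , drop = FALSE]
  }
  num
}

#' Write an expression table
#'
#' TSV, genes as rows (first column `gene`), values with 6 significant
#' digits. Gzip if the path ends in `.gz`.
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- tibble::as_tibble(signif(x, 6), rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a network from disk
#'
#' Two on-disk forms are supported. An *edge list*: tab-separated columns
#' `node1 node2 weight` (header optional; the weight column optional, as in
#' unweighted PPI lists, implying weight 1), one row per unordered pair.
#' Duplicate rows for the same pair — including reciprocal rows — are
#' de-duplicated by keeping the maximum weight, with a warning giving the
#' count. Self-loop rows are dropped. A *matrix*: a labelled square table
#' (row and column labels = nodes); asymmetry beyond `1e-9` is an error.
#'
#' @param path File path (gzip transparent).
#' @param kind `"auto"` (default: matrix if the table is square with
#'   matching labels, else edge list), `"edge_list"` or `"matrix"`.
#' @param network_kind Passed to [weighted_network()] (`"generic"`,
#'   `"coexpression"`, `"ppi"`).
#' @return A [weighted_network()].
#' @export
read_network <- function(path, kind = c("auto", "edge_list", "matrix"),
                         network_kind = "generic") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (kind == "auto") {
    peek <- readr::read_tsv(path, n_max = 5, col_names = FALSE,
                            show_col_types = FALSE, progress = FALSE)
    kind <- if (ncol(peek) <= 3) "edge_list" else "matrix"
  }
  if (kind == "matrix") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m))) {
      stopf("matrix file is not a labelled square matrix: %s", path)
    }
    m <- m[, rownames(m), drop = FALSE]
    return(weighted_network(m, kind = network_kind))
  }
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^node1[\t ]", first) ||
    grepl("(^|\t)(source|from|node)", tolower(first))
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) stopf("edge list needs at least 2 columns: %s", path)
  edges <- tibble::tibble(
    node1 = as.character(df[[1]]),
    node2 = as.character(df[[2]]),
    weight = if (ncol(df) >= 3) as.numeric(df[[3]]) else 1
  )
  edges_to_network(edges, network_kind)
}

#' Build a network from an edge tibble
#'
#' @param edges Tibble/data frame with columns `node1`, `node2` and
#'   optionally `weight` (default 1).
#' @param network_kind Passed to [weighted_network()].
#' @return A [weighted_network()].
#' @export
edges_to_network <- function(edges, network_kind = "generic") {
  if (!all(c("node1", "node2") %in% names(edges))) {
    stopf("edge table must have columns node1, node2")
  }
  w <- edges$weight %||% rep(1, nrow(edges))
  if (anyNA(w)) stopf("edge weights must be numeric and non-missing")
  self <- edges$node1 == edges$node2
  if (any(self)) {
    warnf("dropped %d self-loop row(s)", sum(self))
    edges <- edges[!self, , drop = FALSE]
    w <- w[!self]
  }
  nodes <- lex_sort(unique(c(edges$node1, edges$node2)))
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  i <- match(edges$node1, nodes)
  j <- match(edges$node2, nodes)
  # unordered-pair key to detect duplicate / reciprocal rows
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    warnf("de-duplicated %d repeated/reciprocal edge row(s), keeping the maximum weight",
          sum(duplicated(key)))
    agg <- tapply(w, key, max)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2]); w <- as.numeric(agg)
  }
  m[cbind(i, j)] <- w
  m[cbind(j, i)] <- w
  weighted_network(m, kind = network_kind)
}

#' Write a network to disk
#'
#' @param net A [weighted_network()] or [signed_difference_graph()].
#' @param path Output path.
#' @param format `"edge_list"` (columns `node1 node2 weight`, non-zero
#'   pairs only) or `"matrix"` (labelled square TSV). Weights are written
#'   with 6 significant digits.
#' @export
write_network <- function(net, path, format = c("edge_list", "matrix")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    e <- as_edge_tibble(net)
    e$weight <- signif(e$weight, 6)
    readr::write_tsv(e, path, progress = FALSE)
  } else {
    df <- tibble::as_tibble(signif(net$weights, 6), rownames = "node")
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Returns a [gene_set_collection()]; supply the
#' `universe` the enrichment should condition on (e.g. the genes present in
#' both networks), otherwise the union of all sets is used.
#'
#' @param path GMT file path.
#' @param universe Optional character vector.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) stopf("malformed GMT line %d (need name, description, >= 1 gene)", bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  gene_set_collection(sets, universe = universe)
}

#' Write contrast subgraph results
#'
#' Writes the ranked results as a TSV (columns `rank`, `direction`,
#' `c_value`, `objective`, `size`, `nodes` comma-joined) and a JSON twin
#' carrying full precision plus, when present, the per-rank peel-trace
#' summaries.
#'
#' @param results A `contrast_tbl` from [top_k_contrast()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_contrast_results <- function(results, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  flat <- dplyr::mutate(
    tibble::as_tibble(results),
    objective = signif(.data$objective, 6),
    nodes = vapply(.data$nodes, paste, "", collapse = ",")
  )
  readr::write_tsv(flat, tsv, progress = FALSE)
  payload <- list(
    results = purrr::pmap(tibble::as_tibble(results), function(rank, direction, c_value,
                                                               objective, size, nodes, ...) {
      list(rank = rank, direction = direction, c_value = c_value,
           objective = objective, size = size, nodes = nodes)
    }),
    traces = lapply(attr(results, "traces"), function(tr) {
      list(size = tr$size, objective = tr$objective)
    })
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Write an enrichment table
#'
#' @param results An `enrichment_tbl` from [enrich()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(results, path) {
  flat <- dplyr::mutate(
    tibble::as_tibble(results),
    genes = vapply(.data$genes, paste, "", collapse = ",")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
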