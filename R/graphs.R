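#' Node-labelled symmetric weighted network
#'
#' The container shared by all network-facing functions: an ordered set of
#' unique node labels plus a symmetric weight matrix with a zero diagonal.
#' Coexpression networks carry weights in \eqn{[0, 1]} (they are complete
#' graphs after soft thresholding); protein-protein interaction (PPI)
#' networks carry weights in \{0, 1\}.
#'
#' Node labels are canonicalized by lexicographic sort (C collation) so that
#' all downstream tie-breaking is deterministic and independent of input row
#' order.
#'
#' @param weights Square numeric matrix with identical row/column names
#'   (the node labels). Must be symmetric with zero diagonal (tolerance
#'   `1e-9`); small asymmetries and diagonal entries within tolerance are
#'   cleaned up silently.
#' @param kind One of `"generic"`, `"coexpression"`, `"ppi"`. Coexpression
#'   weights must lie in `[0, 1]`; PPI weights must be 0/1.
#' @return An object of class `weighted_network`: a list with elements
#'   `nodes` (character) and `weights` (dense symmetric matrix).
#' @examples
#' w <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = list(c("b", "a"), c("b", "a")))
#' net <- weighted_network(w, kind = "coexpression")
#' net$nodes # canonical order: "a" "b"
#' @export
weighted_network <- function(weights, kind = c("generic", "coexpression", "ppi")) {
  kind <- match.arg(kind)
  weights <- validate_weight_matrix(weights, allow_negative = FALSE)
  if (kind == "coexpression" && any(weights > 1 + 1e-9)) {
    stopf("coexpression weights must lie in [0, 1]; max observed %.6g", max(weights))
  }
  if (kind == "ppi" && !all(abs(weights) < 1e-9 | abs(weights - 1) < 1e-9)) {
    stopf("PPI weights must be 0 or 1")
  }
  structure(
    list(nodes = rownames(weights), weights = weights, kind = kind),
    class = "weighted_network"
  )
}

#' Signed difference graph
#'
#' The mining substrate: a symmetric zero-diagonal graph whose edge weights
#' may be negative (typically \eqn{w_A(u,v) - w_B(u,v)}). Built directly or
#' via [difference_graph()].
#'
#' @param weights Square numeric matrix, symmetric, zero diagonal, any sign.
#' @return Object of class `signed_difference_graph`.
#' @export
signed_difference_graph <- function(weights) {
  weights <- validate_weight_matrix(weights, allow_negative = TRUE)
  structure(
    list(nodes = rownames(weights), weights = weights),
    class = "signed_difference_graph"
  )
}

validate_weight_matrix <- function(weights, allow_negative) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stopf("weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) stopf("weights must be square")
  labs <- rownames(weights)
  if (is.null(labs) || anyNA(labs)) stopf("weights must have node labels as rownames")
  if (anyDuplicated(labs)) stopf("duplicate node labels: %s",
                                 paste(unique(labs[duplicated(labs)]), collapse = ", "))
  cl <- colnames(weights)
  if (!identical(labs, cl)) stopf("row and column labels must be identical")
  if (anyNA(weights)) stopf("weights must not contain missing values")
  if (max(abs(weights - t(weights))) > 1e-9) {
    stopf("weight matrix is asymmetric beyond tolerance (max |w - t(w)| = %.3g)",
          max(abs(weights - t(weights))))
  }
  if (max(abs(diag(weights))) > 1e-9) {
    stopf("diagonal must be zero (self-loops are not supported)")
  }
  if (!allow_negative && min(weights) < -1e-9) {
    stopf("negative weights are not allowed in a weighted_network")
  }
  # canonicalize: symmetrize exactly, zero the diagonal, sort node labels
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  ord <- order(labs, method = "radix")
  weights[ord, ord, drop = FALSE]
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network [%s]> %d nodes, %d non-zero edges\n",
              x$kind, length(x$nodes), sum(x$weights[upper.tri(x$weights)] != 0)))
  invisible(x)
}

#' @export
print.signed_difference_graph <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<signed_difference_graph> %d nodes, %d positive / %d negative edges\n",
              length(x$nodes), sum(w > 0), sum(w < 0)))
  invisible(x)
}

#' Signed difference of two networks
#'
#' Restricts both networks to their shared node labels (exact string match,
#' lexicographically sorted) and returns the graph with edge weights
#' \eqn{w_A(u,v) - w_B(u,v)}. This is the substrate on which contrast
#' subgraphs are mined: node sets dense in `net_a` and sparse in `net_b`
#' induce large positive weight mass.
#'
#' @param net_a,net_b [weighted_network()] objects sharing at least 2 nodes.
#' @return A [signed_difference_graph()] on the shared nodes.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' a <- weighted_network(w)
#' b <- weighted_network(w * 0.25)
#' difference_graph(a, b)$weights["a", "b"] # 0.75
#' @export
difference_graph <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "weighted_network"), inherits(net_b, "weighted_network"))
  shared <- lex_sort(intersect(net_a$nodes, net_b$nodes))
  if (length(shared) < 2) {
    stopf("networks share %d node(s); at least 2 shared nodes are required to compare them",
          length(shared))
  }
  d <- net_a$weights[shared, shared, drop = FALSE] -
    net_b$weights[shared, shared, drop = FALSE]
  signed_difference_graph(d)
}

#' Sum of induced edge weights
#'
#' \eqn{e(S)}: the sum of edge weights over unordered node pairs within `s`.
#'
#' @param g A [signed_difference_graph()] or [weighted_network()].
#' @param s Character vector of node labels, a subset of `g`'s nodes.
#' @return A single number.
#' @export
induced_edge_sum <- function(g, s) {
  s <- unique(as.character(s))
  missing <- setdiff(s, g$nodes)
  if (length(missing) > 0) {
    stopf("node(s) not in graph: %s", paste(missing, collapse = ", "))
  }
  if (length(s) < 2) return(0)
  sum(g$weights[s, s]) / 2
}

#' Positive and negative node degrees
#'
#' For each node \eqn{v}, the positive degree \eqn{deg^+(v)} (sum of incident
#' positive weights) and negative degree \eqn{deg^-(v) \le 0} (sum of
#' incident negative weights). Their sum is the signed weighted degree. The
#' quantity \eqn{\Delta = \max_v |deg^-(v)|} enters the quality bound of the
#' peeling heuristic (see [peeling_bound()]) and is attached as attribute
#' `delta` and returned by [max_negative_degree()].
#'
#' @param g A [signed_difference_graph()].
#' @return A tibble with columns `node`, `deg_plus`, `deg_minus`, `degree`;
#'   attribute `delta`.
#' @export
signed_degrees <- function(g) {
  w <- g$weights
  dp <- colSums(pmax(w, 0))
  dn <- colSums(pmin(w, 0))
  out <- tibble::tibble(
    node = g$nodes,
    deg_plus = unname(dp),
    deg_minus = unname(dn),
    degree = unname(dp + dn)
  )
  attr(out, "delta") <- max(abs(dn))
  out
}

#' @rdname signed_degrees
#' @export
max_negative_degree <- function(g) {
  max(abs(colSums(pmin(g$weights, 0))))
}

#' Edge-list view of a network
#'
#' @param g A [weighted_network()] or [signed_difference_graph()].
#' @param drop_zero Drop zero-weight pairs (default `TRUE`).
#' @return Tibble with columns `node1`, `node2`, `weight`, one row per
#'   unordered pair with `node1 < node2`.
#' @export
as_edge_tibble <- function(g, drop_zero = TRUE) {
  w <- g$weights
  ut <- upper.tri(w)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble::tibble(
    node1 = g$nodes[idx[, 1]],
    node2 = g$nodes[idx[, 2]],
    weight = w[ut]
  )
  if (drop_zero) out <- out[out$weight != 0, ]
  out
}
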