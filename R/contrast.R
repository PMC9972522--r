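#' Density objective on a signed graph
#'
#' \eqn{f(S) = e(S)/|S|}: the average (signed) induced degree of the node
#' set, i.e. the classic densest-subgraph objective evaluated on a graph
#' whose weights may be negative. Maximizing it over node sets is what
#' contrast-subgraph mining does.
#'
#' @param g A [signed_difference_graph()].
#' @param s Non-empty character vector of node labels.
#' @return A single number.
#' @export
density_objective <- function(g, s) {
  s <- unique(as.character(s))
  if (length(s) == 0) stopf("density objective is undefined for an empty node set")
  induced_edge_sum(g, s) / length(s)
}

#' Size-regularized contrast objective
#'
#' Evaluates \eqn{e_A(S) - e_B(S) - \alpha \binom{|S|}{2}} on the shared
#' nodes of two networks. The regularization term penalizes every within-set
#' pair by \eqn{\alpha}, so edges lighter than \eqn{\alpha} contribute
#' negatively and larger solutions are discouraged. This objective is
#' provided for scoring and reporting candidate sets only; the miner itself
#' optimizes the density objective via greedy peeling.
#'
#' @param net_a,net_b [weighted_network()] objects.
#' @param s Node set, subset of the shared nodes.
#' @param alpha Non-negative regularization scalar.
#' @return A single number.
#' @export
alpha_objective <- function(net_a, net_b, s, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    stopf("alpha must be a single non-negative number")
  }
  s <- unique(as.character(s))
  shared <- intersect(net_a$nodes, net_b$nodes)
  missing <- setdiff(s, shared)
  if (length(missing) > 0) {
    stopf("node(s) not shared by both networks: %s", paste(missing, collapse = ", "))
  }
  ea <- induced_edge_sum(net_a, s)
  eb <- induced_edge_sum(net_b, s)
  ea - eb - alpha * choose(length(s), 2)
}

#' Greedy peeling for the densest subgraph with negative weights
#'
#' Iteratively removes the node minimizing the score
#' \eqn{C \cdot deg^+(v) + deg^-(v)}, storing each intermediate node set
#' \eqn{H_i} as a candidate solution, and returns the candidate maximizing
#' the density objective \eqn{e(S)/|S|}. The scalar \eqn{C \in (0, \infty)}
#' rescales the influence of positive degrees and is meant to be swept over
#' a grid (see [sweep_c()]): different C values avoid different bad
#' instances of plain peeling. The returned objective is always
#' \eqn{\ge 0} because singletons (no within-set edges) are among the
#' candidates.
#'
#' Degrees are updated incrementally after each removal, so one run costs
#' \eqn{O(n^2)} on a dense graph; a complete graph on a few thousand nodes
#' peels in seconds.
#'
#' Ties in the removal score are broken by removing the lexicographically
#' smallest label; ties among equally dense candidates by the smaller set.
#' Both rules make the algorithm deterministic (node order is already
#' canonical in the graph container).
#'
#' @param g A [signed_difference_graph()] with at least one node.
#' @param c_value Positive scalar C.
#' @return Object of class `greedy_peel`: list with `node_set` (character),
#'   `objective` (recomputed exactly on `node_set`), `c_value`, `trace`
#'   (tibble `iteration`, `size`, `objective` for every candidate
#'   \eqn{H_i}), `argmax_iteration`, and `removal_order`.
#' @seealso [sweep_c()], [top_k_contrast()], [brute_force_densest()],
#'   [peeling_bound()]
#' @export
greedy_peel <- function(g, c_value = 1) {
  stopifnot(inherits(g, "signed_difference_graph"))
  if (!is.numeric(c_value) || length(c_value) != 1 || is.na(c_value) || c_value <= 0) {
    stopf("c_value must be a single positive number")
  }
  w <- g$weights
  n <- nrow(w)
  if (n == 0) stopf("graph has no nodes")
  wp <- pmax(w, 0)
  wn <- w - wp
  degp <- colSums(wp)
  degn <- colSums(wn)
  alive <- rep(TRUE, n)
  esum <- sum(degp + degn) / 2
  obj <- numeric(n) # obj[i]: objective of the candidate of size n - i + 1
  obj[1] <- esum / n
  removed <- integer(max(n - 1, 0))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      score <- c_value * degp + degn
      score[!alive] <- Inf
      v <- which.min(score) # first minimum = lexicographically smallest label
      alive[v] <- FALSE
      esum <- esum - (degp[v] + degn[v])
      degp <- degp - wp[, v]
      degn <- degn - wn[, v]
      removed[i] <- v
      obj[i + 1] <- esum / (n - i)
    }
  }
  # best candidate; on (near-)ties prefer the latest iteration = smallest set
  best <- max(obj)
  argmax <- max(which(obj >= best - 1e-12))
  node_set <- if (argmax == 1) g$nodes else g$nodes[-removed[seq_len(argmax - 1)]]
  structure(
    list(
      node_set = node_set,
      objective = density_objective(g, node_set),
      c_value = c_value,
      trace = tibble::tibble(
        iteration = seq_len(n),
        size = n - seq_len(n) + 1L,
        objective = obj
      ),
      argmax_iteration = argmax,
      removal_order = g$nodes[removed]
    ),
    class = "greedy_peel"
  )
}

#' @export
print.greedy_peel <- function(x, ...) {
  cat(sprintf("<greedy_peel> C = %g, |S| = %d, f(S) = %.6g\n",
              x$c_value, length(x$node_set), x$objective))
  invisible(x)
}

#' Sweep the peeling parameter C
#'
#' Runs [greedy_peel()] for every value in `c_grid` and returns the result
#' with the largest objective. Ties are broken by the smaller C, then by the
#' lexicographically smaller node set. The default grid is log-spaced
#' around 1, covering regimes where positive degrees are down- or
#' up-weighted relative to negative ones.
#'
#' @param g A [signed_difference_graph()].
#' @param c_grid Strictly positive numeric vector.
#' @return The best `greedy_peel` object across the grid.
#' @export
sweep_c <- function(g, c_grid = default_c_grid()) {
  if (length(c_grid) == 0 || any(!is.finite(c_grid)) || any(c_grid <= 0)) {
    stopf("c_grid must be a non-empty vector of positive numbers")
  }
  c_grid <- sort(unique(c_grid))
  best <- NULL
  for (cv in c_grid) {
    res <- greedy_peel(g, cv)
    if (is.null(best) ||
        res$objective > best$objective + 1e-12 ||
        (abs(res$objective - best$objective) <= 1e-12 &&
         lex_less(res$node_set, best$node_set))) {
      best <- res
    }
  }
  best
}

#' @rdname sweep_c
#' @export
default_c_grid <- function() c(0.25, 0.5, 1, 2, 4)

#' Top-k contrast subgraphs between two networks
#'
#' Builds the signed difference graph in the requested direction(s) and
#' repeatedly extracts the best contrast subgraph: at each rank a C-sweep of
#' greedy peeling is run, the winning node set is recorded, and all edges
#' within that set are zeroed in the current difference graph before the
#' next rank (nodes stay in the universe, so later subgraphs may reuse
#' nodes but never reuse a within-set edge). Extraction stops early when the
#' best objective drops to `min_objective` or below — a set whose density
#' does not beat the trivial singleton value of 0 carries no contrast
#' signal. The two directions are mined independently, on the difference
#' graph and its negation.
#'
#' @param net_a,net_b [weighted_network()] objects over (partly) shared nodes.
#' @param c_grid Positive grid for the C-sweep.
#' @param k Maximum number of subgraphs per direction.
#' @param direction `"both"` (default), `"ab"` (dense in A, sparse in B) or
#'   `"ba"`.
#' @param min_objective Stop once the best density falls to this value or
#'   below (default 0).
#' @param keep_trace Attach the full peel trace of each rank as attribute
#'   `traces` (a list of tibbles).
#' @return A tibble of class `contrast_tbl` with columns `rank`,
#'   `direction` (`"A_over_B"` / `"B_over_A"`), `c_value`, `objective`,
#'   `size` and the list-column `nodes`.
#' @examples
#' sim <- planted_contrast_pair(n_nodes = 40, module = 8,
#'                              p_in_a = 0.9, p_in_b = 0.05,
#'                              p_background = 0.05, seed = 1)
#' top_k_contrast(sim$net_a, sim$net_b, k = 1, direction = "ab")
#' @export
top_k_contrast <- function(net_a, net_b, c_grid = default_c_grid(), k = 2,
                           direction = c("both", "ab", "ba"),
                           min_objective = 0, keep_trace = FALSE) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  d <- difference_graph(net_a, net_b)
  dirs <- switch(direction, both = c("A_over_B", "B_over_A"),
                 ab = "A_over_B", ba = "B_over_A")
  rows <- list()
  traces <- list()
  for (dr in dirs) {
    cur <- if (dr == "A_over_B") d else signed_difference_graph(-d$weights)
    for (r in seq_len(k)) {
      best <- sweep_c(cur, c_grid)
      if (best$objective <= min_objective) break
      rows[[length(rows) + 1]] <- tibble::tibble(
        rank = r, direction = dr, c_value = best$c_value,
        objective = best$objective, size = length(best$node_set),
        nodes = list(best$node_set)
      )
      if (keep_trace) traces[[paste(dr, r, sep = "_")]] <- best$trace
      # zero the within-set edge support before the next rank
      w <- cur$weights
      w[best$node_set, best$node_set] <- 0
      cur <- signed_difference_graph(w)
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(rank = integer(), direction = character(),
                   c_value = numeric(), objective = numeric(),
                   size = integer(), nodes = list())
  }
  if (keep_trace) attr(out, "traces") <- traces
  class(out) <- c("contrast_tbl", class(out))
  out
}

#' Exact densest subgraph by enumeration (test oracle)
#'
#' Enumerates every non-empty node subset and returns the exact maximizer of
#' the density objective. Intended as a correctness oracle at test scale
#' only; guarded at 20 nodes. Ties are broken by smaller set size, then by
#' lexicographically smaller label sequence.
#'
#' @param g A [signed_difference_graph()] with at most 20 nodes.
#' @return List with `node_set` and `objective` (\eqn{\rho^*}).
#' @export
brute_force_densest <- function(g) {
  n <- length(g$nodes)
  if (n > 20) {
    stopf("brute_force_densest enumerates 2^n subsets and is a test-scale oracle; got n = %d (max 20)", n)
  }
  if (n == 0) stopf("graph has no nodes")
  w <- g$weights
  masks <- seq_len(2^n - 1)
  memb <- vapply(seq_len(n) - 1L,
                 function(b) bitwAnd(masks, bitwShiftL(1L, b)) > 0L,
                 logical(length(masks)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  storage.mode(memb) <- "double"
  sizes <- rowSums(memb)
  esum <- rowSums((memb %*% w) * memb) / 2
  f <- esum / sizes
  best <- max(f)
  cand <- which(f >= best - 1e-12)
  cand <- cand[sizes[cand] == min(sizes[cand])]
  if (length(cand) > 1) {
    keys <- vapply(cand, function(m) paste(g$nodes[memb[m, ] > 0], collapse = "\x01"), "")
    cand <- cand[order(keys, method = "radix")[1]]
  }
  node_set <- g$nodes[memb[cand[1], ] > 0]
  list(node_set = node_set, objective = density_objective(g, node_set))
}

#' Quality bound of greedy peeling
#'
#' The peeling heuristic on a signed graph is guaranteed to return a set of
#' density at least \eqn{\rho^*/2 - \Delta/2}, where \eqn{\rho^*} is the
#' exact optimum and \eqn{\Delta = \max_v |deg^-(v)|}. On an all-positive
#' graph \eqn{\Delta = 0} and the classic 1/2-approximation is recovered.
#'
#' @param g A [signed_difference_graph()].
#' @param rho_star The exact optimal density (e.g. from
#'   [brute_force_densest()] on a small graph).
#' @return The bound \eqn{\rho^*/2 - \Delta/2}.
#' @export
peeling_bound <- function(g, rho_star) {
  rho_star / 2 - max_negative_degree(g) / 2
}
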