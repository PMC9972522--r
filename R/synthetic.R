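#' Planted differential-module network pair
#'
#' Generates two random networks on the same nodes that differ only inside
#' a planted module: within-module pairs get an edge with probability
#' `p_in_a` in network A and `p_in_b` in network B, every other pair with
#' probability `p_background` in both (drawn independently per network).
#' With `p_in_a >> p_in_b` the module is the ground-truth contrast
#' subgraph; with all three probabilities equal the difference graph is
#' pure noise and no contrast should survive. In weighted mode present
#' edges carry Beta-distributed weights with a module-dependent mean
#' (Beta(5, 2), mean 5/7, inside the module of the dense network;
#' Beta(2, 5), mean 2/7, elsewhere), so the signed-weight code paths are
#' exercised beyond 0/1 weights.
#'
#' All randomness comes from R's Mersenne-Twister generator seeded with
#' `seed`; the caller's RNG state is left untouched, and identical seeds
#' give identical networks.
#'
#' @param n_nodes Number of nodes (labels `n0001`, `n0002`, ...).
#' @param module Either a module size (sampled uniformly from the nodes) or
#'   a character vector of node labels.
#' @param p_in_a,p_in_b,p_background Edge probabilities in `[0, 1]`.
#' @param weighted Draw Beta edge weights instead of unit weights.
#' @param seed Integer seed (mandatory).
#' @return List with `net_a`, `net_b` ([weighted_network()]s) and `module`
#'   (sorted character vector).
#' @export
planted_contrast_pair <- function(n_nodes, module, p_in_a, p_in_b,
                                  p_background, weighted = FALSE, seed) {
  if (missing(seed) || is.null(seed)) stopf("a seed is mandatory for reproducibility")
  stopifnot(n_nodes >= 2)
  for (p in c(p_in_a, p_in_b, p_background)) {
    if (!is.numeric(p) || p < 0 || p > 1) stopf("edge probabilities must lie in [0, 1]")
  }
  nodes <- sprintf("n%04d", seq_len(n_nodes))
  with_seed(seed, {
    if (is.numeric(module) && length(module) == 1) {
      if (module > n_nodes) stopf("module size %d exceeds the number of nodes %d", module, n_nodes)
      module <- sample(nodes, module)
    } else {
      module <- as.character(module)
      if (!all(module %in% nodes)) stopf("module labels must be among the generated nodes")
    }
    module <- lex_sort(unique(module))
    in_mod <- nodes %in% module
    pair_in_module <- outer(in_mod, in_mod, `&`)
    draw <- function(p_in) {
      prob <- ifelse(pair_in_module, p_in, p_background)
      ut <- upper.tri(prob)
      w <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
      present <- stats::runif(sum(ut)) < prob[ut]
      if (weighted) {
        dense_mod <- pair_in_module[ut] & p_in >= p_background
        wt <- ifelse(dense_mod, stats::rbeta(sum(ut), 5, 2), stats::rbeta(sum(ut), 2, 5))
        w[ut] <- ifelse(present, wt, 0)
      } else {
        w[ut] <- as.numeric(present)
      }
      w <- w + t(w)
      weighted_network(w, kind = if (weighted) "generic" else "ppi")
    }
    net_a <- draw(p_in_a)
    net_b <- draw(p_in_b)
    list(net_a = net_a, net_b = net_b, module = module)
  })
}

#' Planted two-condition expression matrices
#'
#' Generates genes-by-samples abundance matrices for two conditions, with
#' condition-specific co-regulated gene blocks: for each module active in a
#' condition, a standard-normal latent factor per sample drives every
#' module gene with the given loading, plus independent Gaussian noise
#' (`noise_sd`) on all genes. Each gene carries a baseline log2 level drawn
#' from N(`base_log_mean`, `base_log_sd`), and values are exponentiated
#' (base 2), giving positively skewed, strictly positive, FPKM/TPM-like
#' abundances that exercise the filter-and-log preprocessing path. This
#' emulates the statistical structure the coexpression comparison assumes —
#' condition-specific correlated blocks on a noisy background — and nothing
#' more: no library-size variation, no count dispersion, no compositional
#' closure.
#'
#' @param n_genes Number of genes (labels `g0001`, ...).
#' @param n_samples_a,n_samples_b Samples per condition.
#' @param modules List of module specifications, each a list with `genes`
#'   (size to sample, or character labels), `loading` in (0, 1], and
#'   `active_in` one of `"A"`, `"B"`, `"both"`.
#' @param noise_sd Positive noise standard deviation on the log2 scale.
#' @param base_log_mean,base_log_sd Baseline gene level distribution
#'   (log2 scale); the defaults (5, 1) keep essentially all values above
#'   the default low-expression filter.
#' @param seed Integer seed (mandatory).
#' @return List with `expr_a`, `expr_b` (matrices) and `modules` (named
#'   list of sorted gene vectors, named `M1`, `M2`, ... with the activity
#'   recorded in attribute `active_in`).
#' @export
planted_expression_pair <- function(n_genes, n_samples_a, n_samples_b, modules,
                                    noise_sd, base_log_mean = 5, base_log_sd = 1,
                                    seed) {
  if (missing(seed) || is.null(seed)) stopf("a seed is mandatory for reproducibility")
  stopifnot(n_genes >= 2, n_samples_a >= 1, n_samples_b >= 1, noise_sd > 0)
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    mods <- lapply(modules, function(m) {
      gs <- m$genes
      if (is.numeric(gs) && length(gs) == 1) {
        if (gs > n_genes) stopf("module size %d exceeds the number of genes", gs)
        gs <- sample(genes, gs)
      } else {
        gs <- as.character(gs)
        if (!all(gs %in% genes)) stopf("module gene labels must be among the generated genes")
      }
      if (!is.numeric(m$loading) || m$loading <= 0 || m$loading > 1) {
        stopf("module loading must lie in (0, 1]")
      }
      active <- match.arg(m$active_in, c("A", "B", "both"))
      list(genes = lex_sort(unique(gs)), loading = m$loading, active_in = active)
    })
    baseline <- stats::rnorm(n_genes, base_log_mean, base_log_sd)
    gen_condition <- function(n_samples, cond) {
      lg <- baseline + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                              n_genes, n_samples)
      for (m in mods) {
        if (m$active_in %in% c(cond, "both")) {
          z <- stats::rnorm(n_samples)
          idx <- match(m$genes, genes)
          lg[idx, ] <- lg[idx, ] + m$loading * matrix(z, length(idx), n_samples, byrow = TRUE)
        }
      }
      dimnames(lg) <- list(genes, sprintf("%s%04d", tolower(cond), seq_len(n_samples)))
      2^lg
    }
    expr_a <- gen_condition(n_samples_a, "A")
    expr_b <- gen_condition(n_samples_b, "B")
    out_mods <- lapply(mods, function(m) {
      structure(m$genes, active_in = m$active_in)
    })
    names(out_mods) <- paste0("M", seq_along(out_mods))
    list(expr_a = expr_a, expr_b = expr_b, modules = out_mods)
  })
}

#' Recovery score of a mined contrast subgraph
#'
#' Jaccard index between a mined node set and the planted ground truth.
#'
#' @param found A character vector of node labels, a `greedy_peel` result,
#'   or a `contrast_tbl` (its first row's node set is used).
#' @param planted Character vector, the planted module.
#' @return Jaccard index in `[0, 1]`.
#' @export
recovery_score <- function(found, planted) {
  s <- if (inherits(found, "greedy_peel")) {
    found$node_set
  } else if (inherits(found, "contrast_tbl") || (is.data.frame(found) && "nodes" %in% names(found))) {
    if (nrow(found) == 0) return(0)
    found$nodes[[1]]
  } else {
    as.character(found)
  }
  if (length(s) == 0 && length(planted) == 0) return(1)
  if (length(s) == 0 || length(planted) == 0) return(0)
  jaccard_index(s, planted)
}
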