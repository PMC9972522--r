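#' Gene set collection
#'
#' Named gene sets together with a declared gene universe, the container
#' used for enrichment and overlap testing. Every downstream computation
#' first intersects the sets with the universe, so the universe — typically
#' the genes present in both networks under comparison — defines the
#' sampling frame of the hypergeometric model.
#'
#' @param sets Named list of character vectors (set name -> gene labels).
#' @param universe Character vector of gene labels. Defaults to the union
#'   of all sets.
#' @return Object of class `gene_set_collection` with elements `sets`
#'   (intersected with the universe, duplicates removed) and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0) stopf("collection must contain at least one gene set")
  if (is.null(names(sets)) || any(names(sets) == "") || anyNA(names(sets))) {
    stopf("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) {
    stopf("duplicate set names: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  universe <- unique(as.character(universe %||% unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) stopf("universe must be non-empty")
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Jaccard index of two sets
#'
#' \eqn{|s_1 \cap s_2| / |s_1 \cup s_2|}; the standard measure used to
#' compare contrast subgraphs obtained from different datasets or network
#' construction methods.
#'
#' @param s1,s2 Character vectors (treated as sets); not both empty.
#' @return A number in \eqn{[0, 1]}.
#' @export
jaccard_index <- function(s1, s2) {
  s1 <- unique(as.character(s1))
  s2 <- unique(as.character(s2))
  u <- union(s1, s2)
  if (length(u) == 0) stopf("jaccard index is undefined for two empty sets")
  length(intersect(s1, s2)) / length(u)
}

#' Fisher overlap test of two gene sets
#'
#' Tests whether two sets drawn from a common universe overlap more than
#' expected by chance (Fisher's exact test on the 2x2 membership table).
#' The default alternative is one-sided enrichment, matching the
#' "observed vs. expected by chance" framing; `alternative = "two.sided"`
#' is available. The expected overlap under independence is
#' \eqn{|s_1| |s_2| / N}.
#'
#' @param s1,s2 Character vectors, subsets of `universe`.
#' @param universe Character vector, the non-empty sampling frame.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return One-row tibble: `overlap`, `expected_overlap`, `odds_ratio`
#'   (conditional MLE), `p_value`, `size1`, `size2`, `universe_size`.
#' @export
fisher_overlap <- function(s1, s2, universe, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("universe must be non-empty")
  s1 <- unique(as.character(s1))
  s2 <- unique(as.character(s2))
  out1 <- setdiff(s1, universe)
  out2 <- setdiff(s2, universe)
  if (length(out1) > 0 || length(out2) > 0) {
    stopf("sets must be subsets of the universe; outside it: %s",
          paste(utils::head(c(out1, out2), 5), collapse = ", "))
  }
  k <- length(intersect(s1, s2))
  n1 <- length(s1); n2 <- length(s2); nn <- length(universe)
  tab <- matrix(c(k, n1 - k, n2 - k, nn - n1 - n2 + k), 2, 2)
  ft <- stats::fisher.test(tab, alternative = alternative)
  tibble::tibble(
    overlap = k,
    expected_overlap = n1 * n2 / nn,
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    size1 = n1, size2 = n2, universe_size = nn
  )
}

#' Exact / approximate Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test. For small samples the
#' p-value is exact: the permutation distribution of the rank sum is
#' computed by dynamic programming over subsets (equivalent to full
#' enumeration of all \eqn{\binom{n+m}{n}} group assignments), which —
#' unlike the classical no-ties tables — remains exact in the presence of
#' tied values. Larger samples use the normal approximation with tie
#' correction and continuity correction. The permutation distribution of U
#' is symmetric about \eqn{nm/2}, so the two-sided exact p-value is
#' \eqn{P(|U - nm/2| \ge |u_{obs} - nm/2|)}.
#'
#' @param x,y Numeric vectors.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   (`NULL`) uses exact when \eqn{n + m \le 40}.
#' @return One-row tibble: `u_statistic` (for `x` vs `y`), `p_value`,
#'   `method` (`"exact"` / `"normal"`).
#' @export
mann_whitney_test <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stopf("both samples must be non-empty")
  nn <- n + m
  r <- rank(c(x, y)) # average ranks under ties
  w_obs <- sum(r[seq_len(n)])
  u_obs <- w_obs - n * (n + 1) / 2
  if (is.null(exact)) exact <- nn <= 40
  if (exact) {
    p <- mw_exact_p(r, n)
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u_obs - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble::tibble(u_statistic = u_obs, p_value = p, method = method)
}

# exact two-sided p for the rank-sum via subset-count DP.
# r: average ranks of the pooled sample; n: size of group 1.
mw_exact_p <- function(r, n) {
  nn <- length(r)
  r2 <- as.integer(round(2 * r)) # doubled ranks are integers even with ties
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  # dp[k + 1, s + 1]: number of size-k subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (item in r2) {
    for (k in seq(n, 1)) { # descending so each item is used at most once
      shifted <- c(rep(0, item), dp[k, seq_len(smax + 1 - item)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[n + 1, ]
  total <- sum(counts) # choose(nn, n), exact in doubles for nn <= 40
  sums <- seq(0, smax)
  center <- n * sum(r2) / nn # E[doubled rank sum]
  obs <- sum(r2[seq_len(n)])
  dev <- abs(sums - center)
  sum(counts[dev >= abs(obs - center) - 1e-9]) / total
}

#' Degree-distribution contrast of a node set in two networks
#'
#' For a mined contrast subgraph `s`, computes each node's weighted degree
#' in the two networks and compares the two degree distributions with a
#' two-sided Mann-Whitney U test. A strong contrast subgraph shows a clear
#' shift: its nodes are well connected in one network and weakly in the
#' other. By default degrees are taken within the subgraph induced by `s`
#' (the quantity the contrast objective actually optimizes);
#' `within = FALSE` uses each node's degree in the full network instead.
#'
#' @param s Character vector of at least 2 node labels shared by both
#'   networks.
#' @param net_a,net_b [weighted_network()] objects.
#' @param within Induced-subgraph degrees (default) or full-network degrees.
#' @return Object of class `degree_test`: list with `degrees` (tibble
#'   `node`, `degree_a`, `degree_b`), `u_statistic`, `p_value`, `method`.
#' @export
degree_distribution_test <- function(s, net_a, net_b, within = TRUE) {
  s <- lex_sort(unique(as.character(s)))
  if (length(s) < 2) stopf("at least 2 nodes are required for a degree comparison")
  shared <- intersect(net_a$nodes, net_b$nodes)
  missing <- setdiff(s, shared)
  if (length(missing) > 0) {
    stopf("node(s) not shared by both networks: %s", paste(missing, collapse = ", "))
  }
  deg_in <- function(net) {
    if (within) {
      colSums(net$weights[s, s, drop = FALSE])
    } else {
      colSums(net$weights[, s, drop = FALSE])
    }
  }
  da <- deg_in(net_a)
  db <- deg_in(net_b)
  mw <- mann_whitney_test(da, db)
  structure(
    list(
      degrees = tibble::tibble(node = s, degree_a = unname(da), degree_b = unname(db)),
      u_statistic = mw$u_statistic, p_value = mw$p_value, method = mw$method
    ),
    class = "degree_test"
  )
}

#' @export
print.degree_test <- function(x, ...) {
  cat(sprintf("<degree_test> %d nodes, U = %g, p = %.4g (%s)\n",
              nrow(x$degrees), x$u_statistic, x$p_value, x$method))
  invisible(x)
}

#' Over-representation analysis against a gene set collection
#'
#' Hypergeometric (one-sided, upper tail) over-representation of a query
#' gene list in each set of the collection, with Benjamini-Hochberg
#' adjustment across all tested sets. Query and sets are intersected with
#' the collection's universe first. Sets with zero overlap are reported
#' with p = 1. `gene_ratio` is the fraction of the (universe-restricted)
#' query found in the set.
#'
#' @param query Character vector of gene labels.
#' @param collection A [gene_set_collection()].
#' @param fdr_threshold Adjusted-p cutoff flagged in the `significant`
#'   column (default 0.05).
#' @return Tibble of class `enrichment_tbl`, one row per set, sorted by
#'   adjusted p then p: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `gene_ratio`, `p_value`, `p_adjust`, `significant`,
#'   `genes` (list-column of overlapping genes).
#' @export
enrich <- function(query, collection, fdr_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- intersect(unique(as.character(query)), collection$universe)
  if (length(query) == 0) {
    stopf("query is empty after intersection with the universe")
  }
  nq <- length(query)
  nu <- length(collection$universe)
  rows <- purrr::imap(collection$sets, function(genes, nm) {
    hit <- intersect(query, genes)
    k <- length(hit)
    kk <- length(genes)
    p <- if (k == 0) 1 else stats::phyper(k - 1, kk, nu - kk, nq, lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = kk, query_size = nq,
                   universe_size = nu, gene_ratio = k / nq, p_value = p,
                   genes = list(lex_sort(hit)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjust < fdr_threshold
  out <- dplyr::arrange(out, .data$p_adjust, .data$p_value, .data$set)
  out <- dplyr::relocate(out, "p_adjust", "significant", .after = "p_value")
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Upregulated genes between two expression profiles
#'
#' Calls a gene upregulated in profile A when
#' \eqn{\log_2(a + c) - \log_2(b + c) > t} with pseudo-count \eqn{c} and
#' threshold \eqn{t} (strict inequality: a fold change of exactly
#' \eqn{2^t} is not called). Defaults implement the common
#' \eqn{|\log_2 FC| > 1} rule on TPM values with unit pseudo-count, the
#' appropriate call when no replicates are available. Swapping the
#' arguments yields the down-regulated mirror set.
#'
#' @param tpm_a,tpm_b Named numeric vectors, or single-column matrices /
#'   two-column data frames (gene, value), over the same gene set.
#' @param pseudocount Positive pseudo-count (default 1).
#' @param lfc_threshold Strict log2 fold-change threshold (default 1).
#' @return Character vector of genes upregulated in A, in canonical order.
#' @export
upregulated_genes <- function(tpm_a, tpm_b, pseudocount = 1, lfc_threshold = 1) {
  a <- as_profile(tpm_a)
  b <- as_profile(tpm_b)
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) > 0 || length(only_b) > 0) {
    stopf("gene labels differ between profiles (only in A: %s; only in B: %s)",
          paste(utils::head(only_a, 5), collapse = ",") %|e|% "none",
          paste(utils::head(only_b, 5), collapse = ",") %|e|% "none")
  }
  b <- b[names(a)]
  lfc <- log2(a + pseudocount) - log2(b + pseudocount)
  lex_sort(names(a)[lfc > lfc_threshold])
}

`%|e|%` <- function(x, y) if (identical(x, "")) y else x

as_profile <- function(x) {
  if (is.data.frame(x) && ncol(x) == 2) {
    out <- x[[2]]
    names(out) <- as.character(x[[1]])
    return(out)
  }
  if (is.matrix(x) && ncol(x) == 1) {
    out <- x[, 1]
    names(out) <- rownames(x)
    return(out)
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopf("expected a named numeric vector, single-column matrix, or (gene, value) data frame")
}

#' Cohen's d
#'
#' Standardized mean difference \eqn{(\bar x - \bar y) / s_p} with pooled,
#' Bessel-corrected standard deviation. A zero pooled SD with unequal
#' means yields a signed infinite d with a warning.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A single number.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("both groups need at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  md <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (md == 0) return(0)
    warnf("pooled standard deviation is zero; Cohen's d is infinite")
    return(sign(md) * Inf)
  }
  md / sqrt(sp2)
}

#' mRNA-protein agreement of gene groups
#'
#' For every gene present in both matrices, computes the Pearson
#' correlation between its mRNA and protein profile across the shared
#' samples; then contrasts the correlation distributions of the given gene
#' groups pairwise with Cohen's d (pooled SD). Genes whose profile has zero
#' variance in either assay have no defined correlation and are excluded
#' with a warning. Used to ask whether, e.g., a contrast subgraph more
#' connected at the protein level consists of genes whose transcript is a
#' poor proxy for the protein.
#'
#' @param mrna,protein Expression matrices sharing genes and at least 3
#'   samples.
#' @param groups Named list of gene sets (subsets of the shared genes).
#'   Genes in none of the groups form the implicit `"background"` group
#'   when `add_background = TRUE`.
#' @param add_background Add the complement group (default `TRUE`).
#' @return List of class `agreement`: `correlations` (tibble `gene`, `r`,
#'   `group`) and `cohens_d` (tibble `group1`, `group2`, `d`, `n1`, `n2`).
#' @export
expression_protein_agreement <- function(mrna, protein, groups,
                                         add_background = TRUE) {
  mrna <- as_expression_matrix(mrna)
  protein <- as_expression_matrix(protein)
  genes <- intersect(rownames(mrna), rownames(protein))
  samples <- intersect(colnames(mrna), colnames(protein))
  if (length(samples) < 3) stopf("fewer than 3 shared samples")
  if (length(genes) < 1) stopf("no shared genes")
  if (length(groups) > 0 && (is.null(names(groups)) || any(names(groups) == ""))) {
    stopf("groups must be named")
  }
  m <- mrna[genes, samples, drop = FALSE]
  p <- protein[genes, samples, drop = FALSE]
  r <- vapply(seq_along(genes), function(i) {
    suppressWarnings(stats::cor(m[i, ], p[i, ], use = "pairwise.complete.obs"))
  }, numeric(1))
  names(r) <- genes
  if (anyNA(r)) {
    warnf("%d gene(s) with undefined mRNA-protein correlation (zero variance) excluded",
          sum(is.na(r)))
    r <- r[!is.na(r)]
  }
  groups <- lapply(groups, function(s) intersect(as.character(s), names(r)))
  if (add_background) {
    bg <- setdiff(names(r), unlist(groups, use.names = FALSE))
    if (length(bg) > 0) groups <- c(groups, list(background = bg))
  }
  cors <- tibble::tibble(gene = names(r), r = unname(r))
  grp <- rep(NA_character_, nrow(cors))
  for (nm in names(groups)) grp[cors$gene %in% groups[[nm]]] <- nm
  cors$group <- grp
  pairs <- if (length(groups) >= 2) utils::combn(names(groups), 2, simplify = FALSE) else list()
  dtab <- purrr::map_dfr(pairs, function(pr) {
    x <- r[groups[[pr[1]]]]; y <- r[groups[[pr[2]]]]
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   d = if (length(x) >= 2 && length(y) >= 2) cohens_d(x, y) else NA_real_,
                   n1 = length(x), n2 = length(y))
  })
  structure(list(correlations = cors, cohens_d = dtab), class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("<agreement> %d genes, %d group contrasts\n",
              nrow(x$correlations), nrow(x$cohens_d)))
  if (nrow(x$cohens_d) > 0) print(x$cohens_d)
  invisible(x)
}
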