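#' Coerce to an expression matrix
#'
#' Expression data are genes-by-samples non-negative value tables
#' (FPKM/TPM/protein abundance). Accepted inputs: a numeric matrix with gene
#' rownames, or a data frame whose first column holds gene labels and whose
#' remaining columns are numeric sample values. Missing values are allowed.
#'
#' @param x Matrix or data frame.
#' @return Numeric matrix with unique gene rownames and sample colnames.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) stopf("all sample columns must be numeric")
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("expression data must be a numeric matrix or a data frame with a gene-label first column")
  }
  if (is.null(rownames(x))) stopf("expression matrix must have gene labels as rownames")
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate gene labels: %s (collapse duplicates first, e.g. via read_expression())",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  x
}

#' Remove lowly expressed genes
#'
#' Drops every gene whose value falls below `threshold` in more than
#' `max_low` samples (strictly more: a gene low in exactly `max_low`
#' samples is retained). The default — below 1 in more than 50 samples —
#' is an absolute sample count appropriate for cohorts of several hundred
#' to a thousand samples; `max_low_frac` expresses the cutoff as a fraction
#' of the sample count instead.
#'
#' @param x Expression matrix (see [as_expression_matrix()]).
#' @param threshold Expression value below which a sample counts as "low".
#' @param max_low Maximum tolerated number of low samples (absolute count).
#' @param max_low_frac If non-`NULL`, overrides `max_low` with
#'   `max_low_frac * ncol(x)`.
#' @return The filtered matrix; gene order preserved, samples untouched.
#' @export
filter_low_expression <- function(x, threshold = 1, max_low = 50, max_low_frac = NULL) {
  x <- as_expression_matrix(x)
  if (!is.null(max_low_frac)) max_low <- max_low_frac * ncol(x)
  n_low <- rowSums(x < threshold, na.rm = TRUE)
  keep <- n_low <= max_low
  if (!any(keep)) {
    stopf("all %d genes fall below %g in more than %g samples; review filter parameters",
          nrow(x), threshold, max_low)
  }
  x[keep, , drop = FALSE]
}

#' Log-transform expression values
#'
#' `log2(value + offset)`; with the default offset of 1 a zero maps to 0.
#' Base 2 is a reproducibility convention only: Spearman correlation is
#' rank-invariant, and the proportionality coefficient is invariant to a
#' uniform rescaling of log variances, so the base does not affect any
#' downstream network.
#'
#' @param x Expression matrix with non-negative values.
#' @param offset Positive pseudo-count.
#' @return Matrix of the same shape.
#' @export
log_transform <- function(x, offset = 1) {
  x <- as_expression_matrix(x)
  if (offset <= 0) stopf("offset must be positive")
  if (any(x < 0, na.rm = TRUE)) stopf("expression values must be non-negative")
  log2(x + offset)
}

#' Spearman association matrix
#'
#' Gene-by-gene Spearman rank correlation across samples, with
#' pairwise-complete handling of missing values and average ranks for ties.
#' Genes whose ranks have zero variance (constant expression) get all their
#' correlations set to 0, with a warning; the diagonal stays 1.
#'
#' @param x Expression matrix with at least 3 samples.
#' @return Symmetric matrix in \eqn{[-1, 1]} with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- as_expression_matrix(x)
  if (ncol(x) < 3) stopf("at least 3 samples are required for correlation")
  if (nrow(x) < 2) stopf("at least 2 genes are required")
  rho <- suppressWarnings(
    stats::cor(t(x), method = "spearman", use = "pairwise.complete.obs")
  )
  fix_undefined_assoc(rho)
}

fix_undefined_assoc <- function(a) {
  if (anyNA(a)) {
    bad <- rownames(a)[apply(is.na(a) & !diag(nrow(a)), 1, any)]
    warnf("%d gene(s) with undefined association (zero variance or no complete pairs); their values set to 0: %s",
          length(bad), paste(utils::head(bad, 5), collapse = ", "))
    a[is.na(a)] <- 0
  }
  diag(a) <- 1
  a
}

#' Proportionality association matrix
#'
#' The proportionality coefficient
#' \eqn{\rho_p(i, j) = 1 - var(a_i - a_j) / (var(a_i) + var(a_j))}
#' computed on centered-log-ratio (clr) transformed profiles: each sample's
#' log2 values are centered on their per-sample mean across genes, removing
#' the compositional closure that can induce spurious correlations in
#' relative-abundance data. Equivalently \eqn{\rho_p = 2\,cov(a_i, a_j) /
#' (var(a_i) + var(a_j))}, which is how it is computed here (one covariance
#' matrix, pairwise-complete over missing values).
#'
#' @param x Expression matrix of non-negative values; at least 3 samples.
#' @param log_offset Positive pseudo-count added before the log so the clr
#'   is defined at zeros.
#' @return Symmetric matrix in \eqn{[-1, 1]} with unit diagonal.
#' @export
proportionality_matrix <- function(x, log_offset = 1) {
  x <- as_expression_matrix(x)
  if (ncol(x) < 3) stopf("at least 3 samples are required")
  if (nrow(x) < 2) stopf("at least 2 genes are required")
  if (log_offset <= 0) stopf("log_offset must be positive")
  if (any(x < 0, na.rm = TRUE)) stopf("expression values must be non-negative")
  lg <- log2(x + log_offset)
  clr <- sweep(lg, 2, colMeans(lg, na.rm = TRUE)) # per-sample centering over genes
  cv <- stats::cov(t(clr), use = "pairwise.complete.obs")
  v <- diag(cv)
  denom <- outer(v, v, `+`)
  rho <- 2 * cv / denom
  rho[denom == 0] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  fix_undefined_assoc(rho)
}

#' Soft-threshold an association matrix into network weights
#'
#' Maps each association value \eqn{\rho \in [-1, 1]} to the edge weight
#' \eqn{(0.5\,(1 + \rho))^\beta}. With the default \eqn{\beta = 12} this is
#' the unsigned WGCNA adjacency: perfect positive association maps to 1,
#' perfect negative association to 0, and independence to
#' \eqn{0.5^{12} \approx 2.4\times 10^{-4}} — small correlations are
#' suppressed smoothly, and no hard cutoff is applied, so the resulting
#' network is complete.
#'
#' @param assoc Symmetric matrix of values in \eqn{[-1, 1]} with gene labels.
#' @param beta Positive soft-threshold exponent.
#' @return A complete [weighted_network()] of kind `"coexpression"` (zero
#'   diagonal).
#' @export
soft_threshold <- function(assoc, beta = 12) {
  if (beta <= 0) stopf("beta must be positive")
  if (any(assoc < -1 - 1e-9 | assoc > 1 + 1e-9, na.rm = TRUE)) {
    stopf("association values must lie in [-1, 1]")
  }
  w <- (0.5 * (1 + pmin(pmax(assoc, -1), 1)))^beta
  diag(w) <- 0
  weighted_network(w, kind = "coexpression")
}

#' Coexpression build parameters
#'
#' Bundles the knobs of the network construction: the low-expression filter
#' (`filter_threshold`, `filter_max_low`, optionally `filter_max_low_frac`),
#' the log pseudo-count, the soft-threshold exponent `beta`, the association
#' `measure`, whether raw values should be preprocessed at all
#' (`preprocess = FALSE` for matrices that are already filtered/normalized),
#' and the tolerated fraction of missing values per gene (`max_missing_frac`,
#' motivated by proteomics data; genes above it are dropped with a warning).
#'
#' @param filter_threshold,filter_max_low,filter_max_low_frac See
#'   [filter_low_expression()].
#' @param log_offset See [log_transform()].
#' @param beta See [soft_threshold()].
#' @param measure `"spearman"` or `"proportionality"`.
#' @param preprocess Apply filter and log transform (default `TRUE`).
#' @param max_missing_frac Genes with a higher fraction of missing values
#'   are dropped before association (default 0.2).
#' @return A list of class `coexpression_params`.
#' @export
coexpression_params <- function(filter_threshold = 1, filter_max_low = 50,
                                filter_max_low_frac = NULL, log_offset = 1,
                                beta = 12,
                                measure = c("spearman", "proportionality"),
                                preprocess = TRUE, max_missing_frac = 0.2) {
  measure <- match.arg(measure)
  if (beta <= 0) stopf("beta must be positive")
  if (log_offset <= 0) stopf("log_offset must be positive")
  structure(
    list(filter_threshold = filter_threshold, filter_max_low = filter_max_low,
         filter_max_low_frac = filter_max_low_frac, log_offset = log_offset,
         beta = beta, measure = measure, preprocess = preprocess,
         max_missing_frac = max_missing_frac),
    class = "coexpression_params"
  )
}

#' Build a complete weighted coexpression network
#'
#' The full construction: low-expression filter, log transform, association
#' (Spearman or proportionality), soft threshold. For `measure =
#' "proportionality"` the clr transform consumes the filtered raw values
#' directly (it performs its own log). With `preprocess = FALSE` the filter
#' and log steps are skipped and the association is computed on the matrix
#' as given — use this for data already normalized upstream.
#'
#' @param x Expression matrix (genes x samples).
#' @param params A [coexpression_params()] object.
#' @return A complete [weighted_network()]; the parameters used are
#'   recorded in attribute `params`.
#' @examples
#' sim <- planted_expression_pair(n_genes = 30, n_samples_a = 50,
#'                                n_samples_b = 50,
#'                                modules = list(list(genes = 8, loading = 0.9,
#'                                                    active_in = "A")),
#'                                noise_sd = 0.3, seed = 1)
#' net <- build_network(sim$expr_a, coexpression_params(filter_max_low_frac = 0.25))
#' net
#' @export
build_network <- function(x, params = coexpression_params()) {
  stopifnot(inherits(params, "coexpression_params"))
  x <- as_expression_matrix(x)
  if (params$preprocess) {
    x <- filter_low_expression(x, params$filter_threshold, params$filter_max_low,
                               params$filter_max_low_frac)
  }
  miss <- rowMeans(is.na(x))
  if (any(miss > params$max_missing_frac)) {
    drop <- rownames(x)[miss > params$max_missing_frac]
    warnf("dropping %d gene(s) with > %g%% missing values", length(drop),
          100 * params$max_missing_frac)
    x <- x[miss <= params$max_missing_frac, , drop = FALSE]
  }
  assoc <- if (params$measure == "spearman") {
    spearman_matrix(if (params$preprocess) log_transform(x, params$log_offset) else x)
  } else {
    proportionality_matrix(x, params$log_offset)
  }
  net <- soft_threshold(assoc, params$beta)
  attr(net, "params") <- params
  net
}
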