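# Abundance units, the low-expression filter and the MDS QC ordination.

#' Transcripts-per-million from counts and effective lengths
#'
#' Per sample, each gene's count is converted to a length-normalized rate
#' `count / length`, and rates are rescaled so the column sums to one
#' million. A sample with no counts yields an all-zero column rather than
#' an error.
#'
#' @param counts A [count_matrix()] or a plain numeric matrix.
#' @param lengths Named numeric vector of per-gene effective lengths (bp);
#'   must cover every gene in `counts`.
#' @return Numeric matrix of TPM with attribute `kind = "tpm"`.
#' @export
compute_tpm <- function(counts, lengths) {
  m <- as_count_mat(counts)
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss)) {
    stop("missing length for genes: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10),
         call. = FALSE)
  }
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("effective lengths must be > 0", call. = FALSE)
  rate <- m / len
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero sample stays all-zero
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  attr(tpm, "kind") <- "tpm"
  tpm
}

#' Apply the low-expression filter
#'
#' Genes with abundance below `threshold` TPM are excluded; a gene at
#' exactly the threshold is retained. The default rule averages TPM over
#' samples; alternative rules require every sample (`"all-samples"`) or at
#' least one (`"any-sample"`) to reach the threshold. The retained set is
#' the species' expression-filtered universe used downstream as the
#' sampling frame of the overlap permutation test.
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param threshold Minimum TPM (default 1).
#' @param rule Aggregation rule across samples.
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(tpm, threshold = 1,
                                  rule = c("mean", "all-samples",
                                           "any-sample")) {
  rule <- match.arg(rule)
  if (!identical(attr(tpm, "kind"), "tpm")) {
    stop("`tpm` must come from compute_tpm()", call. = FALSE)
  }
  stat <- switch(rule,
    "mean" = rowMeans(tpm),
    "all-samples" = apply(tpm, 1, min),
    "any-sample" = apply(tpm, 1, max))
  keep <- rownames(tpm)[stat >= threshold]
  if (!length(keep)) warning("no genes pass the expression filter")
  keep
}

#' Log2 counts per million
#'
#' Library-size-normalized log abundance with a prior count to keep zeros
#' finite. The prior is scaled per library in proportion to its size
#' (matching the convention of the major DE toolkits), so equal count
#' profiles give equal columns regardless of depth:
#' `log2((y + pc_s) / (L_s + 2 * pc_s) * 1e6)` with
#' `pc_s = prior_count * L_s / mean(L)`.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param prior_count Prior count at the average library size (default 2).
#' @param norm_factors Optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); effective library size is `L_s * factor_s`.
#' @return Numeric matrix of log2-CPM with attribute `kind = "log2cpm"`.
#' @export
log2_cpm <- function(counts, prior_count = 2, norm_factors = NULL) {
  m <- as_count_mat(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be > 0", call. = FALSE)
  if (!is.null(norm_factors)) lib <- lib * norm_factors
  pc <- prior_count * lib / mean(lib)
  out <- log2(sweep(sweep(m, 2, pc, "+"), 2, lib + 2 * pc, "/") * 1e6)
  attr(out, "kind") <- "log2cpm"
  out
}

#' Classical MDS coordinates of samples
#'
#' QC ordination: Euclidean sample-sample distances over the most variable
#' genes of a log2-CPM matrix, embedded by classical (Torgerson) metric
#' MDS. Coordinates are centered at the origin and dimension 1 carries the
#' largest eigenvalue.
#'
#' @param expr log2-CPM matrix from [log2_cpm()].
#' @param n_top_genes Number of top-variance genes to use (default 500;
#'   capped at the number of genes available).
#' @param n_dims Number of dimensions to return (default 2).
#' @return Matrix (samples x dimensions) of coordinates, with the
#'   eigenvalues in attribute `eig`.
#' @export
mds_coordinates <- function(expr, n_top_genes = 500, n_dims = 2) {
  if (!identical(attr(expr, "kind"), "log2cpm")) {
    stop("`expr` must come from log2_cpm()", call. = FALSE)
  }
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples for MDS", call. = FALSE)
  if (n < n_dims + 1) {
    stop(sprintf("need at least %d samples for %d dimensions",
                 n_dims + 1, n_dims), call. = FALSE)
  }
  v <- apply(expr, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(expr)))]
  d <- stats::dist(t(expr[top, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  coords <- fit$points
  # cmdscale drops trailing zero-eigenvalue axes for degenerate inputs
  if (ncol(coords) < n_dims) {
    coords <- cbind(coords, matrix(0, nrow(coords), n_dims - ncol(coords)))
  }
  dimnames(coords) <- list(colnames(expr), paste0("dim", seq_len(n_dims)))
  attr(coords, "eig") <- fit$eig
  coords
}

# Accept either a count_matrix or a bare matrix.
as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else {
    if (!is.matrix(x) || !is.numeric(x)) {
      stop("expected a count_matrix or numeric matrix", call. = FALSE)
    }
    x
  }
}
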