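#' Construct a validated gene-by-sample count matrix
#'
#' The basic container of the pipeline: a non-negative integer matrix of
#' gene-level counts (rows = genes, columns = samples) together with a
#' per-sample metadata table. Metadata must carry a `sample` and a
#' `condition` column; any further columns (e.g. `block` for family
#' structure, or `timepoint` for a treatment time course) are kept and can
#' be referenced by contrasts downstream.
#'
#' @param counts Numeric matrix of counts with unique rownames (gene ids)
#'   and colnames (sample ids). Values must be non-negative integers
#'   (integer-valued doubles are accepted and coerced).
#' @param sample_meta Data frame with one row per sample; must contain
#'   columns `sample` and `condition`, covering every column of `counts`.
#'   Columns of `counts` are reordered to match the sheet order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `samples` (data frame).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 8L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample = c("s1", "s2"), condition = c("a", "b"))
#' cm <- count_matrix(m, meta)
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid)) {
    stop("`counts` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  if (!is.data.frame(sample_meta) ||
      !all(c("sample", "condition") %in% names(sample_meta))) {
    stop("`sample_meta` needs columns `sample` and `condition`", call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  sample_meta$sample <- as.character(sample_meta$sample)
  missing <- setdiff(sample_meta$sample, sid)
  if (length(missing)) {
    stop("samples in sheet missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(sid, sample_meta$sample)
  if (length(extra)) {
    stop("samples in matrix missing from sheet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts <- counts[, sample_meta$sample, drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, samples = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:",
      paste(sprintf("%s(%d)", names(table(x$samples$condition)),
                    table(x$samples$condition)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a set of samples
#'
#' @param x A `count_matrix`.
#' @param samples Character vector of sample ids to keep (sheet order kept).
#' @return A `count_matrix` restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$samples$sample %in% samples
  if (!any(keep)) stop("no matching samples", call. = FALSE)
  count_matrix(x$counts[, x$samples$sample[keep], drop = FALSE],
               x$samples[keep, , drop = FALSE])
}

#' Aggregate transcript-level counts to gene level
#'
#' Optional pre-step for transcript-level inputs: sums counts of all
#' transcripts mapped to the same gene. The pipeline otherwise assumes
#' counts are already at the analysis (gene) level.
#'
#' @param counts Numeric matrix with transcript rownames.
#' @param tx2gene Data frame or 2-column matrix mapping transcript id
#'   (column 1) to gene id (column 2).
#' @return Matrix of summed counts with gene rownames.
#' @export
aggregate_transcripts <- function(counts, tx2gene) {
  tx2gene <- as.data.frame(tx2gene, stringsAsFactors = FALSE)
  if (ncol(tx2gene) < 2) stop("`tx2gene` needs 2 columns", call. = FALSE)
  idx <- match(rownames(counts), tx2gene[[1]])
  if (anyNA(idx)) {
    stop("transcripts without gene assignment: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  gene <- factor(tx2gene[[2]][idx])
  out <- rowsum(counts, gene)
  out[levels(gene), , drop = FALSE]
}
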