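# Plain-text readers/writers for the pipeline's tabular interchange formats.
# All tables are tab-separated; gene and sample identifiers are opaque,
# case-sensitive strings and are never normalized.

#' Read a count matrix and its sample sheet
#'
#' The counts file is a TSV whose first column holds gene ids and whose
#' remaining columns are samples; the sample sheet is a TSV with columns
#' `sample`, `condition` and optionally `block` or `timepoint`. Columns of
#' the matrix are reordered to the sheet's sample order.
#'
#' @param counts_path Path to the counts TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, sample_sheet_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs gene id + sample columns",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in ", counts_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells in ", counts_path,
                           call. = FALSE)
  rownames(m) <- ids
  meta <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

#' Write a count matrix and sample sheet to TSV
#'
#' @param cm A `count_matrix`.
#' @param counts_path,sample_sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(cm, counts_path, sample_sheet_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, sample_sheet_path)
  invisible(c(counts_path, sample_sheet_path))
}

#' Read per-gene effective lengths
#'
#' @param path TSV with columns gene id and effective length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_lengths <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("lengths file needs 2 columns", call. = FALSE)
  out <- as.numeric(tab[[2]])
  names(out) <- as.character(tab[[1]])
  if (anyNA(out) || any(out <= 0)) {
    stop("lengths must be positive numbers", call. = FALSE)
  }
  out
}

#' Write per-gene lengths
#' @param lengths Named numeric vector.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lengths <- function(lengths, path) {
  write_tsv(data.frame(gene_id = names(lengths), length = as.numeric(lengths),
                       stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read / write a one-id-per-line gene list
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read / write a 2-column ortholog-pair table
#' @param path File path.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    stop("ortholog table needs columns gene_a, gene_b", call. = FALSE)
  }
  tab[, c("gene_a", "gene_b")]
}

#' @rdname read_ortholog_pairs
#' @param map Data frame with columns `gene_a`, `gene_b`.
#' @export
write_ortholog_pairs <- function(map, path) {
  write_tsv(map[, c("gene_a", "gene_b")], path)
  invisible(path)
}

# Internal TSV writer: no quoting, no rownames, fixed col separator.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
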