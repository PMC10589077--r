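# Reciprocal-best-hit ortholog mapping from 12-column tabular alignment
# hit files (outfmt-6 dialect), as produced by blastn and compatible
# aligners. Alignment execution is out of scope: both directions' hit
# tables are consumed precomputed.

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard 12-column tab-separated hit format and retains
#' records with `evalue <= evalue_max`. With `strict = TRUE` (default) a
#' malformed row aborts with its line number; otherwise malformed rows are
#' skipped with a warning listing the line numbers.
#'
#' @param path Path to the hit table.
#' @param evalue_max E-value retention threshold (default 1e-5).
#' @param strict Abort on malformed rows? (default TRUE)
#' @return Data frame of hit records with the 12 standard columns.
#' @export
read_hit_table <- function(path, evalue_max = 1e-5, strict = TRUE) {
  if (!file.exists(path)) stop("cannot read hit table: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty hit table: ", path)
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  parse_num <- function(i) as.numeric(vapply(fields, `[`, "", i))
  if (length(bad) == 0) {
    num <- lapply(3:12, parse_num)
    badnum <- integer(0)
  } else {
    if (strict) {
      stop(sprintf("line %d of %s has %d fields (12 expected)",
                   bad[1], path, nf[bad[1]]), call. = FALSE)
    }
    fields[bad] <- list(rep(NA_character_, 12L))
    num <- lapply(3:12, parse_num)
    badnum <- integer(0)
  }
  df <- data.frame(
    qseqid = vapply(fields, `[`, "", 1L),
    sseqid = vapply(fields, `[`, "", 2L),
    stringsAsFactors = FALSE)
  for (i in seq_along(num)) df[[HIT_COLS[i + 2]]] <- num[[i]]
  malformed <- nf != 12L | Reduce(`|`, lapply(df[3:12], is.na))
  if (any(malformed)) {
    if (strict) {
      stop(sprintf("malformed numeric field at line %d of %s",
                   which(malformed)[1], path), call. = FALSE)
    }
    warning(sprintf("skipped %d malformed line(s) in %s: %s",
                    sum(malformed), path,
                    paste(utils::head(which(malformed), 10), collapse = ", ")))
    df <- df[!malformed, , drop = FALSE]
  }
  if (any(df$evalue < 0)) stop("negative evalue in ", path, call. = FALSE)
  df <- df[df$evalue <= evalue_max, , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_hits <- function() {
  df <- data.frame(qseqid = character(0), sseqid = character(0),
                   stringsAsFactors = FALSE)
  for (col in HIT_COLS[3:12]) df[[col]] <- numeric(0)
  df
}

#' Best hit per query
#'
#' Collapses multiple HSPs of a query-subject pair to the single
#' max-bitscore HSP, then selects each query's best subject by bitscore;
#' ties break by smaller e-value, then larger percent identity, then the
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param hits Data frame from [read_hit_table()].
#' @return Named character vector: `query -> subject`.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$qseqid,
               -hits$bitscore,
               hits$evalue,
               -hits$pident,
               hits$sseqid,
               method = "radix")
  h <- hits[ord, , drop = FALSE]
  # after sorting, the first row per (query, subject) is its best HSP and
  # the first row per query is its best subject
  first <- !duplicated(h$qseqid)
  stats::setNames(h$sseqid[first], h$qseqid[first])
}

#' Reciprocal-best-hit ortholog map
#'
#' A pair `(a, b)` is included iff `a`'s best hit in the A-to-B direction
#' is `b` and `b`'s best hit in the B-to-A direction is `a`. The result is
#' one-to-one by construction.
#'
#' @param best_a_to_b,best_b_to_a Named best-hit vectors from
#'   [best_hits()] for the two search directions.
#' @return Data frame with columns `gene_a`, `gene_b`, ordered by
#'   `gene_a`.
#' @export
build_rbh_map <- function(best_a_to_b, best_b_to_a) {
  a <- names(best_a_to_b)
  b <- unname(best_a_to_b)
  back <- unname(best_b_to_a[b])
  keep <- !is.na(back) & back == a
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
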