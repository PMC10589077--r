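# Over-representation analysis of gene lists against GMT collections:
# one-sided hypergeometric tail per set, BH across sets.

#' Read a GMT gene-set collection
#'
#' GMT lines are `name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a set are collapsed; duplicate set names are
#' an error. When a `background` is supplied, members outside it are
#' dropped (with a message giving the count).
#'
#' @param path Path to the GMT file.
#' @param background Optional character vector restricting set members.
#' @return An object of class `geneset_collection`: list with `sets`
#'   (named list of character vectors), `description` (named character)
#'   and `background` (or `NULL`).
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name at line ",
         which(duplicated(nm))[1], ": ", nm[duplicated(nm)][1], call. = FALSE)
  }
  desc <- stats::setNames(vapply(fields, `[`, "", 2L), nm)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (!is.null(background)) {
    dropped <- sum(vapply(sets, function(s) sum(!s %in% background), 0L))
    if (dropped > 0) {
      message(sprintf("dropped %d set member(s) outside the background",
                      dropped))
    }
    sets <- lapply(sets, function(s) s[s %in% background])
  }
  structure(list(sets = sets, description = desc, background = background),
            class = "geneset_collection")
}

#' Write a collection in GMT format
#' @param collection A `geneset_collection` (or named list of id vectors).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "geneset_collection")) {
    collection$sets
  } else {
    collection
  }
  desc <- if (inherits(collection, "geneset_collection")) {
    collection$description
  } else {
    stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each set, the overlap of the query list with the set (both
#' restricted to the background) is tested against the upper tail of a
#' hypergeometric distribution: `p = P[X >= k]` with `X ~
#' Hypergeometric(N = |background|, K = |set|, n = |query|)`. BH
#' correction is applied across the sets reaching `min_overlap`. This is
#' a self-contained replacement for web-service enrichment tools; term
#' lists are not expected to match any live-database analysis.
#'
#' @param query Character vector of gene ids; must lie in `background`.
#' @param collection A `geneset_collection` from [read_gmt()], or a named
#'   list of character vectors.
#' @param background Character vector: the test universe. Defaults to the
#'   collection's background; an external (e.g. proteome-wide) background
#'   may be supplied instead.
#' @param min_overlap Minimum overlap for a set to enter the BH family
#'   (default 2).
#' @return Data frame, one row per set with overlap `>= min_overlap`,
#'   ordered by p: `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p_value`, `q_value`.
#' @export
ora_test <- function(query, collection, background = NULL, min_overlap = 2) {
  sets <- if (inherits(collection, "geneset_collection")) {
    collection$sets
  } else {
    collection
  }
  if (is.null(background) && inherits(collection, "geneset_collection")) {
    background <- collection$background
  }
  if (is.null(background)) {
    stop("a background universe is required", call. = FALSE)
  }
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  if (!all(query %in% background)) {
    stop("query contains genes outside the background: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!length(query)) {
    warning("empty query; no enrichment computed")
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      background_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(s, query))
    K <- length(s)
    # upper tail P[X >= k]
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
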