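# Cross-species DEG overlap: observed mapped-pair overlap, three-way
# classification of focal DEGs, a permutation null over the two
# expression-filtered universes, and the closed-form expectation used as
# an analytic cross-check of the permutation machinery.

#' Assemble the inputs of the overlap analysis
#'
#' Validates and packages the two species' expression-filtered universes,
#' their DEG sets, and the ortholog map. The map is restricted to pairs
#' with both members in their universes.
#'
#' @param universe_a,universe_b Character vectors: the expression-filtered
#'   gene universes (the sampling frames of the permutation test).
#' @param deg_a,deg_b Character vectors: DEG sets, subsets of the
#'   universes (A is the focal species).
#' @param map Data frame with columns `gene_a`, `gene_b` from
#'   [build_rbh_map()].
#' @return An object of class `overlap_input`.
#' @export
overlap_input <- function(universe_a, universe_b, deg_a, deg_b, map) {
  universe_a <- unique(as.character(universe_a))
  universe_b <- unique(as.character(universe_b))
  deg_a <- unique(as.character(deg_a))
  deg_b <- unique(as.character(deg_b))
  if (!all(deg_a %in% universe_a)) {
    stop("deg_a contains genes outside universe_a: ",
         paste(utils::head(setdiff(deg_a, universe_a), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(deg_b %in% universe_b)) {
    stop("deg_b contains genes outside universe_b: ",
         paste(utils::head(setdiff(deg_b, universe_b), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
    stop("ortholog map must be one-to-one", call. = FALSE)
  }
  keep <- map$gene_a %in% universe_a & map$gene_b %in% universe_b
  map <- map[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(map) <- NULL
  structure(list(universe_a = universe_a, universe_b = universe_b,
                 deg_a = deg_a, deg_b = deg_b, map = map),
            class = "overlap_input")
}

#' @export
print.overlap_input <- function(x, ...) {
  cat(sprintf(
    "overlap_input: N_A=%d N_B=%d n_A=%d n_B=%d mapped pairs M=%d\n",
    length(x$universe_a), length(x$universe_b),
    length(x$deg_a), length(x$deg_b), nrow(x$map)))
  invisible(x)
}

#' Count mapped DEG-DEG pairs
#'
#' @param deg_a,deg_b Character vectors of DEGs.
#' @param map Ortholog-pair data frame (`gene_a`, `gene_b`).
#' @return Integer: number of mapped pairs with both members DE.
#' @export
overlap_count <- function(deg_a, deg_b, map) {
  sum(map$gene_a %in% deg_a & map$gene_b %in% deg_b)
}

#' Classify focal-species DEGs against the reference species
#'
#' Each focal (species A) DEG falls in exactly one class: `shared` (its
#' ortholog is DE in species B), `not_sig` (ortholog tested in B but not
#' significant), `unaligned` (no ortholog in the map), or `untested`
#' (ortholog mapped but not tested in B, e.g. filtered out). The classes
#' partition the focal DEG set.
#'
#' @param input An [overlap_input()].
#' @param tested_b Character vector of species-B genes that were tested
#'   (must lie in `universe_b`).
#' @return List with the observed overlap `k`, the four class id vectors
#'   (`class_shared`, `class_not_sig`, `class_unaligned`,
#'   `class_untested`), and `class_counts`.
#' @export
classify_degs <- function(input, tested_b) {
  stopifnot(inherits(input, "overlap_input"))
  tested_b <- unique(as.character(tested_b))
  if (!all(tested_b %in% input$universe_b)) {
    stop("tested_b must lie within universe_b", call. = FALSE)
  }
  partner <- stats::setNames(input$map$gene_b, input$map$gene_a)
  orth <- partner[input$deg_a]
  unaligned <- input$deg_a[is.na(orth)]
  mapped <- input$deg_a[!is.na(orth)]
  orth <- orth[!is.na(orth)]
  shared <- mapped[orth %in% input$deg_b]
  not_sig <- mapped[orth %in% setdiff(tested_b, input$deg_b)]
  untested <- setdiff(mapped, c(shared, not_sig))
  counts <- c(shared = length(shared), not_sig = length(not_sig),
              unaligned = length(unaligned), untested = length(untested))
  list(k = length(shared),
       class_shared = shared, class_not_sig = not_sig,
       class_unaligned = unaligned, class_untested = untested,
       class_counts = counts)
}

#' Permutation test of cross-species DEG overlap
#'
#' The null draws, independently for each species, a uniform sample
#' without replacement of the observed DEG count from that species'
#' expression-filtered universe (draws deliberately ignore the ortholog
#' map), and counts the mapped-pair overlap. The one-sided empirical
#' p-value is the fraction of permutations whose overlap equals or
#' exceeds the observed overlap; because that rule can return 0, the
#' add-one estimator `(#{perm >= k} + 1) / (n_perm + 1)` is reported
#' alongside.
#'
#' @param input An [overlap_input()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream (optional).
#' @param map_restricted If `TRUE`, draw only from mapped genes instead of
#'   the full universes (non-default variant).
#' @return List: `observed` k, `perm_overlaps` (length `n_perm`),
#'   `p_empirical`, `p_add_one`, `expected` (closed-form mean/variance),
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(input, n_perm = 1000, seed = NULL,
                             map_restricted = FALSE) {
  stopifnot(inherits(input, "overlap_input"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  uni_a <- if (map_restricted) input$map$gene_a else input$universe_a
  uni_b <- if (map_restricted) input$map$gene_b else input$universe_b
  n_a <- length(input$deg_a); n_b <- length(input$deg_b)
  if (n_a > length(uni_a) || n_b > length(uni_b)) {
    stop("DEG set larger than its sampling universe", call. = FALSE)
  }
  k_obs <- overlap_count(input$deg_a, input$deg_b, input$map)
  # indices of each mapped pair's members within the sampling universes
  ia <- match(input$map$gene_a, uni_a)
  ib <- match(input$map$gene_b, uni_b)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  N_a <- length(uni_a); N_b <- length(uni_b)
  in_a <- logical(N_a); in_b <- logical(N_b)
  perm <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    in_a[] <- FALSE; in_b[] <- FALSE
    in_a[sample.int(N_a, n_a)] <- TRUE
    in_b[sample.int(N_b, n_b)] <- TRUE
    perm[r] <- sum(in_a[ia] & in_b[ib])
  }
  hits <- sum(perm >= k_obs)
  list(observed = k_obs,
       perm_overlaps = perm,
       p_empirical = hits / n_perm,
       p_add_one = (hits + 1) / (n_perm + 1),
       expected = expected_overlap(input, map_restricted = map_restricted),
       n_perm = n_perm,
       seed = seed)
}

#' Closed-form mean and variance of the permutation overlap
#'
#' Under the permutation scheme, the overlap is a sum over the M mapped
#' pairs of products of two without-replacement inclusion indicators.
#' Linearity gives mean `M * (n_A/N_A) * (n_B/N_B)`; the variance uses the
#' exact pairwise inclusion probabilities
#' `n(n-1) / (N(N-1))` of the hypergeometric draw (distinct mapped pairs
#' share no genes because the map is one-to-one).
#'
#' @param input An [overlap_input()].
#' @param map_restricted Match the sampling frame of
#'   [permutation_test()]'s variant.
#' @return List with `mean` and `variance`.
#' @export
expected_overlap <- function(input, map_restricted = FALSE) {
  stopifnot(inherits(input, "overlap_input"))
  M <- nrow(input$map)
  N_a <- if (map_restricted) M else length(input$universe_a)
  N_b <- if (map_restricted) M else length(input$universe_b)
  n_a <- length(input$deg_a); n_b <- length(input$deg_b)
  if (M == 0) return(list(mean = 0, variance = 0))
  p_a <- n_a / N_a; p_b <- n_b / N_b
  p1 <- p_a * p_b
  mu <- M * p1
  p_a2 <- if (N_a > 1) n_a * (n_a - 1) / (N_a * (N_a - 1)) else p_a
  p_b2 <- if (N_b > 1) n_b * (n_b - 1) / (N_b * (N_b - 1)) else p_b
  ex2 <- M * p1 + M * (M - 1) * p_a2 * p_b2
  list(mean = mu, variance = max(ex2 - mu^2, 0))
}

#' Cross-species logFC concordance of shared DEG pairs
#'
#' For every mapped pair DE in both species, tabulates both species'
#' fold changes and significance and flags whether the directions agree
#' under a user-declared correspondence of condition orientations. The
#' correspondence is never inferred from the data: `orientation = c(1, 1)`
#' declares that each contrast's `condition_b` corresponds across species;
#' use -1 to flip a side. Pairs with a missing logFC are flagged
#' incomplete rather than dropped.
#'
#' @param shared_pairs Data frame (`gene_a`, `gene_b`) of pairs DE in
#'   both species.
#' @param de_a,de_b [fit_and_test()] results for the two contrasts.
#' @param labels_a,labels_b Character vectors of length 2: the condition
#'   labels `(a, b)` of each contrast, used to print which condition had
#'   higher expression.
#' @param orientation Numeric length-2 vector of +-1 declaring the
#'   condition correspondence (see above).
#' @return Data frame with one row per shared pair: ids, both logFCs and
#'   p-values, higher-expression labels, `concordant`, `incomplete`.
#' @export
concordance_table <- function(shared_pairs, de_a, de_b,
                              labels_a = c("a", "b"),
                              labels_b = c("a", "b"),
                              orientation = c(1, 1)) {
  stopifnot(length(orientation) == 2, all(orientation %in% c(-1, 1)))
  ia <- match(shared_pairs$gene_a, de_a$gene)
  ib <- match(shared_pairs$gene_b, de_b$gene)
  lfc_a <- de_a$logFC[ia]; lfc_b <- de_b$logFC[ib]
  incomplete <- is.na(lfc_a) | is.na(lfc_b)
  higher <- function(lfc, labels) {
    ifelse(is.na(lfc), NA_character_, ifelse(lfc > 0, labels[2], labels[1]))
  }
  data.frame(
    gene_a = shared_pairs$gene_a,
    gene_b = shared_pairs$gene_b,
    logFC_a = lfc_a, p_a = de_a$p_value[ia],
    logFC_b = lfc_b, p_b = de_b$p_value[ib],
    higher_a = higher(lfc_a, labels_a),
    higher_b = higher(lfc_b, labels_b),
    concordant = ifelse(incomplete, NA,
                        sign(lfc_a * orientation[1]) ==
                          sign(lfc_b * orientation[2])),
    incomplete = incomplete,
    stringsAsFactors = FALSE)
}

#' Histogram of permutation overlaps as a frequency table
#'
#' @param perm_overlaps Integer vector from [permutation_test()].
#' @return Data frame with columns `overlap`, `frequency`, covering the
#'   full observed range.
#' @export
permutation_histogram <- function(perm_overlaps) {
  tab <- table(factor(perm_overlaps,
                      levels = seq(min(perm_overlaps), max(perm_overlaps))))
  data.frame(overlap = as.integer(names(tab)),
             frequency = as.integer(tab), row.names = NULL)
}
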