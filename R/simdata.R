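# Two-species synthetic RNA-seq generator. Emulates the statistical
# structure the downstream analysis assumes: partially overlapping 1:1
# ortholog catalogs, negative-binomial counts with block structure in the
# focal species and a timepoint course against a shared control in the
# reference species, a configurable fraction of truly DE genes per
# contrast, and a configurable fraction of ortholog pairs sharing
# plasticity. All stochastic draws derive from one RNG stream seeded from
# the config.

#' Build and validate a simulation configuration
#'
#' Defaults reflect the study design the pipeline targets: a focal
#' species with two trophic morphs sampled across families (blocks), a
#' reference species with a control and three treatment timepoints, a
#' shared fraction of 0.562 of the joint ortholog catalog, and log2
#' fold changes spanning 0.8-3.
#'
#' @param n_genes_a,n_genes_b Gene counts per species (>= 10).
#' @param frac_shared_orthologs Fraction of the two catalogs' union that
#'   is 1:1 orthologous (default 0.562).
#' @param samples_a Data frame `condition`, `block`: the focal species'
#'   sample sheet. Default: 3 + 3 morphs in each of 2 families.
#' @param samples_b Data frame `condition`, `timepoint`: the reference
#'   species. Default: 4 controls and 4 treatment samples at each of
#'   t24/t48/t72.
#' @param frac_de_a Fraction of focal genes truly DE between morphs
#'   (default 0.35, emulating the roughly one-third of tested genes with
#'   morph-biased expression in the motivating system).
#' @param frac_de_b_per_timepoint Fraction of reference genes truly DE in
#'   each control-vs-timepoint contrast (default 0.02).
#' @param rho_shared Fraction of DE ortholog pairs forced DE in both
#'   species (default 0; forced pairs are DE at every timepoint).
#' @param prob_concordant Probability a forced shared pair's effects have
#'   the same sign (default 0.5).
#' @param logfc_range Positive `(low, high)` range of |log2 fold change|
#'   (default 0.8-3).
#' @param baseline_logmean_params `(mu, sigma)` of the log-normal
#'   baseline mean-count distribution (natural-log scale; default 4, 1).
#' @param dispersion_params `(phi0, a)` of the dispersion trend
#'   `phi(mu) = phi0 + a / mu` (default 0.16, 0.5).
#' @param libsize_cv Coefficient of variation of library-size factors
#'   (default 0.2).
#' @param frac_low_expression Fraction of genes simulated below the 1-TPM
#'   filter (default 0.1).
#' @param block_sigma Log-normal sigma of per-(gene, block)
#'   multiplicative effects (default 0.1).
#' @param decoy_max Max decoy alignments per gene (0-2 drawn uniformly;
#'   default 2).
#' @param inject_ties Give decoys bitscore/e-value ties with the true hit
#'   to exercise downstream tie-breaking (default FALSE).
#' @param n_pathways Number of pathway labels used to build the GMT
#'   fixture (default 20).
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes_a = 4000,
                       n_genes_b = 4000,
                       frac_shared_orthologs = 0.562,
                       samples_a = NULL,
                       samples_b = NULL,
                       frac_de_a = 0.35,
                       frac_de_b_per_timepoint = 0.02,
                       rho_shared = 0,
                       prob_concordant = 0.5,
                       logfc_range = c(0.8, 3),
                       baseline_logmean_params = c(mu = 4, sigma = 1),
                       dispersion_params = c(phi0 = 0.16, a = 0.5),
                       libsize_cv = 0.2,
                       frac_low_expression = 0.1,
                       block_sigma = 0.1,
                       decoy_max = 2,
                       inject_ties = FALSE,
                       n_pathways = 20,
                       seed = 1) {
  if (is.null(samples_a)) {
    samples_a <- expand.grid(rep = 1:3,
                             condition = c("omnivore", "carnivore"),
                             block = c("fam1", "fam2"),
                             stringsAsFactors = FALSE)[, c("condition",
                                                          "block")]
  }
  if (is.null(samples_b)) {
    samples_b <- rbind(
      data.frame(condition = "control", timepoint = "control", n = 4),
      data.frame(condition = "treatment", timepoint = c("t24", "t48", "t72"),
                 n = 4))
    samples_b <- samples_b[rep(seq_len(nrow(samples_b)), samples_b$n),
                           c("condition", "timepoint")]
  }
  cfg <- list(n_genes_a = n_genes_a, n_genes_b = n_genes_b,
              frac_shared_orthologs = frac_shared_orthologs,
              samples_a = as.data.frame(samples_a),
              samples_b = as.data.frame(samples_b),
              frac_de_a = frac_de_a,
              frac_de_b_per_timepoint = frac_de_b_per_timepoint,
              rho_shared = rho_shared, prob_concordant = prob_concordant,
              logfc_range = as.numeric(logfc_range),
              baseline_logmean_params = as.numeric(baseline_logmean_params),
              dispersion_params = as.numeric(dispersion_params),
              libsize_cv = libsize_cv,
              frac_low_expression = frac_low_expression,
              block_sigma = block_sigma, decoy_max = decoy_max,
              inject_ties = inject_ties, n_pathways = n_pathways,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("invalid config: `%s` must be a fraction in [0, 1]",
                   field), call. = FALSE)
    }
  }
  for (f in c("frac_shared_orthologs", "frac_de_a",
              "frac_de_b_per_timepoint", "rho_shared", "prob_concordant",
              "frac_low_expression")) chk_frac(f)
  if (cfg$n_genes_a < 10 || cfg$n_genes_b < 10) {
    stop("invalid config: `n_genes_a`/`n_genes_b` must be >= 10",
         call. = FALSE)
  }
  if (length(cfg$logfc_range) != 2 || cfg$logfc_range[1] <= 0 ||
      cfg$logfc_range[2] < cfg$logfc_range[1]) {
    stop("invalid config: `logfc_range` must be 0 < low <= high",
         call. = FALSE)
  }
  if (cfg$libsize_cv < 0) {
    stop("invalid config: `libsize_cv` must be >= 0", call. = FALSE)
  }
  if (any(cfg$dispersion_params < 0)) {
    stop("invalid config: `dispersion_params` must be >= 0", call. = FALSE)
  }
  sa <- cfg$samples_a
  if (!all(c("condition", "block") %in% names(sa))) {
    stop("invalid config: `samples_a` needs condition and block columns",
         call. = FALSE)
  }
  if (length(unique(sa$condition)) != 2 || any(table(sa$condition) < 2)) {
    stop("invalid config: `samples_a` needs 2 conditions with >= 2 samples",
         call. = FALSE)
  }
  sb <- cfg$samples_b
  if (!all(c("condition", "timepoint") %in% names(sb))) {
    stop("invalid config: `samples_b` needs condition and timepoint columns",
         call. = FALSE)
  }
  if (sum(sb$condition == "control") < 2) {
    stop("invalid config: `samples_b` needs >= 2 control samples",
         call. = FALSE)
  }
  trt <- sb[sb$condition != "control", ]
  if (!nrow(trt) || any(table(trt$timepoint) < 2)) {
    stop("invalid config: `samples_b` needs >= 2 samples per timepoint",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a full two-species dataset
#'
#' Draws negative-binomial counts (mean = library-size-scaled baseline x
#' condition fold change x block effect; dispersion `phi0 + a/mu`) for
#' both species, alignment hit tables encoding the true ortholog map as
#' mutual best hits plus lower-scoring decoys, gene lengths, pathway
#' labels, and an exact truth table.
#'
#' @param config A [sim_config()].
#' @return List: `counts_a`, `counts_b` ([count_matrix()]s), `lengths_a`,
#'   `lengths_b` (named vectors), `hits_a_to_b`, `hits_b_to_a` (hit
#'   tables), `pathways` (named list), `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must come from sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  nA <- config$n_genes_a; nB <- config$n_genes_b
  genes_a <- sprintf("SMA%05d", seq_len(nA))
  genes_b <- sprintf("PCU%05d", seq_len(nB))

  # ortholog catalog: S shared pairs so that S / (nA + nB - S) = frac
  frac <- config$frac_shared_orthologs
  S <- round(frac * (nA + nB) / (1 + frac))
  S <- min(S, nA, nB)
  paired_a <- sort(sample(genes_a, S))
  paired_b <- sample(genes_b, S)  # random partner assignment
  pairs <- data.frame(gene_a = paired_a, gene_b = paired_b,
                      stringsAsFactors = FALSE)

  lengths_a <- stats::setNames(pmax(round(stats::rlnorm(nA, log(1000), 0.6)),
                                    200), genes_a)
  lengths_b <- stats::setNames(pmax(round(stats::rlnorm(nB, log(1000), 0.6)),
                                    200), genes_b)

  # baselines; a fraction of genes sits far below the 1-TPM filter
  blp <- config$baseline_logmean_params
  base_a <- stats::setNames(stats::rlnorm(nA, blp[1], blp[2]), genes_a)
  base_b <- stats::setNames(stats::rlnorm(nB, blp[1], blp[2]), genes_b)
  low_a <- sample(genes_a, round(config$frac_low_expression * nA))
  low_b <- sample(genes_b, round(config$frac_low_expression * nB))
  base_a[low_a] <- base_a[low_a] * 0.001
  base_b[low_b] <- base_b[low_b] * 0.001

  # true DE in A, stratified over paired/unpaired genes so that the
  # realized shared-pair count is exact
  unpaired_a <- setdiff(genes_a, paired_a)
  n_de_paired <- round(config$frac_de_a * S)
  n_de_unpaired <- round(config$frac_de_a * (nA - S))
  de_a <- c(sample(paired_a, n_de_paired),
            if (n_de_unpaired > 0) sample(unpaired_a, n_de_unpaired))
  lfc_a <- stats::setNames(
    draw_logfc(length(de_a), config$logfc_range), de_a)

  # shared plasticity: rho_shared of the DE ortholog pairs forced DE in B
  de_paired_rows <- pairs[pairs$gene_a %in% de_a, , drop = FALSE]
  n_shared <- round(config$rho_shared * nrow(de_paired_rows))
  shared <- de_paired_rows[sample(nrow(de_paired_rows), n_shared), ,
                           drop = FALSE]
  concordant <- stats::runif(n_shared) < config$prob_concordant
  shared$concordant <- concordant

  timepoints <- unique(config$samples_b$timepoint[
    config$samples_b$condition != "control"])
  n_de_b <- round(config$frac_de_b_per_timepoint * nB)
  de_b <- list()
  for (tp in timepoints) {
    forced <- shared$gene_b
    extra_n <- max(0, n_de_b - length(forced))
    pool <- setdiff(genes_b, forced)
    extra <- if (extra_n > 0) sample(pool, extra_n) else character(0)
    gene <- c(forced, extra)
    lfc <- numeric(length(gene))
    if (length(forced)) {
      mag <- draw_logfc(length(forced), config$logfc_range)
      sgn <- sign(lfc_a[shared$gene_a]) * ifelse(shared$concordant, 1, -1)
      lfc[seq_along(forced)] <- abs(mag) * sgn
    }
    if (extra_n > 0) {
      lfc[length(forced) + seq_len(extra_n)] <-
        draw_logfc(extra_n, config$logfc_range)
    }
    de_b[[tp]] <- data.frame(gene = gene, logfc = lfc,
                             stringsAsFactors = FALSE)
  }

  # counts, species A: condition effect on the second condition level in
  # sheet order, block effects multiplicative log-normal per (gene, block)
  sa <- config$samples_a
  sa$sample <- sprintf("A_s%02d", seq_len(nrow(sa)))
  cond_levels_a <- unique(sa$condition)
  effect_cond_a <- cond_levels_a[2]
  lfc_vec_a <- stats::setNames(numeric(nA), genes_a)
  lfc_vec_a[de_a] <- lfc_a
  blocks <- unique(sa$block)
  block_eff <- matrix(stats::rlnorm(nA * length(blocks), 0,
                                    config$block_sigma),
                      nA, length(blocks),
                      dimnames = list(genes_a, blocks))
  lib_a <- libsize_factors(nrow(sa), config$libsize_cv)
  mu_a <- matrix(0, nA, nrow(sa), dimnames = list(genes_a, sa$sample))
  for (j in seq_len(nrow(sa))) {
    fc <- if (sa$condition[j] == effect_cond_a) 2^lfc_vec_a else 1
    mu_a[, j] <- lib_a[j] * base_a * fc * block_eff[, sa$block[j]]
  }
  counts_a <- draw_nb(mu_a, config$dispersion_params)

  # counts, species B: control baseline; each timepoint's treatment
  # samples carry that timepoint's fold changes; no block structure
  sb <- config$samples_b
  sb$sample <- sprintf("B_s%02d", seq_len(nrow(sb)))
  lfc_mat_b <- matrix(0, nB, length(timepoints),
                      dimnames = list(genes_b, timepoints))
  for (tp in timepoints) lfc_mat_b[de_b[[tp]]$gene, tp] <- de_b[[tp]]$logfc
  lib_b <- libsize_factors(nrow(sb), config$libsize_cv)
  mu_b <- matrix(0, nB, nrow(sb), dimnames = list(genes_b, sb$sample))
  for (j in seq_len(nrow(sb))) {
    fc <- if (sb$condition[j] == "control") 1 else 2^lfc_mat_b[, sb$timepoint[j]]
    mu_b[, j] <- lib_b[j] * base_b * fc
  }
  counts_b <- draw_nb(mu_b, config$dispersion_params)

  hits <- make_hit_tables(pairs, genes_a, genes_b, config)

  pathways <- split(genes_a,
                    sprintf("pathway%02d",
                            sample.int(config$n_pathways, nA,
                                       replace = TRUE)))

  truth <- list(
    ortholog_pairs = pairs,
    de_genes_a = data.frame(gene = de_a, logfc = unname(lfc_a),
                            stringsAsFactors = FALSE),
    de_genes_b = de_b,
    shared_pairs = shared,
    low_genes_a = low_a, low_genes_b = low_b,
    effect_condition_a = effect_cond_a,
    timepoints = timepoints,
    mu_a = mu_a, mu_b = mu_b,
    libsize_factors_a = lib_a, libsize_factors_b = lib_b)

  list(counts_a = count_matrix(counts_a, sa[, c("sample", "condition",
                                                "block")]),
       counts_b = count_matrix(counts_b, sb[, c("sample", "condition",
                                                "timepoint")]),
       lengths_a = lengths_a, lengths_b = lengths_b,
       hits_a_to_b = hits$a_to_b, hits_b_to_a = hits$b_to_a,
       pathways = pathways, truth = truth, config = config)
}

draw_logfc <- function(n, range) {
  if (n == 0) return(numeric(0))
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

libsize_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

# NB draws with dispersion trend phi(mu) = phi0 + a/mu; Poisson when the
# dispersion vanishes.
draw_nb <- function(mu, dispersion_params) {
  phi0 <- dispersion_params[1]; a <- dispersion_params[2]
  mu_pos <- pmax(mu, 1e-12)
  phi <- phi0 + a / mu_pos
  out <- mu
  pois <- phi < 1e-12
  out[pois] <- stats::rpois(sum(pois), mu_pos[pois])
  out[!pois] <- stats::rnbinom(sum(!pois), mu = mu_pos[!pois],
                               size = 1 / phi[!pois])
  storage.mode(out) <- "integer"
  out
}

# Hit tables encoding the true map as mutual best hits. Decoy targets are
# always paired genes of the other species, whose own best hit remains
# their true partner, so decoys never create spurious reciprocal pairs.
make_hit_tables <- function(pairs, genes_a, genes_b, config) {
  S <- nrow(pairs)
  bs_ab <- stats::runif(S, 500, 1000)
  bs_ba <- stats::runif(S, 500, 1000)
  ev_ab <- 10^-stats::runif(S, 30, 180)
  ev_ba <- 10^-stats::runif(S, 30, 180)
  true_ab <- hit_rows(pairs$gene_a, pairs$gene_b, bs_ab, evalue = ev_ab)
  true_ba <- hit_rows(pairs$gene_b, pairs$gene_a, bs_ba, evalue = ev_ba)
  decoys_ab <- decoy_rows(genes_a, pairs$gene_a, pairs$gene_b, bs_ab, ev_ab,
                          config)
  decoys_ba <- decoy_rows(genes_b, pairs$gene_b, pairs$gene_a, bs_ba, ev_ba,
                          config)
  list(a_to_b = rbind(true_ab, decoys_ab),
       b_to_a = rbind(true_ba, decoys_ba))
}

hit_rows <- function(q, s, bitscore, pident = NULL, evalue = NULL) {
  n <- length(q)
  if (n == 0) return(empty_hits())
  if (is.null(pident)) pident <- round(stats::runif(n, 88, 100), 2)
  if (is.null(evalue)) evalue <- 10^-stats::runif(n, 30, 180)
  len <- round(stats::runif(n, 200, 800))
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = round(len * (1 - pident / 100)), gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = evalue, bitscore = round(bitscore, 1),
             stringsAsFactors = FALSE)
}

decoy_rows <- function(queries, paired_q, paired_s, true_bs, true_ev,
                       config) {
  n_decoy <- sample(0:config$decoy_max, length(queries), replace = TRUE)
  q <- rep(queries, n_decoy)
  if (!length(q)) return(empty_hits())
  true_bs_by_q <- stats::setNames(rep(NA_real_, length(queries)), queries)
  true_bs_by_q[paired_q] <- true_bs
  true_ev_by_q <- stats::setNames(rep(NA_real_, length(queries)), queries)
  true_ev_by_q[paired_q] <- true_ev
  partner_by_q <- stats::setNames(rep(NA_character_, length(queries)),
                                  queries)
  partner_by_q[paired_q] <- paired_s
  targ <- sample(paired_s, length(q), replace = TRUE)
  clash <- !is.na(partner_by_q[q]) & targ == partner_by_q[q]
  while (any(clash)) {
    targ[clash] <- sample(paired_s, sum(clash), replace = TRUE)
    clash <- !is.na(partner_by_q[q]) & targ == partner_by_q[q]
  }
  own <- true_bs_by_q[q]
  if (config$inject_ties) {
    # exact bitscore + e-value ties with the true hit; the lower percent
    # identity leaves the true pair winning only at the last tie-break
    bs <- ifelse(is.na(own), stats::runif(length(q), 50, 400), own)
    ev <- ifelse(is.na(own), 10^-stats::runif(length(q), 10, 25),
                 true_ev_by_q[q])
    pid <- round(stats::runif(length(q), 70, 85), 2)  # below true-range
    hit_rows(q, targ, bs, pident = pid, evalue = ev)
  } else {
    bs <- ifelse(is.na(own), stats::runif(length(q), 50, 400),
                 own * stats::runif(length(q), 0.3, 0.9))
    hit_rows(q, targ, bs)
  }
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Writes counts and sample sheets, gene lengths, both hit tables
#' (headerless 12-column TSV), a GMT built from the simulated pathway
#' labels, and the truth tables, plus a manifest of files with md5
#' checksums. Refuses a non-empty directory unless `overwrite = TRUE`.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory?
#' @return Data frame manifest: `file`, `md5`, `rows`.
#' @export
write_fixture_bundle <- function(dataset, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir,
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_count_matrix(dataset$counts_a, p("counts_a.tsv"), p("samples_a.tsv"))
  write_count_matrix(dataset$counts_b, p("counts_b.tsv"), p("samples_b.tsv"))
  write_lengths(dataset$lengths_a, p("lengths_a.tsv"))
  write_lengths(dataset$lengths_b, p("lengths_b.tsv"))
  write_hit_table(dataset$hits_a_to_b, p("hits_a_to_b.tsv"))
  write_hit_table(dataset$hits_b_to_a, p("hits_b_to_a.tsv"))
  write_gmt(dataset$pathways, p("genesets.gmt"))
  tr <- dataset$truth
  write_tsv(tr$ortholog_pairs, p("truth_ortholog_pairs.tsv"))
  write_tsv(tr$de_genes_a, p("truth_de_a.tsv"))
  de_b_long <- do.call(rbind, lapply(names(tr$de_genes_b), function(tp) {
    cbind(timepoint = tp, tr$de_genes_b[[tp]])
  }))
  write_tsv(de_b_long, p("truth_de_b.tsv"))
  write_tsv(tr$shared_pairs, p("truth_shared_pairs.tsv"))
  files <- c("counts_a.tsv", "samples_a.tsv", "counts_b.tsv",
             "samples_b.tsv", "lengths_a.tsv", "lengths_b.tsv",
             "hits_a_to_b.tsv", "hits_b_to_a.tsv", "genesets.gmt",
             "truth_ortholog_pairs.tsv", "truth_de_a.tsv", "truth_de_b.tsv",
             "truth_shared_pairs.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    rows = vapply(files, function(f) length(readLines(p(f))), 0L),
    stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  manifest
}

# Headerless 12-column writer (the conventional tabular alignment layout).
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a set-level overlap instance
#'
#' Lightweight companion to [simulate_dataset()] for calibration studies
#' of the permutation test alone: builds two universes, a one-to-one map
#' of `n_mapped` pairs, and DEG sets in which a fraction `rho_shared` of
#' the mapped focal DEGs have their partner forced into the reference DEG
#' set.
#'
#' @param n_universe_a,n_universe_b Universe sizes.
#' @param n_mapped Number of mapped ortholog pairs.
#' @param n_deg_a,n_deg_b DEG set sizes.
#' @param rho_shared Fraction of mapped focal DEGs whose partner is
#'   forced DE in the reference species.
#' @param seed Optional seed.
#' @return An [overlap_input()]; the number of forced pairs is in
#'   attribute `n_forced`.
#' @export
simulate_deg_sets <- function(n_universe_a, n_universe_b, n_mapped,
                              n_deg_a, n_deg_b, rho_shared = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_mapped <= min(n_universe_a, n_universe_b),
            n_deg_a <= n_universe_a, n_deg_b <= n_universe_b)
  uni_a <- sprintf("a%05d", seq_len(n_universe_a))
  uni_b <- sprintf("b%05d", seq_len(n_universe_b))
  map <- data.frame(gene_a = sample(uni_a, n_mapped),
                    gene_b = sample(uni_b, n_mapped),
                    stringsAsFactors = FALSE)
  deg_a <- sample(uni_a, n_deg_a)
  mapped_de <- map[map$gene_a %in% deg_a, , drop = FALSE]
  n_forced <- round(rho_shared * nrow(mapped_de))
  forced <- mapped_de$gene_b[sample.int(nrow(mapped_de), n_forced)]
  rest <- sample(setdiff(uni_b, forced), max(0, n_deg_b - n_forced))
  out <- overlap_input(uni_a, uni_b, deg_a, c(forced, rest), map)
  attr(out, "n_forced") <- n_forced
  out
}
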