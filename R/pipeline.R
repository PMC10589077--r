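# End-to-end driver: expression filter -> DE per contrast in both species
# -> RBH map -> overlap + permutation per reference-species contrast ->
# optional enrichment. All stage outputs are written as TSVs so every
# number in the summary is recomputable from files alone.

#' Declare a pipeline configuration
#'
#' @param counts_a,samples_a,counts_b,samples_b Paths to the two species'
#'   count TSVs and sample sheets (A is the focal species).
#' @param lengths_a,lengths_b Paths to effective-length TSVs.
#' @param hits_a_to_b,hits_b_to_a Paths to the two alignment hit tables.
#' @param out_dir Output directory.
#' @param gmt Optional path to a GMT collection for enrichment of the
#'   focal DEG list.
#' @param contrast_a List `(condition_a, condition_b, block)` declaring
#'   the focal contrast; `block` may be `NULL`.
#' @param control_b Condition label of the reference species' control
#'   samples (default `"control"`); every other timepoint level becomes a
#'   control-vs-timepoint contrast.
#' @param tpm_threshold,q_threshold,evalue_max,n_perm,seed Analysis
#'   parameters (defaults 1 TPM, q < 0.05, 1e-5, 1000 permutations).
#' @param orientation Length-2 vector of +-1 declaring the cross-species
#'   condition correspondence used for concordance labels.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_a, samples_a, counts_b, samples_b,
                            lengths_a, lengths_b, hits_a_to_b, hits_b_to_a,
                            out_dir, gmt = NULL,
                            contrast_a = list(condition_a = "omnivore",
                                              condition_b = "carnivore",
                                              block = "block"),
                            control_b = "control",
                            tpm_threshold = 1, q_threshold = 0.05,
                            evalue_max = 1e-5, n_perm = 1000, seed = 1,
                            orientation = c(1, 1)) {
  cfg <- list(counts_a = counts_a, samples_a = samples_a,
              counts_b = counts_b, samples_b = samples_b,
              lengths_a = lengths_a, lengths_b = lengths_b,
              hits_a_to_b = hits_a_to_b, hits_b_to_a = hits_b_to_a,
              out_dir = out_dir, gmt = gmt, contrast_a = contrast_a,
              control_b = control_b, tpm_threshold = tpm_threshold,
              q_threshold = q_threshold, evalue_max = evalue_max,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              orientation = orientation)
  if (tpm_threshold < 0) stop("tpm_threshold must be >= 0", call. = FALSE)
  if (q_threshold <= 0 || q_threshold > 1) {
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  for (f in c("counts_a", "samples_a", "counts_b", "samples_b",
              "lengths_a", "lengths_b", "hits_a_to_b", "hits_b_to_a")) {
    if (!file.exists(cfg[[f]])) {
      stop("input file for `", f, "` not found: ", cfg[[f]], call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full cross-species overlap pipeline
#'
#' Stages: TPM filter per species; TMM + NB-GLM/LRT differential
#' expression for the focal contrast and for every control-vs-timepoint
#' contrast of the reference species; RBH ortholog map; per-timepoint
#' overlap classification, permutation test and concordance table;
#' optional ORA of the focal DEG list. Writes all stage outputs plus a
#' machine-readable summary (one row per reference contrast with n_A,
#' n_B, N_A, N_B, M, observed overlap, expectation and empirical p) and a
#' run manifest into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary` (data frame), `manifest`
#'   (file checksums) and the per-stage objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  cm_a <- read_count_matrix(config$counts_a, config$samples_a)
  cm_b <- read_count_matrix(config$counts_b, config$samples_b)
  len_a <- read_lengths(config$lengths_a)
  len_b <- read_lengths(config$lengths_b)

  universe_a <- filter_low_expression(compute_tpm(cm_a, len_a),
                                      config$tpm_threshold)
  universe_b <- filter_low_expression(compute_tpm(cm_b, len_b),
                                      config$tpm_threshold)
  write_gene_list(universe_a, p("universe_a.txt"))
  write_gene_list(universe_b, p("universe_b.txt"))
  log_stage("quantfilter", "universe A %d/%d, universe B %d/%d genes",
            length(universe_a), nrow(cm_a$counts),
            length(universe_b), nrow(cm_b$counts))

  ca <- config$contrast_a
  contrast_a <- de_contrast(ca$condition_a, ca$condition_b,
                            block = ca$block)
  de_a <- fit_and_test(cm_a, contrast_a, universe = universe_a,
                       q_threshold = config$q_threshold)
  write_tsv(de_a, p("de_a.tsv"))
  deg_a <- deg_set(de_a, config$q_threshold)
  log_stage("detest", "species A: %d tested, %d DEGs at q < %g",
            sum(de_a$tested), length(deg_a), config$q_threshold)

  meta_b <- cm_b$samples
  tp_col <- if ("timepoint" %in% names(meta_b)) "timepoint" else "condition"
  timepoints <- setdiff(unique(meta_b[[tp_col]][meta_b$condition !=
                                                  config$control_b]), NA)
  de_b <- list()
  for (tp in timepoints) {
    keep <- meta_b$condition == config$control_b |
      (meta_b$condition != config$control_b & meta_b[[tp_col]] == tp)
    ctr <- de_contrast(config$control_b,
                       setdiff(unique(meta_b$condition[keep]),
                               config$control_b)[1],
                       samples = meta_b$sample[keep])
    de_b[[tp]] <- fit_and_test(cm_b, ctr, universe = universe_b,
                               q_threshold = config$q_threshold)
    write_tsv(de_b[[tp]], p(sprintf("de_b_%s.tsv", tp)))
    log_stage("detest", "species B %s: %d tested, %d DEGs", tp,
              sum(de_b[[tp]]$tested),
              length(deg_set(de_b[[tp]], config$q_threshold)))
  }

  hits_ab <- read_hit_table(config$hits_a_to_b, config$evalue_max)
  hits_ba <- read_hit_table(config$hits_b_to_a, config$evalue_max)
  map <- build_rbh_map(best_hits(hits_ab), best_hits(hits_ba))
  write_ortholog_pairs(map, p("ortholog_pairs.tsv"))
  log_stage("orthomap", "%d reciprocal best-hit pairs", nrow(map))

  summary_rows <- list()
  overlaps <- list()
  for (i in seq_along(timepoints)) {
    tp <- timepoints[i]
    deg_b_tp <- deg_set(de_b[[tp]], config$q_threshold)
    inp <- overlap_input(universe_a, universe_b, deg_a, deg_b_tp, map)
    cls <- classify_degs(inp, tested_b = de_b[[tp]]$gene[de_b[[tp]]$tested])
    perm <- permutation_test(inp, n_perm = config$n_perm,
                             seed = config$seed + i)
    shared_pairs <- inp$map[inp$map$gene_a %in% cls$class_shared, ,
                            drop = FALSE]
    conc <- concordance_table(
      shared_pairs, de_a, de_b[[tp]],
      labels_a = c(ca$condition_a, ca$condition_b),
      labels_b = c(config$control_b, tp),
      orientation = config$orientation)
    write_tsv(conc, p(sprintf("concordance_%s.tsv", tp)))
    write_tsv(permutation_histogram(perm$perm_overlaps),
              p(sprintf("perm_hist_%s.tsv", tp)))
    overlaps[[tp]] <- list(input = inp, classes = cls, permutation = perm,
                           concordance = conc)
    summary_rows[[tp]] <- data.frame(
      contrast = tp,
      n_A = length(inp$deg_a), n_B = length(inp$deg_b),
      N_A = length(inp$universe_a), N_B = length(inp$universe_b),
      M = nrow(inp$map), k = perm$observed,
      shared = cls$class_counts[["shared"]],
      not_sig = cls$class_counts[["not_sig"]],
      unaligned = cls$class_counts[["unaligned"]],
      untested = cls$class_counts[["untested"]],
      expected_overlap = perm$expected$mean,
      p_empirical = perm$p_empirical,
      p_add_one = perm$p_add_one,
      n_perm = config$n_perm, seed = config$seed + i,
      stringsAsFactors = FALSE)
    log_stage("overlap", "%s: k=%d expected=%.2f p=%.3f", tp,
              perm$observed, perm$expected$mean, perm$p_empirical)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  write_tsv(summary, p("overlap_summary.tsv"))

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    coll <- read_gmt(config$gmt, background = universe_a)
    enrichment <- ora_test(deg_a, coll, background = universe_a)
    write_tsv(enrichment, p("enrichment_a.tsv"))
    log_stage("enrich", "%d sets tested", nrow(enrichment))
  }

  outputs <- list.files(config$out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.tsv")
  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(config$out_dir, outputs))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))

  invisible(list(summary = summary, manifest = manifest,
                 universe_a = universe_a, universe_b = universe_b,
                 de_a = de_a, de_b = de_b, map = map, overlaps = overlaps,
                 enrichment = enrichment, config = config))
}

# md5 of the packaged shared-DEG table; guards transcription integrity
TABLE4_MD5 <- "b11b689af5c29f81780b325f52d2aa02"

#' Load the packaged shared-DEG reference table
#'
#' A transcription of the published table of differentially expressed
#' genes shared between the focal species' resource polyphenism and the
#' reference species' developmental acceleration: one row per (gene,
#' treatment timepoint) with both species' log2 fold changes and
#' p-values, the higher-expression side in each species, and a flag for
#' genes appearing in more than one treatment. An md5 checksum guards the
#' packaged file against accidental edits.
#'
#' @return Data frame with 53 rows and columns `gene_id`, `gene_name`,
#'   `pc_treatment`, `pc_logfc`, `pc_p`, `sm_logfc`, `sm_p`, `pc_higher`,
#'   `sm_higher`, `multi_treatment`.
#' @export
load_table4_fixture <- function() {
  path <- system.file("extdata", "table4_shared_degs.tsv",
                      package = "crossdeg", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE4_MD5)) {
    stop("checksum mismatch on packaged shared-DEG table: ", md5,
         call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}
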