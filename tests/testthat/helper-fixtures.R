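# Shared builders for small in-memory fixtures.

tiny_cm <- function(counts, conditions, blocks = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  meta <- data.frame(sample = colnames(counts), condition = conditions,
                     stringsAsFactors = FALSE)
  if (!is.null(blocks)) meta$block <- blocks
  count_matrix(counts, meta)
}

# random NB count matrix with a 3+3 two-condition design
random_cm <- function(n_genes, seed = 1, mu_log = 4, phi = 0.2,
                      n_per_cond = 3) {
  set.seed(seed)
  mu <- rlnorm(n_genes, mu_log, 1)
  m <- matrix(rnbinom(n_genes * 2 * n_per_cond, mu = mu, size = 1 / phi),
              n_genes, 2 * n_per_cond)
  tiny_cm(m, rep(c("ctl", "trt"), each = n_per_cond))
}

# hit table from a compact spec (q, s, bitscore, optional pident/evalue);
# remaining 12-column fields filled with valid values
make_hits <- function(df) {
  data.frame(qseqid = df$q, sseqid = df$s,
             pident = if (!is.null(df$pident)) df$pident else 95,
             length = 300, mismatch = 10, gapopen = 0,
             qstart = 1, qend = 300, sstart = 1, send = 300,
             evalue = if (!is.null(df$evalue)) df$evalue else 1e-50,
             bitscore = df$bitscore, stringsAsFactors = FALSE)
}

write_hits_fixture <- function(df, path) {
  utils::write.table(make_hits(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# exact distribution of the mapped-pair overlap under the permutation
# scheme, by exhaustive enumeration of both species' draws
enum_overlap_dist <- function(input) {
  N_a <- length(input$universe_a); N_b <- length(input$universe_b)
  n_a <- length(input$deg_a); n_b <- length(input$deg_b)
  ia <- match(input$map$gene_a, input$universe_a)
  ib <- match(input$map$gene_b, input$universe_b)
  draws_a <- utils::combn(N_a, n_a)
  draws_b <- utils::combn(N_b, n_b)
  counts <- integer(0)
  for (i in seq_len(ncol(draws_a))) {
    in_a <- ia %in% draws_a[, i]
    for (j in seq_len(ncol(draws_b))) {
      counts <- c(counts, sum(in_a & ib %in% draws_b[, j]))
    }
  }
  counts
}

random_overlap_instance <- function(seed, max_n = 12) {
  set.seed(seed)
  N_a <- sample(4:max_n, 1); N_b <- sample(4:max_n, 1)
  M <- sample(1:min(N_a, N_b), 1)
  n_a <- sample(1:N_a, 1); n_b <- sample(1:N_b, 1)
  simulate_deg_sets(N_a, N_b, M, n_a, n_b, rho_shared = 0)
}
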