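test_that("configuration errors name the offending field", {
  expect_error(sim_config(frac_de_a = 1.2), "frac_de_a")
  expect_error(sim_config(rho_shared = -0.1), "rho_shared")
  expect_error(sim_config(n_genes_a = 5), "n_genes")
  expect_error(sim_config(logfc_range = c(0, 2)), "logfc_range")
  expect_error(sim_config(logfc_range = c(3, 1)), "logfc_range")
  expect_error(sim_config(samples_a = data.frame(condition = "x",
                                                 block = "b")), "samples_a")
  expect_error(sim_config(samples_b = data.frame(condition = "control",
                                                 timepoint = "t")),
               "samples_b")
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- sim_config(n_genes_a = 120, n_genes_b = 120, seed = 51)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts_a$counts, d2$counts_a$counts)
  expect_identical(d1$hits_a_to_b, d2$hits_a_to_b)
  expect_identical(d1$truth$de_genes_a, d2$truth$de_genes_a)

  d3 <- simulate_dataset(sim_config(n_genes_a = 120, n_genes_b = 120,
                                    seed = 52))
  expect_false(identical(d1$counts_a$counts, d3$counts_a$counts))
  expect_identical(dim(d1$counts_a$counts), dim(d3$counts_a$counts))
})

test_that("a null configuration carries no true DE anywhere", {
  ds <- simulate_dataset(sim_config(n_genes_a = 100, n_genes_b = 100,
                                    frac_de_a = 0,
                                    frac_de_b_per_timepoint = 0,
                                    seed = 53))
  expect_equal(nrow(ds$truth$de_genes_a), 0)
  expect_true(all(vapply(ds$truth$de_genes_b, nrow, 1L) == 0))
  expect_equal(nrow(ds$truth$shared_pairs), 0)
})

test_that("full sharing forces the exact shared-pair count", {
  cfg <- sim_config(n_genes_a = 200, n_genes_b = 200, frac_de_a = 0.2,
                    frac_de_b_per_timepoint = 0.2, rho_shared = 1,
                    seed = 54)
  ds <- simulate_dataset(cfg)
  S <- nrow(ds$truth$ortholog_pairs)
  expect_equal(nrow(ds$truth$shared_pairs), round(0.2 * S))
  # every shared pair's members are DE in the respective species
  expect_true(all(ds$truth$shared_pairs$gene_a %in%
                    ds$truth$de_genes_a$gene))
  for (tp in ds$truth$timepoints) {
    expect_true(all(ds$truth$shared_pairs$gene_b %in%
                      ds$truth$de_genes_b[[tp]]$gene))
  }
})

test_that("the ortholog catalog honours the shared fraction", {
  # with catalogs of 500 and 400 genes the shared fraction caps at 0.8
  for (frac in c(0.3, 0.562, 0.75)) {
    ds <- simulate_dataset(sim_config(n_genes_a = 500, n_genes_b = 400,
                                      frac_shared_orthologs = frac,
                                      seed = 55))
    S <- nrow(ds$truth$ortholog_pairs)
    union_size <- 500 + 400 - S
    expect_equal(S / union_size, frac, tolerance = 0.01)
    expect_equal(anyDuplicated(ds$truth$ortholog_pairs$gene_a), 0)
    expect_equal(anyDuplicated(ds$truth$ortholog_pairs$gene_b), 0)
  }
})

test_that("simulated counts match the configured NB moments", {
  samples_a <- data.frame(condition = rep(c("omnivore", "carnivore"),
                                          each = 110), block = "b1")
  cfg <- sim_config(n_genes_a = 250, n_genes_b = 20, samples_a = samples_a,
                    frac_de_a = 0, frac_low_expression = 0, libsize_cv = 0,
                    block_sigma = 0, seed = 56)
  ds <- simulate_dataset(cfg)
  m <- ds$counts_a$counts
  mu <- ds$truth$mu_a[, 1]  # constant across samples in this design
  phi <- 0.16 + 0.5 / mu
  n <- ncol(m)
  se <- sqrt((mu + phi * mu^2) / n)
  within3 <- abs(rowMeans(m) - mu) <= 3 * se
  expect_gte(mean(within3), 0.98)
  # overdispersion: empirical variance exceeds the mean for phi > 0
  v <- apply(m, 1, var)
  expect_gte(mean(v > rowMeans(m)), 0.95)
})

test_that("fixture bundles round-trip and refuse silent overwrites", {
  ds <- simulate_dataset(sim_config(n_genes_a = 80, n_genes_b = 80,
                                    rho_shared = 0.5, frac_de_a = 0.2,
                                    frac_de_b_per_timepoint = 0.1,
                                    seed = 57))
  dir1 <- withr::local_tempdir()
  manifest <- write_fixture_bundle(ds, dir1, overwrite = TRUE)
  expect_gte(nrow(manifest), 8)
  expect_true(all(file.exists(file.path(dir1, manifest$file))))

  back <- read_count_matrix(file.path(dir1, "counts_a.tsv"),
                            file.path(dir1, "samples_a.tsv"))
  expect_identical(back$counts, ds$counts_a$counts)
  hits <- read_hit_table(file.path(dir1, "hits_a_to_b.tsv"))
  expect_equal(nrow(hits), nrow(ds$hits_a_to_b))
  lens <- read_lengths(file.path(dir1, "lengths_a.tsv"))
  expect_identical(lens, ds$lengths_a)
  gmt <- read_gmt(file.path(dir1, "genesets.gmt"))
  expect_setequal(unlist(gmt$sets), rownames(ds$counts_a$counts))

  expect_error(write_fixture_bundle(ds, dir1), "not empty")

  # same seed, fresh directory: identical checksums
  dir2 <- withr::local_tempdir()
  ds2 <- simulate_dataset(sim_config(n_genes_a = 80, n_genes_b = 80,
                                     rho_shared = 0.5, frac_de_a = 0.2,
                                     frac_de_b_per_timepoint = 0.1,
                                     seed = 57))
  manifest2 <- write_fixture_bundle(ds2, dir2, overwrite = TRUE)
  expect_identical(manifest$md5, manifest2$md5)
})

test_that("set-level instances force the requested sharing", {
  inp0 <- simulate_deg_sets(500, 500, 200, 50, 50, rho_shared = 0, seed = 58)
  expect_equal(attr(inp0, "n_forced"), 0)
  inp1 <- simulate_deg_sets(500, 500, 200, 50, 50, rho_shared = 1, seed = 58)
  mapped_de <- sum(inp1$map$gene_a %in% inp1$deg_a)
  expect_equal(attr(inp1, "n_forced"), mapped_de)
  expect_gte(overlap_count(inp1$deg_a, inp1$deg_b, inp1$map), mapped_de)
})
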