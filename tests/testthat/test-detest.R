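test_that("TMM factors are 1 under symmetry and have geometric mean 1", {
  m <- matrix(rep(c(5L, 20L, 100L, 7L), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(tmm_factors(m)), rep(1, 3))

  m2 <- cbind(s1 = c(5L, 20L, 100L, 7L), s2 = c(10L, 40L, 200L, 14L))
  rownames(m2) <- paste0("g", 1:4)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))  # pure depth difference

  cm <- random_cm(300, seed = 5)
  f <- tmm_factors(cm)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM factors agree with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(6)
  cm <- random_cm(400, seed = 6)
  m <- cm$counts
  m[, 1] <- m[, 1] + rpois(400, 40) * rbinom(400, 1, 0.1)  # composition shift
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(tmm_factors(m)), unname(ref), tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  out <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.5), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimation recovers Poisson and phi = 0.4 truth", {
  samples_a <- data.frame(condition = rep(c("omnivore", "carnivore"), each = 3),
                          block = "b1")
  base <- list(n_genes_a = 2000, n_genes_b = 20, samples_a = samples_a,
               frac_de_a = 0, frac_low_expression = 0, libsize_cv = 0,
               block_sigma = 0)
  ct <- de_contrast("omnivore", "carnivore")

  ds0 <- simulate_dataset(do.call(sim_config, c(base, list(
    dispersion_params = c(0, 0), seed = 31))))
  d0 <- estimate_dispersions(ds0$counts_a, ct)
  expect_lte(median(d0), 0.05)

  ds4 <- simulate_dataset(do.call(sim_config, c(base, list(
    dispersion_params = c(0.4, 0), seed = 32))))
  d4 <- estimate_dispersions(ds4$counts_a, ct)
  expect_gte(median(d4), 0.2)
  expect_lte(median(d4), 0.6)

  # infinite prior collapses every gene onto the common value
  dinf <- estimate_dispersions(ds4$counts_a, ct, prior_df = 1e12)
  expect_equal(as.vector(dinf), rep(attr(dinf, "common"), length(dinf)),
               tolerance = 1e-6)
})

test_that("a gene with identical counts everywhere is a perfect null", {
  m <- matrix(rep(c(12L, 40L, 7L, 90L, 25L), 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  cm <- tiny_cm(m, rep(c("ctl", "trt"), each = 3))
  de <- fit_and_test(cm, de_contrast("ctl", "trt"),
                     dispersions = setNames(rep(0.1, 5), rownames(m)))
  expect_equal(de$logFC, rep(0, 5), tolerance = 1e-8)
  expect_true(all(de$p_value >= 0.99))
  expect_true(all(de$direction == "none"))
})

test_that("relabeling the conditions flips logFC and preserves p-values", {
  cm <- random_cm(200, seed = 7)
  fwd <- fit_and_test(cm, de_contrast("ctl", "trt"))
  rev <- fit_and_test(cm, de_contrast("trt", "ctl"))
  expect_equal(fwd$logFC, -rev$logFC, tolerance = 1e-6)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-8)
})

test_that("a constant per-block multiplier does not change calls", {
  samples_a <- data.frame(condition = rep(c("omnivore", "carnivore"), 4),
                          block = rep(c("f1", "f2"), each = 4))
  ds <- simulate_dataset(sim_config(n_genes_a = 1000, n_genes_b = 20,
                                    samples_a = samples_a, frac_de_a = 0.2,
                                    frac_low_expression = 0, seed = 41))
  ct <- de_contrast("omnivore", "carnivore", block = "block")
  de1 <- fit_and_test(ds$counts_a, ct)
  bumped <- ds$counts_a$counts
  f2 <- ds$counts_a$samples$block == "f2"
  bumped[, f2] <- round(bumped[, f2] * 1.4)
  cm2 <- count_matrix(bumped, ds$counts_a$samples)
  de2 <- fit_and_test(cm2, ct)
  call1 <- de1$gene %in% deg_set(de1)
  call2 <- de2$gene %in% deg_set(de2)
  expect_gte(mean(call1 == call2), 0.99)
})

test_that("DEG counts increase weakly with simulated effect size", {
  samples_a <- data.frame(condition = rep(c("omnivore", "carnivore"), each = 3),
                          block = "b1")
  n_deg <- sapply(c(1, 2.5), function(fc) {
    ds <- simulate_dataset(sim_config(n_genes_a = 800, n_genes_b = 20,
                                      samples_a = samples_a, frac_de_a = 0.2,
                                      logfc_range = c(fc, fc),
                                      frac_low_expression = 0, seed = 42))
    length(deg_set(fit_and_test(ds$counts_a, de_contrast("omnivore",
                                                         "carnivore"))))
  })
  expect_lte(n_deg[1], n_deg[2])
})

test_that("logFC estimates track the reference NB-GLM implementation", {
  skip_if_not_installed("edgeR")
  samples_a <- data.frame(condition = rep(c("omnivore", "carnivore"), each = 3),
                          block = "b1")
  ds <- simulate_dataset(sim_config(n_genes_a = 500, n_genes_b = 20,
                                    samples_a = samples_a, frac_de_a = 0.3,
                                    frac_low_expression = 0, seed = 43))
  de <- fit_and_test(ds$counts_a, de_contrast("omnivore", "carnivore"))
  y <- edgeR::DGEList(ds$counts_a$counts)
  y <- edgeR::calcNormFactors(y)
  design <- model.matrix(~factor(ds$counts_a$samples$condition,
                                 levels = c("omnivore", "carnivore")))
  y <- edgeR::estimateDisp(y, design)
  lrt <- edgeR::glmLRT(edgeR::glmFit(y, design))
  ref <- lrt$table[de$gene, ]
  ok <- de$tested
  expect_gte(cor(de$logFC[ok], ref$logFC[ok]), 0.98)
  expect_gte(cor(log10(de$p_value[ok] + 1e-300),
                 log10(ref$PValue[ok] + 1e-300)), 0.9)
})

test_that("genes outside the universe or with no counts are not tested", {
  m <- matrix(c(0L, 0L, 0L, 0L, 0L, 0L,
                5L, 9L, 4L, 6L, 8L, 7L,
                50L, 40L, 60L, 45L, 55L, 52L), 3, 6, byrow = TRUE,
              dimnames = list(c("dead", "live1", "live2"), paste0("s", 1:6)))
  cm <- tiny_cm(m, rep(c("ctl", "trt"), each = 3))
  de <- fit_and_test(cm, de_contrast("ctl", "trt"), universe = c("dead", "live2"))
  expect_false(de$tested[de$gene == "dead"])
  expect_false(de$tested[de$gene == "live1"])  # outside universe
  expect_true(de$tested[de$gene == "live2"])
  expect_true(is.na(de$p_value[de$gene == "dead"]))
})
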