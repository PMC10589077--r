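test_that("overlap count matches a nested-loop oracle", {
  set.seed(23)
  for (rep in 1:50) {
    inp <- random_overlap_instance(seed = 1000 + rep)
    brute <- 0
    for (i in seq_len(nrow(inp$map))) {
      for (a in inp$deg_a) for (b in inp$deg_b) {
        if (inp$map$gene_a[i] == a && inp$map$gene_b[i] == b) {
          brute <- brute + 1
        }
      }
    }
    expect_identical(overlap_count(inp$deg_a, inp$deg_b, inp$map),
                     as.integer(brute))
  }
})

test_that("DEG classification covers the boundary cases", {
  uni_a <- paste0("a", 1:6); uni_b <- paste0("b", 1:6)
  # empty map: every focal DEG is unaligned
  inp <- overlap_input(uni_a, uni_b, uni_a[1:3], uni_b[1:2],
                       data.frame(gene_a = character(0),
                                  gene_b = character(0)))
  cls <- classify_degs(inp, tested_b = uni_b)
  expect_equal(cls$class_counts[["unaligned"]], 3)
  expect_equal(cls$k, 0)

  # all mapped reference genes DE and tested: every mapped focal DEG shared
  map <- data.frame(gene_a = uni_a[1:4], gene_b = uni_b[1:4])
  inp2 <- overlap_input(uni_a, uni_b, uni_a[1:3], uni_b[1:4], map)
  cls2 <- classify_degs(inp2, tested_b = uni_b)
  expect_equal(cls2$class_counts[["shared"]], 3)
  expect_equal(cls2$class_counts[["unaligned"]], 0)

  # untested orthologs fall in their own class
  inp3 <- overlap_input(uni_a, uni_b, uni_a[1:4], character(0), map)
  cls3 <- classify_degs(inp3, tested_b = uni_b[1:2])
  expect_equal(cls3$class_counts[["not_sig"]], 2)
  expect_equal(cls3$class_counts[["untested"]], 2)

  expect_error(overlap_input(uni_a, uni_b, c("zz"), character(0), map),
               "outside universe_a")
})

test_that("classification partitions the focal DEG set on random inputs", {
  set.seed(29)
  for (rep in 1:100) {
    inp <- random_overlap_instance(seed = 2000 + rep)
    tested_b <- sample(inp$universe_b,
                       sample(0:length(inp$universe_b), 1))
    tested_b <- union(tested_b, inp$deg_b)
    cls <- classify_degs(inp, tested_b)
    expect_equal(sum(cls$class_counts), length(inp$deg_a))
    all_ids <- c(cls$class_shared, cls$class_not_sig, cls$class_unaligned,
                 cls$class_untested)
    expect_equal(anyDuplicated(all_ids), 0)
    expect_setequal(all_ids, inp$deg_a)
  }
})

test_that("permutation test handles saturated and empty draws", {
  uni_a <- paste0("a", 1:5); uni_b <- paste0("b", 1:5)
  map <- data.frame(gene_a = uni_a[1:4], gene_b = uni_b[1:4])
  sat <- permutation_test(overlap_input(uni_a, uni_b, uni_a, uni_b, map),
                          n_perm = 50, seed = 1)
  expect_true(all(sat$perm_overlaps == 4))
  expect_equal(sat$p_empirical, 1)

  none <- permutation_test(overlap_input(uni_a, uni_b, character(0),
                                         uni_b[1:2], map),
                           n_perm = 50, seed = 1)
  expect_true(all(none$perm_overlaps == 0))
  expect_equal(none$observed, 0)
  expect_equal(none$p_empirical, 1)

  inp <- overlap_input(uni_a, uni_b, uni_a[1:2], uni_b[1:2], map)
  expect_error(permutation_test(inp, n_perm = 0), "n_perm")
})

test_that("identical seeds give identical permutation vectors", {
  inp <- simulate_deg_sets(200, 150, 80, 30, 25, rho_shared = 0.2, seed = 3)
  p1 <- permutation_test(inp, n_perm = 300, seed = 99)
  p2 <- permutation_test(inp, n_perm = 300, seed = 99)
  p3 <- permutation_test(inp, n_perm = 300, seed = 100)
  expect_identical(p1$perm_overlaps, p2$perm_overlaps)
  expect_false(identical(p1$perm_overlaps, p3$perm_overlaps))
})

test_that("closed-form mean and variance match exhaustive enumeration", {
  for (rep in 1:25) {
    inp <- random_overlap_instance(seed = 3000 + rep, max_n = 9)
    enum <- enum_overlap_dist(inp)
    eo <- expected_overlap(inp)
    expect_equal(eo$mean, mean(enum), tolerance = 1e-9)
    expect_equal(eo$variance, mean(enum^2) - mean(enum)^2, tolerance = 1e-9)
  }
  # degenerate corners
  uni <- paste0("g", 1:4)
  map <- data.frame(gene_a = uni, gene_b = uni)
  full <- expected_overlap(overlap_input(uni, uni, uni, uni, map))
  expect_equal(full$mean, 4); expect_equal(full$variance, 0)
  nomap <- expected_overlap(overlap_input(uni, uni, uni[1], uni[1],
                                          map[0, ]))
  expect_equal(nomap$mean, 0); expect_equal(nomap$variance, 0)
})

test_that("permutation means sit within 4 SE of the closed form", {
  set.seed(31)
  for (rep in 1:5) {
    inp <- simulate_deg_sets(sample(50:150, 1), sample(50:150, 1),
                             sample(20:50, 1), sample(5:20, 1),
                             sample(5:20, 1), rho_shared = 0)
    pt <- permutation_test(inp, n_perm = 10000, seed = 4000 + rep)
    eo <- expected_overlap(inp)
    se <- sqrt(eo$variance / pt$n_perm)
    expect_lt(abs(mean(pt$perm_overlaps) - eo$mean), 4 * se + 1e-9)
  }
})

test_that("empirical p-values are not anti-conservative under the null", {
  set.seed(37)
  hits <- 0; n_rep <- 500
  for (rep in seq_len(n_rep)) {
    inp <- simulate_deg_sets(300, 300, 150, 40, 40, rho_shared = 0)
    pt <- permutation_test(inp, n_perm = 200)
    if (pt$p_empirical <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.08)
})

test_that("concordance follows the declared correspondence", {
  de_a <- data.frame(gene = c("a1", "a2", "a3"),
                     logFC = c(1.2, -0.8, NA), p_value = c(0.01, 0.02, NA))
  de_b <- data.frame(gene = c("b1", "b2", "b3"),
                     logFC = c(0.5, 0.9, 1.1), p_value = c(0.03, 0.01, 0.2))
  pairs <- data.frame(gene_a = c("a1", "a2", "a3"),
                      gene_b = c("b1", "b2", "b3"))
  ct <- concordance_table(pairs, de_a, de_b,
                          labels_a = c("omnivore", "carnivore"),
                          labels_b = c("control", "t48"))
  expect_equal(ct$concordant[1:2], c(TRUE, FALSE))
  expect_true(ct$incomplete[3] && is.na(ct$concordant[3]))
  expect_equal(ct$higher_a[1:2], c("carnivore", "omnivore"))
  expect_equal(ct$higher_b[1:2], c("t48", "t48"))
  # flipping one side's orientation flips every complete flag
  ct2 <- concordance_table(pairs, de_a, de_b, orientation = c(1, -1))
  expect_equal(ct2$concordant[1:2], !ct$concordant[1:2])
})

test_that("permutation histogram is a complete frequency table", {
  h <- permutation_histogram(c(2L, 2L, 4L, 5L, 2L))
  expect_equal(h$overlap, 2:5)
  expect_equal(h$frequency, c(3L, 0L, 1L, 1L))
  expect_equal(sum(h$frequency), 5)
})
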