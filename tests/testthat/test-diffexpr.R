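test_that("low-expression filter matches hand-computed CPMs", {
  counts <- rbind(
    g1 = c(0, 0, 0, 0, 0),        # removed: all zero
    g2 = c(1, 1, 1, 1, 0),        # CPM 1000 in 4 samples: kept
    g3 = c(5, 0, 0, 0, 0),        # high in 1 sample only: removed
    g4 = c(2, 2, 2, 2, 2),        # kept everywhere
    g5 = c(993, 998, 998, 994, 999))  # padding so libraries ~1000
  cm <- toy_count_matrix(counts,
                         population = rep(c("coastal", "inland"),
                                          c(3, 2)),
                         state = rep("nonmigratory", 5))
  kept <- filter_low_expression(cm, cpm_threshold = 1, min_samples = 4)
  expect_identical(rownames(kept$counts), c("g2", "g4", "g5"))
})

test_that("CPM boundary is inclusive at exactly the threshold", {
  # library sizes exactly 1e6; gene at exactly 1 CPM in 4 samples stays
  counts <- rbind(g1 = c(1, 1, 1, 1, 0),
                  g2 = c(999999, 999999, 999999, 999999, 1000000))
  cm <- toy_count_matrix(counts, population = rep("coastal", 5),
                         state = rep("migratory", 5))
  kept <- filter_low_expression(cm)
  expect_true("g1" %in% rownames(kept$counts))
})

test_that("size factors are exact for proportional samples", {
  counts <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(counts) <- c("a", "b", "c")
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(s1 = c(5, 9), s2 = c(5, 9), s3 = c(5, 9))
  rownames(same) <- c("a", "b")
  expect_equal(unname(estimate_size_factors(same)), c(1, 1, 1))
})

test_that("size factors equal the brute-force median-of-ratios", {
  set.seed(81)
  # odd gene count so the median is an order statistic, not interpolated
  counts <- matrix(rnbinom(51 * 6, mu = 60, size = 5) + 1, 51, 6,
                   dimnames = list(sprintf("g%02d", 1:51),
                                   sprintf("s%d", 1:6)))
  sf <- estimate_size_factors(counts)
  # independent recomputation, ratio by ratio
  geo <- apply(counts, 1, function(x) prod(x)^(1 / length(x)))
  ratios <- sweep(counts, 1, geo, "/")
  expect_equal(unname(sf), unname(apply(ratios, 2, median)),
               tolerance = 1e-10)
})

test_that("size factors agree with DESeq2 on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(82)
  counts <- matrix(rnbinom(80 * 8, mu = 40, size = 3) + 1, 80, 8,
                   dimnames = list(sprintf("g%02d", 1:80),
                                   sprintf("s%d", 1:8)))
  sf <- estimate_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("size factors scale with a rescaled sample", {
  set.seed(83)
  counts <- matrix(rnbinom(60 * 5, mu = 50, size = 4) + 1, 60, 5,
                   dimnames = list(sprintf("g%02d", 1:60),
                                   sprintf("s%d", 1:5)))
  sf <- estimate_size_factors(counts)
  k <- 3
  counts2 <- counts
  counts2[, 2] <- counts[, 2] * k
  sf2 <- estimate_size_factors(counts2)
  # sample 2's factor picks up k (up to the geometric-mean term k^(1/n))
  expect_equal(unname(sf2[2] / sf[2] * k^(1 / 5)), k, tolerance = 1e-8)
})

test_that("a flat gene has zero fold change in every contrast", {
  set.seed(84)
  counts <- rbind(flat = rep(7, 18),
                  other = rnbinom(18, mu = 100, size = 10) + 1)
  cm <- toy_count_matrix(
    counts,
    population = rep(rep(c("coastal", "inland"), each = 9), 1),
    state = rep(rep(c("nonmigratory", "migratory"), c(4, 5)), 2))
  de <- fit_de(cm, sf = setNames(rep(1, 18), cm$samples$sample))
  flat <- de[de$gene_id == "flat", ]
  expect_true(all(flat$log2fc == 0))
  expect_true(all(flat$pvalue == 1))
})

test_that("subspecies fold change recovers the simulated cis+trans effect", {
  arch <- simulate_regulatory_architectures(
    600, proportions = c(cis_trans = 0.25, conserved = 0.75),
    effect_size = 1, seed = 55)  # cis 1 + trans 1 = log2FC 2
  sim <- simulate_expression_counts(arch, sim_design(depth = 1e6,
                                                     seed = 55))
  cm <- filter_low_expression(sim$cm)
  de <- fit_de(cm, contrasts = "subspecies")
  m <- merge(de, arch[, c("gene_id", "category")], by = "gene_id")
  est <- mean(m$log2fc[m$category == "cis_trans"])
  expect_equal(est, 2, tolerance = 0.2)
})

test_that("BH adjustment matches hand computation and the step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))

  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  # NA p-values stay NA and shrink the denominator
  p <- c(0.01, NA, 0.04)
  q <- adjust_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_stepup_oracle(c(0.01, 0.04)))
})

test_that("gene effect classes follow the significance flags", {
  mk <- function(sig) data.frame(
    gene_id = "g1", contrast = c("state", "subspecies", "interaction"),
    sig = sig, stringsAsFactors = FALSE)
  expect_identical(classify_gene_effects(mk(c(TRUE, FALSE, FALSE)))$category,
                   "E")
  expect_identical(classify_gene_effects(mk(c(FALSE, FALSE, TRUE)))$category,
                   "GxE")
  expect_identical(classify_gene_effects(mk(c(FALSE, FALSE, FALSE)))$category,
                   "none")
  expect_identical(classify_gene_effects(mk(c(TRUE, TRUE, TRUE)))$category,
                   "G+E+GxE")
})
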