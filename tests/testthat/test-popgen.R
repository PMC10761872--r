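gm_from <- function(g1, g2, pos = NULL, contig = "chr1") {
  gt <- cbind(g1, g2)
  colnames(gt) <- c(sprintf("a_%d", seq_len(ncol(g1))),
                    sprintf("b_%d", seq_len(ncol(g2))))
  genotype_matrix(gt, pos = pos %||% seq_len(nrow(gt)), contig = contig,
                  pop = rep(c("popA", "popB"),
                            c(ncol(g1), ncol(g2))))
}

test_that("single-site statistics match direct pair counting", {
  # allele copies A,A,T,T in one population: pi = 4/6
  gm <- gm_from(matrix(c(0L, 2L), 1), matrix(c(0L, 0L), 1))
  st <- interval_popgen_stats(gm, data.frame(contig = "chr1", start = 0,
                                             end = 1))
  expect_equal(st$pi_popA, 4 / 6)
  expect_equal(st$pi_popB, 0)

  # fixed difference: dxy = 1, Hudson FST = 1
  gm2 <- gm_from(matrix(c(0L, 0L), 1), matrix(c(2L, 2L), 1))
  st2 <- interval_popgen_stats(gm2, data.frame(contig = "chr1",
                                               start = 0, end = 1))
  expect_equal(st2$dxy, 1)
  expect_equal(st2$fst, 1)
})

test_that("interval pi and dxy equal the all-pairs brute force", {
  set.seed(91)
  for (rep in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    n_sites <- sample(30:120, 1)
    gm <- simulate_genotypes(runif(1, 0, 0.4), n1 = n1, n2 = n2,
                             n_sites = n_sites,
                             missing_rate = runif(1, 0, 0.3),
                             seed = 1000 + rep)
    iv <- data.frame(contig = "chr1", start = 0, end = n_sites)
    st <- interval_popgen_stats(gm, iv)
    b <- brute_pi_dxy(gm$gt[, gm$pop == "coastal", drop = FALSE],
                      gm$gt[, gm$pop == "inland", drop = FALSE])
    expect_equal(st$pi_coastal, unname(b["pi1"]), tolerance = 1e-12)
    expect_equal(st$pi_inland, unname(b["pi2"]), tolerance = 1e-12)
    expect_equal(st$dxy, unname(b["dxy"]), tolerance = 1e-12)
  }
})

test_that("removing one individual's call changes only comparison counts", {
  gm <- simulate_genotypes(0.2, n1 = 5, n2 = 5, n_sites = 40, seed = 92)
  iv <- data.frame(contig = "chr1", start = 0, end = 40)
  before <- interval_popgen_stats(gm, iv)
  gm2 <- gm
  gm2$gt[10, 1] <- NA
  after <- interval_popgen_stats(gm2, iv)
  expect_lt(after$n_comparisons, before$n_comparisons)
  # brute force still agrees after the deletion
  b <- brute_pi_dxy(gm2$gt[, gm2$pop == "coastal", drop = FALSE],
                    gm2$gt[, gm2$pop == "inland", drop = FALSE])
  expect_equal(after$dxy, unname(b["dxy"]), tolerance = 1e-12)
})

test_that("interval pi is a ratio of sums, not a mean of ratios", {
  # site 1: pi = 4/6 over 6 pairs; site 2 has one individual missing:
  # pi = 1 over 1 pair. Ratio of sums (4+1)/(6+1) differs from the mean
  # of ratios (4/6 + 1)/2.
  g1 <- rbind(c(0L, 2L), c(0L, NA))
  g1[2, 1] <- 1L
  gm <- gm_from(g1, rbind(c(0L, 0L), c(0L, 0L)))
  st <- interval_popgen_stats(gm, data.frame(contig = "chr1", start = 0,
                                             end = 2))
  ratio_of_sums <- (4 + 1) / (6 + 1)
  mean_of_ratios <- (4 / 6 + 1) / 2
  expect_equal(st$pi_popA, ratio_of_sums)
  expect_false(isTRUE(all.equal(st$pi_popA, mean_of_ratios)))
})

test_that("the fixed-SNP mask applies a strict threshold", {
  # population-fixed difference: WC FST = 1, masked
  g1 <- matrix(0L, 1, 6); g2 <- matrix(2L, 1, 6)
  gm <- gm_from(g1, g2)
  expect_equal(nrow(build_mask(gm, 0.90)), 1)
  expect_equal(build_mask(gm, 0.90)$start, 0)

  # identical frequencies: FST ~ 0, not masked
  g <- matrix(rep(c(0L, 1L, 2L), 2), 1)
  gm2 <- gm_from(g, g)
  expect_equal(nrow(build_mask(gm2, 0.90)), 0)

  # a site exactly at the threshold is NOT masked (strict >)
  gm3 <- simulate_genotypes(0.5, n1 = 8, n2 = 8, n_sites = 50, seed = 93)
  fst <- per_site_fst(gm3, "wc")
  f <- fst$fst[which.max(fst$fst)]
  expect_false(any(build_mask(gm3, threshold = f)$start == fst$pos[which.max(fst$fst)] - 1))
  expect_true(any(build_mask(gm3, threshold = f - 1e-9)$start ==
                    fst$pos[which.max(fst$fst)] - 1))
})

test_that("elements are assigned to genes within the flank window", {
  genes <- data.frame(contig = "chr1", start = c(20000, 100000),
                      end = c(30000, 110000),
                      gene_id = c("gA", "gB"),
                      stringsAsFactors = FALSE)
  elements <- data.frame(
    contig = "chr1",
    start = c(14900, 9998, 95000),
    end = c(15000, 9999, 105000),
    stringsAsFactors = FALSE)
  # element 1 ends 5000 bp upstream of gA: assigned
  # element 2 ends 10001 bp upstream of gA (gap > 10 kb): not assigned
  # element 3 overlaps gB directly
  asg <- assign_elements(elements, genes, flank = 10000)
  expect_true(any(asg$element == 1 & asg$gene_id == "gA"))
  expect_false(any(asg$element == 2))
  expect_true(any(asg$element == 3 & asg$gene_id == "gB"))

  # an element in two gene windows is assigned to both
  genes2 <- data.frame(contig = "chr1", start = c(0, 3000),
                       end = c(1000, 4000), gene_id = c("g1", "g2"))
  near_both <- data.frame(contig = "chr1", start = 1800, end = 1900)
  asg2 <- assign_elements(near_both, genes2, flank = 10000)
  expect_setequal(asg2$gene_id, c("g1", "g2"))
})

test_that("flank boundary: a gap just over the flank excludes the element", {
  genes <- data.frame(contig = "chr1", start = 50000, end = 60000,
                      gene_id = "gA")
  just_in <- data.frame(contig = "chr1", start = 40000, end = 40001)
  just_out <- data.frame(contig = "chr1", start = 39999, end = 40000)
  expect_equal(nrow(assign_elements(just_in, genes, flank = 10000)), 1)
  expect_equal(nrow(assign_elements(just_out, genes, flank = 10000)), 0)
})

test_that("association model detects a shifted statistic and stays null-calibrated", {
  set.seed(94)
  genes <- sprintf("g%03d", 1:200)
  de <- setNames(rep(c(TRUE, FALSE), each = 100), genes)
  base <- function() rep(rnorm(200, 0, 0.05), each = 5) +
    rnorm(1000, 0, 0.05)
  shifted <- data.frame(gene_id = rep(genes, each = 5),
                        value = base() + 0.1 * rep(de[genes], each = 5))
  a <- de_association_model(shifted, de, "fst")
  expect_gt(a$estimate, 0)
  expect_lt(a$p_value, 0.01)

  flat <- data.frame(gene_id = rep(genes, each = 5), value = 1)
  a0 <- de_association_model(flat, de)
  expect_equal(a0$estimate, 0)
  expect_equal(a0$p_value, 1)
})
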