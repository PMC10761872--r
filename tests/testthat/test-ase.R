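make_act <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(individual = r[[1]], snp_id = r[[2]], gene_id = r[[3]],
               coastal_count = r[[4]], inland_count = r[[5]],
               state = r[[6]], stringsAsFactors = FALSE)))
  allele_count_table(df)
}

test_that("per-individual allele counts sum over heterozygous SNPs", {
  act <- make_act(list(
    list("i1", "s1", "gA", 5, 3, "migratory"),
    list("i1", "s2", "gA", 7, 1, "migratory")))
  gs <- aggregate_to_genes(act, min_het = 1)
  expect_equal(gs$mean_coastal, 12)
  expect_equal(gs$mean_inland, 4)
})

test_that("a SNP mapped to two genes is an error", {
  df <- data.frame(individual = "i1", snp_id = "s1",
                   gene_id = c("gA", "gB"), coastal_count = 1,
                   inland_count = 1, state = "migratory")
  expect_error(allele_count_table(df), "multiple genes")
})

test_that("eligibility boundaries are strict as specified", {
  # 2 vs 3 heterozygous individuals (overall rule)
  two_het <- make_act(lapply(1:2, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 5, 5, "migratory")))
  expect_false(aggregate_to_genes(two_het)$eligible_overall)

  three_het <- make_act(lapply(1:3, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 5, 5, "migratory")))
  expect_true(aggregate_to_genes(three_het)$eligible_overall)

  # GxE: 3 per state and >= 10 pooled reads
  gxe_rows <- c(
    lapply(1:3, function(i)
      list(paste0("m", i), paste0("sm", i), "gA", 1, 1, "migratory")),
    lapply(1:3, function(i)
      list(paste0("n", i), paste0("sn", i), "gA", 1, 1, "nonmigratory")))
  act12 <- make_act(gxe_rows)             # 12 reads total
  expect_true(aggregate_to_genes(act12)$eligible_gxe)

  # drop to 9 reads: one individual loses 3 reads
  act9 <- act12
  act9$coastal_count[1] <- 0
  act9$inland_count[1] <- 0
  act9$coastal_count[2] <- 0
  gs9 <- aggregate_to_genes(allele_count_table(as.data.frame(act9)))
  expect_equal(gs9$total_reads, 9)
  expect_false(gs9$eligible_gxe)
  expect_true(aggregate_to_genes(allele_count_table(as.data.frame(act9)),
                                 min_reads = 9)$eligible_gxe)

  # only 2 heterozygotes in one state fails the per-state rule
  lopsided <- make_act(c(
    lapply(1:4, function(i)
      list(paste0("m", i), paste0("sm", i), "gA", 5, 5, "migratory")),
    lapply(1:2, function(i)
      list(paste0("n", i), paste0("sn", i), "gA", 5, 5, "nonmigratory"))))
  expect_false(aggregate_to_genes(lopsided)$eligible_gxe)
})

test_that("allelic log2 ratios follow the displayed formulas", {
  gs <- aggregate_to_genes(make_act(lapply(1:3, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 8, 8, "migratory"))))
  expect_equal(allelic_log2fc(gs)$hybrid_allelic_log2fc, 0)

  gs2 <- aggregate_to_genes(make_act(lapply(1:3, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 16, 4, "migratory"))))
  expect_equal(allelic_log2fc(gs2, pseudocount = 0)$hybrid_allelic_log2fc,
               2)

  gs3 <- aggregate_to_genes(make_act(lapply(1:3, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 0, 3, "migratory"))))
  expect_equal(allelic_log2fc(gs3, pseudocount = 0.5)$hybrid_allelic_log2fc,
               log2(0.5 / 3.5))

  # ineligible genes are flagged undefined, never zero
  gs4 <- aggregate_to_genes(make_act(list(
    list("i1", "s1", "gA", 4, 4, "migratory"))))
  a <- allelic_log2fc(gs4)
  expect_true(is.na(a$hybrid_allelic_log2fc))
  expect_false(a$hybrid_allelic_defined)
})

test_that("parental double ratio follows the displayed formula", {
  # group means per population x state: coastal nm 8, coastal m 2,
  # inland nm 4, inland m 4 -> log2((8/2)/(4/4)) = 2 (pseudocount 0)
  counts <- rbind(gA = c(8, 8, 2, 2, 4, 4, 4, 4),
                  gB = c(6, 6, 6, 6, 6, 6, 6, 6))
  cm <- toy_count_matrix(
    counts,
    population = rep(c("coastal", "coastal", "inland", "inland"),
                     each = 2),
    state = rep(c("nonmigratory", "migratory", "nonmigratory",
                  "migratory"), each = 2))
  p <- parental_log2fc(cm, sf = setNames(rep(1, 8), cm$samples$sample),
                       pseudocount = 0)
  expect_equal(p$gxe_parental_log2fc[p$gene_id == "gA"], 2)
  expect_equal(p$gxe_parental_log2fc[p$gene_id == "gB"], 0)
  # overall ratio: coastal mean 5, inland mean 4
  expect_equal(p$parental_log2fc[p$gene_id == "gA"], log2(5 / 4))
})

test_that("ratio regression handles exact and degenerate inputs", {
  rt <- data.frame(gene_id = letters[1:5],
                   parental_log2fc = c(-2, -1, 0, 1, 2),
                   hybrid_allelic_log2fc = c(-2, -1, 0, 1, 2))
  # lm warns about the numerically perfect fits; that is the point here
  r <- suppressWarnings(regress_ratios(rt, "overall"))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$n, 5)

  rt$hybrid_allelic_log2fc <- rep(0.5, 5)
  r2 <- suppressWarnings(regress_ratios(rt, "overall"))
  expect_equal(r2$slope, 0, tolerance = 1e-12)

  expect_error(regress_ratios(rt[1:2, ], "overall"), "at least 3")
})

test_that("binomial ASE test matches exact arithmetic", {
  sym <- aggregate_to_genes(make_act(lapply(1:3, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 4, 4, "migratory"))))
  expect_equal(per_gene_ase_test(sym)$pvalue, 1)

  skew <- aggregate_to_genes(make_act(lapply(1:4, function(i)
    list(paste0("i", i), paste0("s", i), "gA", 5, 0, "migratory"))))
  expect_equal(per_gene_ase_test(skew)$pvalue, 2 * 0.5^20,
               tolerance = 1e-12)
})

test_that("null allelic data keeps the BH-significant fraction in check", {
  set.seed(61)
  arch <- simulate_regulatory_architectures(
    400, proportions = c(conserved = 1), seed = 61)
  sim <- simulate_expression_counts(arch, sim_design(depth = 2e5,
                                                     seed = 61))
  gs <- aggregate_to_genes(sim$alleles)
  tst <- per_gene_ase_test(gs)
  expect_lte(mean(tst$qvalue < 0.10, na.rm = TRUE), 0.10)
})

test_that("mean-then-ratio and ratio-then-mean estimates agree closely", {
  sc <- ase_scenario("cis_only", n_genes = 400, seed = 62)
  gs <- aggregate_to_genes(sc$sim$alleles)
  a_mean_first <- allelic_log2fc(gs)

  # ratio per individual first, then averaged across individuals
  al <- sc$sim$alleles
  key <- paste(al$individual, al$gene_id)
  coastal <- tapply(al$coastal_count, key, sum)
  inland <- tapply(al$inland_count, key, sum)
  gene <- sub("^\\S+ ", "", names(coastal))
  ind_ratio <- log2((coastal + 0.5) / (inland + 0.5))
  a_ratio_first <- tapply(ind_ratio, gene, mean)

  m <- merge(a_mean_first,
             data.frame(gene_id = names(a_ratio_first),
                        alt = as.numeric(a_ratio_first)),
             by = "gene_id")
  ok <- is.finite(m$hybrid_allelic_log2fc)
  expect_gte(cor(m$hybrid_allelic_log2fc[ok], m$alt[ok]), 0.9)
})

test_that("state-independent cis divergence does not fake a GxE signal", {
  sc <- ase_scenario("cis_only", n_genes = 400, seed = 63)
  r <- regress_ratios(sc$rt, "gxe")
  expect_lt(abs(r$slope), 0.1)
})
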