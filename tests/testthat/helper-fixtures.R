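# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk unless a test writes it first.

# Tiny count matrix with explicit group structure.
toy_count_matrix <- function(counts, population, state,
                             batch = NULL) {
  n <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  samples <- data.frame(
    sample = sprintf("s%02d", seq_len(n)),
    population = population, state = state,
    batch = batch %||% rep("b1", n),
    stringsAsFactors = FALSE
  )
  colnames(counts) <- samples$sample
  count_matrix(counts, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-interval pi / dxy by looping over every pair of allele
# copies; the O(n^2) oracle for interval_popgen_stats.
brute_pi_dxy <- function(gt1, gt2) {
  copies <- function(g) {
    unlist(lapply(g, function(x)
      if (is.na(x)) NULL else c(rep(1L, x), rep(0L, 2L - x))))
  }
  d1 <- c1 <- d2 <- c2 <- dd <- cd <- 0
  for (s in seq_len(nrow(gt1))) {
    a1 <- copies(gt1[s, ]); a2 <- copies(gt2[s, ])
    if (length(a1) >= 2) {
      pr <- utils::combn(a1, 2)
      d1 <- d1 + sum(pr[1, ] != pr[2, ]); c1 <- c1 + ncol(pr)
    }
    if (length(a2) >= 2) {
      pr <- utils::combn(a2, 2)
      d2 <- d2 + sum(pr[1, ] != pr[2, ]); c2 <- c2 + ncol(pr)
    }
    dd <- dd + sum(outer(a1, a2, "!="))
    cd <- cd + length(a1) * length(a2)
  }
  c(pi1 = if (c1 > 0) d1 / c1 else NA_real_,
    pi2 = if (c2 > 0) d2 / c2 else NA_real_,
    dxy = if (cd > 0) dd / cd else NA_real_)
}

# Independently coded BH step-up (oracle for adjust_fdr).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Simulate one pure-category ASE scenario and return its ratio table.
ase_scenario <- function(category, n_genes = 300, effect_sd = 2,
                         depth = 1e6, seed = 1) {
  arch <- simulate_regulatory_architectures(
    n_genes, proportions = stats::setNames(1, category),
    effect_sd = effect_sd, seed = seed)
  sim <- simulate_expression_counts(arch, sim_design(depth = depth,
                                                     seed = seed))
  rt <- build_ratio_table(allelic_log2fc(aggregate_to_genes(sim$alleles)),
                          parental_log2fc(sim$cm))
  list(arch = arch, sim = sim, rt = rt)
}
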