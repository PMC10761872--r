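# Synthetic-data generators. Every downstream stage is validated against
# the ground truth these produce, so the generative model is explicit:
#
# log2 expected expression, with s = 1 in the migratory state and 0 in the
# non-migratory state, b = baseline, c = cis, t = trans, e = state effect,
# gc/gt = state-dependent (GxE) cis/trans effects, h = hybrid offset:
#   inland parent:  b + e*s
#   coastal parent: b + c + t + (e + gc + gt)*s
#   hybrid allele (inland):  b - 1 + t/2 + (e + gt/2)*s
#   hybrid allele (coastal): b - 1 + c + t/2 + (e + gc + gt/2)*s
#   hybrid total: log2(2^inland_allele + 2^coastal_allele) + h
# so the expected coastal-allele share in a hybrid is
#   p = 2^(c + gc*s) / (1 + 2^(c + gc*s))
# and trans divergence moves both alleles equally (allelic ratio ignores t).
# The hybrid trans term is the parental midpoint (t/2 per allele), the
# simplest model in which a diffusible factor acts on both alleles.

ARCH_CATEGORIES <- c("conserved", "cis_only", "trans_only", "cis_trans",
                     "cisE", "transE", "transgressive")

#' Simulate per-gene regulatory architectures
#'
#' Assigns each gene a regulatory-divergence category and draws the
#' corresponding effect sizes (log2 units), baseline expression and
#' negative-binomial dispersion. Categories: `conserved` (no divergence),
#' `cis_only`, `trans_only`, `cis_trans` (state-independent divergence),
#' `cisE`/`transE` (state-dependent, GxE divergence), `transgressive`
#' (hybrid-specific offset).
#'
#' @param n_genes number of genes.
#' @param proportions named numeric vector over the seven categories,
#'   summing to 1.
#' @param effect_sd standard deviation of the normal distribution effect
#'   sizes are drawn from (log2 units); ignored when `effect_size` is set.
#' @param effect_size optional fixed effect size; when given, every nonzero
#'   effect equals this value exactly (point-mass distribution).
#' @param effect_sign `"positive"` (default) keeps fixed effects at
#'   `+effect_size`; `"random"` flips each to `-effect_size` with
#'   probability 1/2. Ignored when effects are drawn from the normal.
#' @param env_sd standard deviation of the shared migratory-state effect
#'   `e_g`, drawn for every gene independently of category (0 disables).
#' @param baseline_range range of baseline log2 mean expression.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   NB dispersion.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with class `architecture_table`: `gene_id`,
#'   `category`, `baseline_log2_mu`, `cis`, `trans`, `env`, `cis_x_env`,
#'   `trans_x_env`, `hybrid_offset`, `dispersion`.
#' @export
simulate_regulatory_architectures <- function(n_genes = 2000,
                                              proportions = c(
                                                conserved = 0.55,
                                                cis_only = 0.09,
                                                trans_only = 0.09,
                                                cis_trans = 0.09,
                                                cisE = 0.06,
                                                transE = 0.06,
                                                transgressive = 0.06),
                                              effect_sd = 1,
                                              effect_size = NULL,
                                              effect_sign = c("positive",
                                                              "random"),
                                              env_sd = 0,
                                              baseline_range = c(3, 10),
                                              dispersion_meanlog = log(0.05),
                                              dispersion_sdlog = 0.4,
                                              seed = 1) {
  assert_that(all(names(proportions) %in% ARCH_CATEGORIES),
              paste("unknown category; use:",
                    paste(ARCH_CATEGORIES, collapse = ", ")))
  assert_that(all(proportions >= 0) && abs(sum(proportions) - 1) < 1e-8,
              "category proportions must be non-negative and sum to 1")
  assert_that(is.null(effect_size) || effect_size > 0,
              "effect_size must be positive")
  assert_that(effect_sd > 0, "effect_sd must be positive")
  effect_sign <- match.arg(effect_sign)
  set.seed(seed)

  full <- setNames(rep(0, length(ARCH_CATEGORIES)), ARCH_CATEGORIES)
  full[names(proportions)] <- proportions
  category <- sample(ARCH_CATEGORIES, n_genes, replace = TRUE, prob = full)

  draw <- function(active) {
    eff <- rep(0, n_genes)
    if (is.null(effect_size)) {
      eff[active] <- rnorm(sum(active), 0, effect_sd)
    } else {
      sign <- if (effect_sign == "random")
        sample(c(-1, 1), sum(active), replace = TRUE) else 1
      eff[active] <- sign * effect_size
    }
    eff
  }
  arch <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    category = category,
    baseline_log2_mu = runif(n_genes, baseline_range[1], baseline_range[2]),
    cis = draw(category %in% c("cis_only", "cis_trans")),
    trans = draw(category %in% c("trans_only", "cis_trans")),
    env = if (env_sd > 0) rnorm(n_genes, 0, env_sd) else rep(0, n_genes),
    cis_x_env = draw(category == "cisE"),
    trans_x_env = draw(category == "transE"),
    hybrid_offset = draw(category == "transgressive"),
    dispersion = exp(rnorm(n_genes, dispersion_meanlog, dispersion_sdlog)),
    stringsAsFactors = FALSE
  )
  class(arch) <- c("architecture_table", "data.frame")
  arch
}

#' Describe a simulated study design
#'
#' Defaults mirror a two-season captive experiment: 4 birds per parental
#' population in the non-migratory state and 5 in the migratory state, with
#' 8 and 10 hybrids, hybrids split across two processing batches.
#'
#' @param n_parental_nonmig,n_parental_mig birds per parental population in
#'   each state.
#' @param n_hybrid_nonmig,n_hybrid_mig hybrid birds in each state.
#' @param depth target library size (reads per sample); realized sizes vary
#'   log-normally (sdlog 0.2) around it.
#' @param hybrid_batches number of hybrid processing batches (parentals are
#'   all batch `b1`).
#' @param seed integer seed.
#' @export
sim_design <- function(n_parental_nonmig = 4, n_parental_mig = 5,
                       n_hybrid_nonmig = 8, n_hybrid_mig = 10,
                       depth = 1e6, hybrid_batches = 2, seed = 1) {
  counts <- c(n_parental_nonmig, n_parental_mig,
              n_hybrid_nonmig, n_hybrid_mig)
  assert_that(all(counts >= 1), "all group sizes must be >= 1")
  assert_that(depth >= 1, "depth must be >= 1")
  structure(list(n_parental_nonmig = n_parental_nonmig,
                 n_parental_mig = n_parental_mig,
                 n_hybrid_nonmig = n_hybrid_nonmig,
                 n_hybrid_mig = n_hybrid_mig,
                 depth = depth, hybrid_batches = hybrid_batches,
                 seed = seed),
            class = "sim_design")
}

# Sample metadata table implied by a design.
design_samples <- function(design) {
  grp <- function(pop, state, n, prefix) {
    data.frame(sample = sprintf("%s_%s_%d", prefix,
                                ifelse(state == "nonmigratory", "nm", "mig"),
                                seq_len(n)),
               population = pop, state = state,
               batch = "b1", stringsAsFactors = FALSE)
  }
  s <- rbind(
    grp("coastal", "nonmigratory", design$n_parental_nonmig, "coa"),
    grp("coastal", "migratory", design$n_parental_mig, "coa"),
    grp("inland", "nonmigratory", design$n_parental_nonmig, "inl"),
    grp("inland", "migratory", design$n_parental_mig, "inl"),
    grp("hybrid", "nonmigratory", design$n_hybrid_nonmig, "hyb"),
    grp("hybrid", "migratory", design$n_hybrid_mig, "hyb")
  )
  hyb <- s$population == "hybrid"
  if (design$hybrid_batches > 1) {
    s$batch[hyb] <- sprintf("b%d", 1 + (seq_len(sum(hyb)) %%
                                          design$hybrid_batches))
  }
  s
}

#' Simulate expression counts and hybrid allelic counts
#'
#' Draws a genes x samples count matrix (negative binomial around the
#' expected means of the generative model, scaled to each sample's library
#' size) and, for hybrid samples, per-SNP allele-origin read counts whose
#' coastal share follows the cis (and cis-by-state) effects only. Allelic
#' counts for a gene sum exactly to that hybrid's total count for the gene.
#'
#' @param arch architecture table from
#'   [simulate_regulatory_architectures()].
#' @param design a [sim_design()].
#' @param n_snps_per_gene diagnostic SNPs per gene over which a hybrid's
#'   allelic reads are spread.
#' @param prob_het probability that a hybrid individual is heterozygous at
#'   a gene's diagnostic SNPs (1 = all hybrids are F1-like).
#' @param allelic_rho beta-binomial overdispersion of allelic counts in
#'   (0, 1); 0 gives pure binomial sampling.
#' @param batch_sd standard deviation of per-gene log2 batch effects for
#'   batches beyond the first.
#' @return list with `cm` (a [count_matrix()]), `alleles` (an
#'   [allele_count_table()] restricted to heterozygous individuals), and
#'   `truth` (the architecture table, the ground-truth labels).
#' @export
simulate_expression_counts <- function(arch, design = sim_design(),
                                       n_snps_per_gene = 2,
                                       prob_het = 1,
                                       allelic_rho = 0,
                                       batch_sd = 0.2) {
  assert_that(inherits(arch, "architecture_table"),
              "arch must be an architecture_table")
  assert_that(inherits(design, "sim_design"), "design must be a sim_design")
  assert_that(allelic_rho >= 0 && allelic_rho < 1,
              "allelic_rho must be in [0, 1)")
  set.seed(derive_seed(design$seed, 11L))

  samples <- design_samples(design)
  n_genes <- nrow(arch)
  n_samp <- nrow(samples)
  s <- as.numeric(samples$state == "migratory")

  b <- arch$baseline_log2_mu
  cis <- arch$cis; trans <- arch$trans; env <- arch$env
  gc_ <- arch$cis_x_env; gt_ <- arch$trans_x_env; h <- arch$hybrid_offset

  batches <- sort(unique(samples$batch))
  batch_eff <- matrix(0, n_genes, length(batches),
                      dimnames = list(NULL, batches))
  if (length(batches) > 1) {
    for (bt in batches[-1]) batch_eff[, bt] <- rnorm(n_genes, 0, batch_sd)
  }

  # log2 expected expression per gene x sample
  eta <- matrix(0, n_genes, n_samp)
  for (j in seq_len(n_samp)) {
    sj <- s[j]
    base <- b + batch_eff[, samples$batch[j]]
    eta[, j] <- switch(samples$population[j],
      inland  = base + env * sj,
      coastal = base + cis + trans + (env + gc_ + gt_) * sj,
      hybrid  = {
        a_inl <- base - 1 + trans / 2 + (env + gt_ / 2) * sj
        a_coa <- base - 1 + cis + trans / 2 + (env + gc_ + gt_ / 2) * sj
        log2(2^a_inl + 2^a_coa) + h
      })
  }

  lib <- design$depth * exp(rnorm(n_samp, 0, 0.2))
  mu <- 2^eta
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")

  size <- 1 / pmax(arch$dispersion, 1e-8)
  counts <- matrix(rnbinom(n_genes * n_samp, mu = as.vector(mu),
                           size = rep(size, n_samp)),
                   n_genes, n_samp,
                   dimnames = list(arch$gene_id, samples$sample))
  cm <- count_matrix(counts, samples)

  # hybrid allelic counts at diagnostic SNPs
  hyb_idx <- which(samples$population == "hybrid")
  rows <- vector("list", length(hyb_idx))
  for (k in seq_along(hyb_idx)) {
    j <- hyb_idx[k]
    sj <- s[j]
    het <- runif(n_genes) <= prob_het
    tot <- counts[, j]
    x <- cis + gc_ * sj
    p <- 2^x / (1 + 2^x)
    if (allelic_rho > 0) {
      shape <- (1 - allelic_rho) / allelic_rho
      p <- rbeta(n_genes, p * shape, (1 - p) * shape)
    }
    coastal <- rbinom(n_genes, tot, p)
    inland <- tot - coastal
    # spread each gene's allelic reads uniformly over its SNPs
    gi <- rep(seq_len(n_genes), each = n_snps_per_gene)
    split_counts <- function(v) {
      out <- integer(n_genes * n_snps_per_gene)
      nz <- which(v > 0)
      for (g in nz) {
        out[(g - 1) * n_snps_per_gene + seq_len(n_snps_per_gene)] <-
          as.integer(rmultinom(1, v[g], rep(1, n_snps_per_gene)))
      }
      out
    }
    df <- data.frame(
      individual = samples$sample[j],
      snp_id = sprintf("%s_snp%d", arch$gene_id[gi],
                       rep(seq_len(n_snps_per_gene), n_genes)),
      gene_id = arch$gene_id[gi],
      coastal_count = split_counts(coastal),
      inland_count = split_counts(inland),
      state = samples$state[j],
      het_flag = het[gi],
      stringsAsFactors = FALSE
    )
    rows[[k]] <- df[df$het_flag, , drop = FALSE]
  }
  alleles <- allele_count_table(do.call(rbind, rows))
  list(cm = cm, alleles = alleles, truth = arch)
}

#' Simulate two-population genotype panels under a Balding-Nichols model
#'
#' Per site, an ancestral allele frequency is drawn uniformly and each
#' population's frequency is drawn from a Beta distribution centred on it
#' with variance parameter `fst_target`; diploid genotypes are then
#' binomial(2, freq) with independent missingness. The Hudson
#' ratio-of-averages FST estimator recovers `fst_target` in expectation.
#'
#' @param fst_target differentiation parameter in [0, 1).
#' @param n1,n2 diploid sample sizes per population.
#' @param n_sites number of sites.
#' @param missing_rate per-call missingness probability.
#' @param contig contig name; positions are 1, 2, ... n_sites.
#' @param ancestral_range range of the ancestral allele frequency.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(fst_target, n1 = 15, n2 = 15,
                               n_sites = 1e4, missing_rate = 0,
                               contig = "chr1",
                               ancestral_range = c(0.05, 0.95),
                               seed = 1) {
  assert_that(fst_target >= 0 && fst_target < 1,
              "fst_target must be in [0, 1)")
  assert_that(n1 >= 2 && n2 >= 2, "sample sizes must be >= 2")
  set.seed(derive_seed(seed, 23L))
  p0 <- runif(n_sites, ancestral_range[1], ancestral_range[2])
  if (fst_target == 0) {
    p1 <- p0; p2 <- p0
  } else {
    shape <- (1 - fst_target) / fst_target
    p1 <- rbeta(n_sites, p0 * shape, (1 - p0) * shape)
    p2 <- rbeta(n_sites, p0 * shape, (1 - p0) * shape)
  }
  g1 <- matrix(rbinom(n_sites * n1, 2, rep(p1, n1)), n_sites, n1)
  g2 <- matrix(rbinom(n_sites * n2, 2, rep(p2, n2)), n_sites, n2)
  gt <- cbind(g1, g2)
  if (missing_rate > 0) {
    gt[matrix(runif(length(gt)) < missing_rate, nrow(gt))] <- NA
  }
  colnames(gt) <- c(sprintf("coa_%02d", seq_len(n1)),
                    sprintf("inl_%02d", seq_len(n2)))
  genotype_matrix(gt, pos = seq_len(n_sites), contig = contig,
                  pop = rep(c("coastal", "inland"), c(n1, n2)))
}

#' Simulate nightly activity traces
#'
#' Per 10-minute bin, raw motion-sensor detections are Poisson distributed:
#' a bin is "bursting" with probability given by the night's true state and
#' then uses the active intensity, otherwise the quiet intensity. Truth
#' labels are returned for classifier validation.
#'
#' @param n_birds,n_nights,bins_per_night trace dimensions (72 dark bins
#'   corresponds to a 12-hour night at 10-minute resolution).
#' @param state_schedule optional data.frame (`bird`, `night`, `state`)
#'   giving each bird-night's true state; by default the first half of the
#'   nights is non-migratory and the second half migratory for every bird.
#' @param rates named vector `c(quiet =, active =)` of raw detection
#'   intensities per bin (the downstream classifier divides by 3).
#' @param active_fraction named vector over states of the per-bin
#'   probability of a bursting bin.
#' @param seed integer seed.
#' @return list with `trace` (bird, night, bin_index, detections) and
#'   `truth` (bird, night, state).
#' @export
simulate_activity <- function(n_birds = 10, n_nights = 20,
                              bins_per_night = 72,
                              state_schedule = NULL,
                              rates = c(quiet = 6, active = 90),
                              active_fraction = c(nonmigratory = 0.005,
                                                  migratory = 0.6),
                              seed = 1) {
  assert_that(all(rates >= 0), "rates must be non-negative")
  set.seed(derive_seed(seed, 37L))
  if (is.null(state_schedule)) {
    state_schedule <- expand.grid(bird = sprintf("bird%02d",
                                                 seq_len(n_birds)),
                                  night = seq_len(n_nights),
                                  stringsAsFactors = FALSE)
    state_schedule$state <- ifelse(state_schedule$night <= n_nights / 2,
                                   "nonmigratory", "migratory")
  }
  assert_that(all(c("bird", "night", "state") %in% names(state_schedule)),
              "state_schedule needs columns bird, night, state")
  n_bn <- nrow(state_schedule)
  trace <- state_schedule[rep(seq_len(n_bn), each = bins_per_night),
                          c("bird", "night")]
  trace$bin_index <- rep(seq_len(bins_per_night), n_bn)
  st <- rep(state_schedule$state, each = bins_per_night)
  bursting <- runif(nrow(trace)) < active_fraction[st]
  trace$detections <- rpois(nrow(trace),
                            ifelse(bursting, rates["active"],
                                   rates["quiet"]))
  rownames(trace) <- NULL
  list(trace = trace, truth = state_schedule)
}
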