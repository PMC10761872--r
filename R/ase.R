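# Allele-specific expression in hybrids and the cis/trans decomposition.
#
# In a hybrid, a cis change rides with its allele and shifts the
# coastal/inland allelic ratio; a trans change acts on both alleles and
# leaves the ratio untouched. Regressing the hybrid allelic log2 fold
# change on the parental log2 fold change therefore reads out the cis
# share of divergence: slope near 1 = cis, near 0 = trans. The same logic
# applied to between-state double ratios reads out the regulation of GxE
# expression.

#' Aggregate allele counts to genes and apply eligibility filters
#'
#' Per individual and gene, allele counts are summed over that
#' individual's heterozygous SNPs; means are then taken across
#' contributing individuals, pooled and per migratory state. A gene is
#' eligible for the overall contrast with at least `min_het` heterozygous
#' individuals, and for the GxE contrast with at least `min_het`
#' heterozygous individuals in each state and at least `min_reads` reads
#' covering it (pooled across individuals and alleles by default).
#'
#' @param act an [allele_count_table()].
#' @param min_het minimum heterozygous individuals (default 3).
#' @param min_reads minimum pooled read coverage for the GxE contrast
#'   (default 10).
#' @param per_state_reads apply `min_reads` within each state instead of
#'   pooled.
#' @return data.frame of class `gene_allelic_summary`, one row per gene:
#'   heterozygote tallies, pooled/per-state mean and summed allele counts,
#'   `total_reads`, `eligible_overall`, `eligible_gxe`.
#' @export
aggregate_to_genes <- function(act, min_het = 3, min_reads = 10,
                               per_state_reads = FALSE) {
  act <- allele_count_table(act)
  act <- act[act$het_flag, , drop = FALSE]
  assert_that(nrow(act) > 0, "no heterozygous allele counts")

  # per individual x gene totals over heterozygous SNPs
  key <- paste(act$individual, act$gene_id, sep = "\r")
  ind <- data.frame(
    individual = act$individual[!duplicated(key)],
    gene_id = act$gene_id[!duplicated(key)],
    state = act$state[!duplicated(key)],
    coastal = as.numeric(tapply(act$coastal_count, key, sum)[unique(key)]),
    inland = as.numeric(tapply(act$inland_count, key, sum)[unique(key)]),
    stringsAsFactors = FALSE
  )

  per_gene <- function(d) {
    nm <- d$state == "nonmigratory"
    data.frame(
      gene_id = d$gene_id[1],
      n_het = nrow(d),
      n_het_nonmig = sum(nm),
      n_het_mig = sum(!nm),
      mean_coastal = mean(d$coastal),
      mean_inland = mean(d$inland),
      mean_coastal_nonmig = if (any(nm)) mean(d$coastal[nm]) else NA_real_,
      mean_coastal_mig = if (any(!nm)) mean(d$coastal[!nm]) else NA_real_,
      mean_inland_nonmig = if (any(nm)) mean(d$inland[nm]) else NA_real_,
      mean_inland_mig = if (any(!nm)) mean(d$inland[!nm]) else NA_real_,
      sum_coastal = sum(d$coastal),
      sum_inland = sum(d$inland),
      total_reads = sum(d$coastal) + sum(d$inland),
      reads_nonmig = sum(d$coastal[nm]) + sum(d$inland[nm]),
      reads_mig = sum(d$coastal[!nm]) + sum(d$inland[!nm]),
      stringsAsFactors = FALSE
    )
  }
  gs <- do.call(rbind, lapply(split(ind, ind$gene_id), per_gene))
  rownames(gs) <- NULL
  gs$eligible_overall <- gs$n_het >= min_het
  reads_ok <- if (per_state_reads) {
    gs$reads_nonmig >= min_reads & gs$reads_mig >= min_reads
  } else {
    gs$total_reads >= min_reads
  }
  gs$eligible_gxe <- gs$n_het_nonmig >= min_het &
    gs$n_het_mig >= min_het & reads_ok
  class(gs) <- c("gene_allelic_summary", "data.frame")
  gs
}

#' Hybrid allelic log2 fold changes
#'
#' Overall: `log2(mean coastal-allele / mean inland-allele)` across
#' eligible heterozygous individuals. GxE: the between-state double ratio
#' `log2((coastal_nonmig/coastal_mig) / (inland_nonmig/inland_mig))` on
#' allele means. A pseudocount keeps ratios finite and symmetric under
#' allele swap; ineligible genes are flagged undefined, never zeroed.
#'
#' @param gs a `gene_allelic_summary`.
#' @param pseudocount added to every mean entering a log ratio
#'   (default 0.5).
#' @return data.frame: `gene_id`, `hybrid_allelic_log2fc`,
#'   `gxe_hybrid_allelic_log2fc` and their `*_defined` flags.
#' @export
allelic_log2fc <- function(gs, pseudocount = 0.5) {
  assert_that(inherits(gs, "gene_allelic_summary"),
              "gs must come from aggregate_to_genes()")
  pc <- pseudocount
  a <- ifelse(gs$eligible_overall,
              log2((gs$mean_coastal + pc) / (gs$mean_inland + pc)),
              NA_real_)
  ag <- ifelse(gs$eligible_gxe,
               log2(((gs$mean_coastal_nonmig + pc) /
                       (gs$mean_coastal_mig + pc)) /
                      ((gs$mean_inland_nonmig + pc) /
                         (gs$mean_inland_mig + pc))),
               NA_real_)
  data.frame(gene_id = gs$gene_id,
             hybrid_allelic_log2fc = a,
             hybrid_allelic_defined = gs$eligible_overall,
             gxe_hybrid_allelic_log2fc = ag,
             gxe_hybrid_allelic_defined = gs$eligible_gxe,
             stringsAsFactors = FALSE)
}

#' Parental log2 fold changes, overall and GxE
#'
#' Overall: `log2(coastal / inland)` on size-factor-normalized group mean
#' expression pooled across migratory states. GxE: the double ratio
#' `log2((coastal_nonmig/coastal_mig) / (inland_nonmig/inland_mig))` on
#' per-state group means. Shares the allelic pseudocount.
#'
#' @param cm a [count_matrix()] containing parental samples.
#' @param sf size factors (computed from `cm` when `NULL`).
#' @param pseudocount added to every group mean (default 0.5).
#' @return data.frame: `gene_id`, `parental_log2fc`, `gxe_parental_log2fc`
#'   and `*_defined` flags.
#' @export
parental_log2fc <- function(cm, sf = NULL, pseudocount = 0.5) {
  assert_that(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  keep <- cm$samples$population %in% c("coastal", "inland")
  assert_that(any(keep), "no parental samples present")
  cm2 <- count_matrix(cm$counts[, keep, drop = FALSE],
                      cm$samples[keep, , drop = FALSE])
  if (is.null(sf)) sf <- estimate_size_factors(cm2) else
    sf <- sf[cm2$samples$sample]
  gm_pool <- group_means(cm2, sf, by = "population")
  gm_st <- group_means(cm2, sf, by = c("population", "state"))
  pc <- pseudocount
  need <- c("coastal.nonmigratory", "coastal.migratory",
            "inland.nonmigratory", "inland.migratory")
  have_states <- all(need %in% colnames(gm_st))
  p <- log2((gm_pool[, "coastal"] + pc) / (gm_pool[, "inland"] + pc))
  pg <- if (have_states) {
    log2(((gm_st[, "coastal.nonmigratory"] + pc) /
            (gm_st[, "coastal.migratory"] + pc)) /
           ((gm_st[, "inland.nonmigratory"] + pc) /
              (gm_st[, "inland.migratory"] + pc)))
  } else rep(NA_real_, nrow(gm_pool))
  data.frame(gene_id = rownames(cm2$counts),
             parental_log2fc = as.numeric(p),
             parental_defined = TRUE,
             gxe_parental_log2fc = as.numeric(pg),
             gxe_parental_defined = have_states,
             stringsAsFactors = FALSE)
}

#' Assemble the ratio table for the cis/trans regression
#'
#' Joins hybrid allelic and parental log2 fold changes by gene.
#'
#' @param allelic output of [allelic_log2fc()].
#' @param parental output of [parental_log2fc()].
#' @return data.frame of class `ratio_table`.
#' @export
build_ratio_table <- function(allelic, parental) {
  rt <- merge(allelic, parental, by = "gene_id", all = FALSE)
  class(rt) <- c("ratio_table", "data.frame")
  rt
}

#' Regress hybrid allelic on parental fold changes
#'
#' Ordinary least squares of the hybrid allelic log2 fold change on the
#' parental log2 fold change over genes where both are defined, in the
#' overall or the GxE contrast. A slope near 1 indicates cis control of
#' the divergence, a slope near 0 trans control.
#'
#' @param rt a `ratio_table`.
#' @param mode `"overall"` or `"gxe"`.
#' @param method `"ols"` (default) or `"spearman"` (rank correlation, for
#'   sensitivity; slope/intercept are then on ranks).
#' @return list: `slope`, `intercept`, `r_squared` (adjusted), `n`,
#'   `p_value` (two-sided, slope), `mode`.
#' @export
regress_ratios <- function(rt, mode = c("overall", "gxe"),
                           method = c("ols", "spearman")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "overall") {
    x <- rt$parental_log2fc
    y <- rt$hybrid_allelic_log2fc
  } else {
    x <- rt$gxe_parental_log2fc
    y <- rt$gxe_hybrid_allelic_log2fc
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    stop("need at least 3 genes with both fold changes defined",
         call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x[ok]); y <- rank(y[ok])
  } else {
    x <- x[ok]; y <- y[ok]
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  pv <- if (nrow(sm$coefficients) > 1) sm$coefficients["x", 4] else NA_real_
  slope <- if ("x" %in% rownames(sm$coefficients))
    sm$coefficients["x", 1] else 0
  list(slope = unname(slope),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$adj.r.squared,
       n = sum(ok),
       p_value = unname(pv),
       mode = mode)
}

#' Per-gene test for allele-specific expression
#'
#' Exact binomial test of the pooled coastal-allele read count against a
#' 0.5 allelic proportion, BH-adjusted across eligible genes.
#'
#' @param gs a `gene_allelic_summary`.
#' @return data.frame: `gene_id`, `coastal_fraction`, `pvalue`, `qvalue`;
#'   ineligible or uncovered genes carry `NA`.
#' @export
per_gene_ase_test <- function(gs) {
  assert_that(inherits(gs, "gene_allelic_summary"),
              "gs must come from aggregate_to_genes()")
  p <- rep(NA_real_, nrow(gs))
  frac <- rep(NA_real_, nrow(gs))
  for (i in seq_len(nrow(gs))) {
    if (!gs$eligible_overall[i]) next
    x <- round(gs$sum_coastal[i]); n <- round(gs$total_reads[i])
    if (n == 0) next
    p[i] <- binom.test(x, n, p = 0.5)$p.value
    frac[i] <- x / n
  }
  data.frame(gene_id = gs$gene_id, coastal_fraction = frac,
             pvalue = p, qvalue = bh_adjust(p),
             stringsAsFactors = FALSE)
}
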