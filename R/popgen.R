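# Population-genetic statistics over element intervals, computed
# pixy-style from genotype matrices with missing data: every statistic is
# a ratio of summed per-site differences to summed per-site comparisons,
# so invariant sites contribute comparisons (with zero differences) and
# missing calls only shrink the comparison counts.

# Per-site allele tallies for one population: n = non-missing allele
# copies, d = alternate-allele copies.
site_tallies <- function(gt) {
  n <- 2L * rowSums(!is.na(gt))
  d <- rowSums(gt, na.rm = TRUE)
  list(n = n, d = d)
}

# Per-site within-population difference/comparison counts.
pi_site <- function(n, d) {
  list(diff = d * (n - d), comp = n * (n - 1) / 2)
}

# Per-site between-population difference/comparison counts.
dxy_site <- function(n1, d1, n2, d2) {
  list(diff = d1 * (n2 - d2) + d2 * (n1 - d1), comp = n1 * n2)
}

# Per-site Weir & Cockerham (1984) theta components for two populations,
# from diploid genotype calls (uses observed heterozygosity).
wc_site_components <- function(gt1, gt2) {
  r <- 2
  nmat <- cbind(rowSums(!is.na(gt1)), rowSums(!is.na(gt2)))
  pmat <- cbind(rowMeans(gt1, na.rm = TRUE) / 2,
                rowMeans(gt2, na.rm = TRUE) / 2)
  hmat <- cbind(rowMeans(gt1 == 1, na.rm = TRUE),
                rowMeans(gt2 == 1, na.rm = TRUE))
  nbar <- rowMeans(nmat)
  nc <- (r * nbar - rowSums(nmat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(nmat * pmat) / (r * nbar)
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Per-site FST
#'
#' @param gm a [genotype_matrix()].
#' @param estimator `"wc"` (Weir-Cockerham 1984 theta, default here
#'   because per-site masking mirrors vcftools) or `"hudson"`.
#' @return data.frame: `contig`, `pos`, `fst` (`NaN` where undefined,
#'   e.g. monomorphic with no variance components).
#' @export
per_site_fst <- function(gm, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  pops <- unique(gm$pop)
  gt1 <- gm$gt[, gm$pop == pops[1], drop = FALSE]
  gt2 <- gm$gt[, gm$pop == pops[2], drop = FALSE]
  if (estimator == "wc") {
    comp <- wc_site_components(gt1, gt2)
    fst <- comp$a / (comp$a + comp$b + comp$c)
  } else {
    t1 <- site_tallies(gt1); t2 <- site_tallies(gt2)
    p1 <- t1$d / t1$n; p2 <- t2$d / t2$n
    num <- (p1 - p2)^2 -
      p1 * (1 - p1) / (t1$n - 1) - p2 * (1 - p2) / (t2$n - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- num / den
  }
  data.frame(contig = gm$contig, pos = gm$pos, fst = fst,
             stringsAsFactors = FALSE)
}

#' Interval pi, dXY and FST with missing data
#'
#' Within-population nucleotide diversity, between-population divergence
#' and FST over each interval, as ratios of summed site differences to
#' summed site comparisons. Interval FST defaults to the Hudson
#' ratio-of-averages estimator, `1 - mean within-pi / mean between`, with
#' per-site Weir-Cockerham (aggregated as sum a / sum (a+b+c)) optional.
#' Negative estimates are reported as computed, never clamped.
#'
#' @param gm a [genotype_matrix()].
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open, BED convention) and optionally `element_type`, `gene_id`,
#'   `name`.
#' @param fst_estimator `"hudson"` (default) or `"wc"`.
#' @return data.frame of class `interval_stats`: the interval columns plus
#'   `pi_<pop1>`, `pi_<pop2>`, `dxy`, `fst`, `n_sites`, `n_comparisons`,
#'   and a `defined` flag (FALSE when no callable comparisons exist).
#' @export
interval_popgen_stats <- function(gm, intervals,
                                  fst_estimator = c("hudson", "wc")) {
  fst_estimator <- match.arg(fst_estimator)
  assert_that(all(c("contig", "start", "end") %in% names(intervals)),
              "intervals need contig, start, end")
  assert_that(all(intervals$end > intervals$start),
              "interval end must exceed start")
  pops <- unique(gm$pop)
  gt1 <- gm$gt[, gm$pop == pops[1], drop = FALSE]
  gt2 <- gm$gt[, gm$pop == pops[2], drop = FALSE]
  t1 <- site_tallies(gt1); t2 <- site_tallies(gt2)
  p1s <- pi_site(t1$n, t1$d); p2s <- pi_site(t2$n, t2$d)
  dxs <- dxy_site(t1$n, t1$d, t2$n, t2$d)
  wc <- if (fst_estimator == "wc") wc_site_components(gt1, gt2) else NULL

  res <- intervals
  n <- nrow(intervals)
  res$pi1 <- res$pi2 <- res$dxy <- res$fst <- NA_real_
  res$n_sites <- 0L
  res$n_comparisons <- 0
  res$defined <- FALSE
  for (i in seq_len(n)) {
    # BED half-open [start, end) on 0-based coordinates; gm$pos is 1-based
    sel <- gm$contig == intervals$contig[i] &
      gm$pos - 1L >= intervals$start[i] & gm$pos - 1L < intervals$end[i]
    if (!any(sel)) next
    res$n_sites[i] <- sum(sel)
    c1 <- sum(p1s$comp[sel]); c2 <- sum(p2s$comp[sel])
    cd <- sum(dxs$comp[sel])
    res$n_comparisons[i] <- c1 + c2 + cd
    if (c1 > 0) res$pi1[i] <- sum(p1s$diff[sel]) / c1
    if (c2 > 0) res$pi2[i] <- sum(p2s$diff[sel]) / c2
    if (cd > 0) res$dxy[i] <- sum(dxs$diff[sel]) / cd
    if (fst_estimator == "hudson") {
      if (c1 > 0 && c2 > 0 && cd > 0 && res$dxy[i] > 0) {
        res$fst[i] <- 1 - ((res$pi1[i] + res$pi2[i]) / 2) / res$dxy[i]
      }
    } else {
      den <- sum(wc$a[sel] + wc$b[sel] + wc$c[sel], na.rm = TRUE)
      if (is.finite(den) && den > 0) {
        res$fst[i] <- sum(wc$a[sel], na.rm = TRUE) / den
      }
    }
    res$defined[i] <- res$n_comparisons[i] > 0
  }
  names(res)[names(res) == "pi1"] <- paste0("pi_", pops[1])
  names(res)[names(res) == "pi2"] <- paste0("pi_", pops[2])
  class(res) <- c("interval_stats", "data.frame")
  res
}

#' Genome-wide Hudson FST (ratio of averages)
#'
#' @param gm a [genotype_matrix()].
#' @return single FST estimate over all sites.
#' @export
genome_fst_hudson <- function(gm) {
  one <- interval_popgen_stats(
    gm, data.frame(contig = unique(gm$contig),
                   start = 0, end = max(gm$pos),
                   stringsAsFactors = FALSE),
    fst_estimator = "hudson")
  # combine contigs by pooling comparison-weighted sums
  if (nrow(one) == 1) return(one$fst)
  stop("multi-contig genome FST not implemented; pass one contig")
}

#' Build the nearly-fixed-SNP mask
#'
#' Sites whose per-site Weir-Cockerham FST strictly exceeds `threshold`
#' (nearly fixed between the subspecies) as 1-bp BED features, the set
#' masked before read mapping to avoid subspecies mapping bias.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold strict lower bound (default 0.90; a site at exactly
#'   the threshold is not masked).
#' @return data.frame `contig`, `start`, `end`, `fst` in BED coordinates.
#' @export
build_mask <- function(gm, threshold = 0.90) {
  fst <- per_site_fst(gm, estimator = "wc")
  sel <- !is.na(fst$fst) & fst$fst > threshold
  data.frame(contig = fst$contig[sel], start = fst$pos[sel] - 1L,
             end = fst$pos[sel], fst = fst$fst[sel],
             stringsAsFactors = FALSE)
}

#' Assign elements to genes by flanked overlap
#'
#' A regulatory element (CNE or intron) is assigned to every gene whose
#' interval, extended by `flank` on both sides, it overlaps. Elements in
#' multiple gene windows are assigned to all of them.
#'
#' @param elements data.frame `contig`, `start`, `end` (0-based
#'   half-open), optional `name`, `element_type`.
#' @param genes data.frame `contig`, `start`, `end`, `gene_id`.
#' @param flank window extension in bp (default 10000).
#' @return data.frame of element rows (with an `element` index into
#'   `elements`) paired with `gene_id`.
#' @export
assign_elements <- function(elements, genes, flank = 10000) {
  assert_that(all(elements$end > elements$start) &&
                all(genes$end > genes$start),
              "interval end must exceed start")
  # GRanges is 1-based closed; convert half-open 0-based intervals
  er <- GenomicRanges::GRanges(elements$contig,
                               IRanges::IRanges(elements$start + 1,
                                                elements$end))
  gr <- GenomicRanges::GRanges(genes$contig,
                               IRanges::IRanges(
                                 pmax(genes$start + 1 - flank, 1),
                                 genes$end + flank))
  hits <- GenomicRanges::findOverlaps(er, gr)
  out <- elements[S4Vectors::queryHits(hits), , drop = FALSE]
  out$element <- S4Vectors::queryHits(hits)
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}

#' Mixed-model association between genomic variation and DE status
#'
#' Fits (by maximum likelihood) `statistic ~ de_status + (1 | gene)` over
#' element-gene rows against the no-predictor null, and reports the
#' DE fixed effect with a 1-df likelihood-ratio chi-square. On a singular
#' random-effect fit, falls back to averaging elements within genes and a
#' Welch two-sample t-test, flagged in `method`.
#'
#' @param stats data.frame with `gene_id` and a `value` column holding
#'   the per-element statistic.
#' @param de_flags named logical vector: per-gene DE indicator.
#' @param statistic label for the statistic being modelled.
#' @return list of class `association_result`: `statistic`, `estimate`,
#'   `chisq`, `p_value`, `n_elements`, `n_genes`, `method`.
#' @export
de_association_model <- function(stats, de_flags, statistic = "stat") {
  d <- data.frame(value = stats$value, gene_id = stats$gene_id,
                  stringsAsFactors = FALSE)
  d$de <- as.numeric(de_flags[d$gene_id])
  d <- d[complete.cases(d), ]
  assert_that(length(unique(d$de)) == 2,
              "need genes in both DE classes")
  assert_that(length(unique(d$gene_id)) >= 4, "too few genes")
  if (var(d$value) == 0) {
    out <- list(statistic = statistic, estimate = 0, chisq = 0,
                p_value = 1, n_elements = nrow(d),
                n_genes = length(unique(d$gene_id)),
                method = "constant")
    class(out) <- "association_result"
    return(out)
  }

  full <- tryCatch(suppressWarnings(suppressMessages(
    lme4::lmer(value ~ de + (1 | gene_id), data = d, REML = FALSE))),
    error = function(e) NULL)
  singular <- is.null(full) || lme4::isSingular(full, tol = 1e-4)
  if (!singular) {
    null <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ 1 + (1 | gene_id), data = d, REML = FALSE)))
    an <- anova(null, full)
    out <- list(statistic = statistic,
                estimate = unname(lme4::fixef(full)["de"]),
                chisq = an$Chisq[2], p_value = an$`Pr(>Chisq)`[2],
                n_elements = nrow(d),
                n_genes = length(unique(d$gene_id)),
                method = "lmm_lrt")
  } else {
    gm <- aggregate(value ~ gene_id + de, data = d, FUN = mean)
    tt <- t.test(value ~ de, data = gm)
    est <- unname(diff(rev(tt$estimate)))
    out <- list(statistic = statistic,
                estimate = -est,
                chisq = unname(tt$statistic)^2,
                p_value = tt$p.value,
                n_elements = nrow(d),
                n_genes = length(unique(gm$gene_id)),
                method = "gene_mean_ttest")
  }
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ DE status: estimate %.4g, chi-sq %.3g, p %.3g (%s; %d elements, %d genes)\n",
              x$statistic, x$estimate, x$chisq, x$p_value, x$method,
              x$n_elements, x$n_genes))
  invisible(x)
}
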