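# Differential expression: low-expression filtering, median-of-ratios
# size factors, per-gene negative-binomial GLMs with Wald (or LRT) tests
# for migratory state, subspecies, their interaction (GxE), and
# hybrid-vs-parent contrasts, with BH FDR control at q < 0.10.

#' Remove genes with low expression
#'
#' Keeps genes reaching at least `cpm_threshold` counts per million in at
#' least `min_samples` samples. CPM uses raw column sums as library sizes
#' (the conventional definition), and the threshold is inclusive.
#'
#' @param cm a [count_matrix()].
#' @param cpm_threshold counts-per-million cutoff (default 1).
#' @param min_samples number of samples that must reach the cutoff
#'   (default 4).
#' @return the filtered [count_matrix()].
#' @export
filter_low_expression <- function(cm, cpm_threshold = 1, min_samples = 4) {
  assert_that(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  lib <- colSums(cm$counts)
  assert_that(all(lib > 0), "all library sizes must be positive")
  cpm <- sweep(cm$counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= cpm_threshold) >= min_samples
  assert_that(any(keep), "no genes pass the expression filter")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}

#' Median-of-ratios size factors
#'
#' For every gene with nonzero counts in all samples, each sample's count
#' is divided by the gene's geometric mean across samples; the sample's
#' size factor is the median of these ratios. No further rescaling is
#' applied.
#'
#' @param cm a [count_matrix()] or a bare count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has nonzero counts in every sample; filter more ",
         "stringently or supply a pseudo-reference", call. = FALSE)
  }
  sf <- apply(logs[use, , drop = FALSE], 2,
              function(x) exp(median(x - loggeo[use])))
  setNames(sf, colnames(counts))
}

# Model matrix with aliased (rank-deficient) columns dropped, e.g. a batch
# level confounded with population when only hybrids were re-batched.
design_matrix <- function(samples, formula) {
  samples$state <- factor(samples$state,
                          levels = c("nonmigratory", "migratory"))
  pops <- intersect(c("inland", "coastal", "hybrid"),
                    unique(samples$population))
  samples$population <- factor(samples$population, levels = pops)
  samples$batch <- factor(samples$batch)
  # drop single-level factors (e.g. batch when the subset has only one)
  vars <- all.vars(formula)
  keep <- vapply(vars, function(v) length(unique(samples[[v]])) > 1,
                 logical(1))
  if (!all(keep)) {
    terms_kept <- attr(terms(formula), "term.labels")
    terms_kept <- terms_kept[!vapply(terms_kept, function(tl)
      any(vars[!keep] %in% all.vars(as.formula(paste("~", tl)))),
      logical(1))]
    assert_that(length(terms_kept) > 0, "no varying design terms")
    formula <- as.formula(paste("~", paste(terms_kept, collapse = "+")))
  }
  mm <- model.matrix(formula, samples)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    mm <- mm[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
  }
  mm
}

# Fit one gene's NB GLM with log link and log size-factor offset.
# Maximum-likelihood dispersion via glm.nb, then a degrees-of-freedom bias
# correction: the ML dispersion ignores the p estimated mean parameters,
# so phi is inflated by n/(n-p) (theta deflated) and the model refit at
# the corrected value. On glm.nb failure, a method-of-moments dispersion
# (floored at 1e-8) is used instead.
fit_nb_gene <- function(y, mm, off) {
  n <- length(y)
  p <- ncol(mm)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ mm - 1 + offset(off))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    theta <- fit$theta * (n - p) / n
    converged <- TRUE
  } else {
    z <- y / exp(off)
    mz <- mean(z)
    phi <- max((var(z) - mz) / mz^2 * n / (n - p), 1e-8)
    theta <- 1 / phi
    converged <- FALSE
  }
  refit <- tryCatch(
    suppressWarnings(glm(y ~ mm - 1 + offset(off),
                         family = MASS::negative.binomial(theta = theta))),
    error = function(e) NULL)
  if (is.null(refit)) return(NULL)
  list(fit = refit, theta = theta, converged = converged, df = n - p)
}

# Map user-facing contrast names to model-matrix coefficient names.
contrast_coef <- function(contrast, coefs) {
  want <- switch(contrast,
    state = "statemigratory",
    subspecies = "populationcoastal",
    interaction = "statemigratory:populationcoastal",
    hybrid_vs_coastal = ,
    hybrid_vs_inland = "populationhybrid",
    stop("unknown contrast: ", contrast, call. = FALSE))
  hit <- grep(want, coefs, fixed = TRUE, value = TRUE)
  # the interaction pattern also matches the main effects' names reversed
  if (contrast == "interaction") {
    hit <- grep(":", hit, fixed = TRUE, value = TRUE)
  } else {
    hit <- setdiff(hit, grep(":", hit, fixed = TRUE, value = TRUE))
  }
  if (length(hit) != 1) {
    stop("contrast '", contrast, "' not estimable from this design",
         call. = FALSE)
  }
  hit
}

#' Negative-binomial differential expression
#'
#' Fits per-gene NB GLMs with log link and log size-factor offsets and
#' tests the requested contrasts. The main three contrasts (`state`,
#' `subspecies`, `interaction`) are fit on parental samples under
#' `~ state * population + batch`; `hybrid_vs_coastal` and
#' `hybrid_vs_inland` are fit within one migratory state under
#' `~ population + batch` on the relevant sample pairs. Positive fold
#' changes mean: migratory over non-migratory, coastal over inland, and
#' hybrid over parent. Non-convergent genes keep a method-of-moments
#' dispersion fallback; genes where even that fails get missing p-values
#' and are excluded from the FDR denominator.
#'
#' @param cm a filtered [count_matrix()].
#' @param sf size factors from [estimate_size_factors()]; computed from
#'   `cm` when `NULL`.
#' @param contrasts character vector among `state`, `subspecies`,
#'   `interaction`, `hybrid_vs_coastal`, `hybrid_vs_inland`.
#' @param state migratory state the hybrid contrasts are fit in (required
#'   for them, ignored otherwise).
#' @param include_hybrids include hybrid samples in the main three-way
#'   model (default `FALSE`: parental-only).
#' @param test `"wald"` (default) or `"lrt"` (likelihood ratio at the
#'   full fit's dispersion).
#' @param fdr significance threshold on BH-adjusted p-values.
#' @return data.frame of class `de_result`: `gene_id`, `contrast`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `qvalue`, `sig`, `converged`.
#' @export
fit_de <- function(cm, sf = NULL,
                   contrasts = c("state", "subspecies", "interaction"),
                   state = NULL, include_hybrids = FALSE,
                   test = c("wald", "lrt"), fdr = 0.10) {
  assert_that(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  test <- match.arg(test)
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  sf <- sf[cm$samples$sample]
  assert_that(all(is.finite(sf) & sf > 0), "invalid size factors")

  main <- intersect(contrasts, c("state", "subspecies", "interaction"))
  hybc <- intersect(contrasts, c("hybrid_vs_coastal", "hybrid_vs_inland"))
  out <- list()

  if (length(main)) {
    keep <- if (include_hybrids) rep(TRUE, nrow(cm$samples)) else
      cm$samples$population != "hybrid"
    out <- c(out, fit_de_block(cm, sf, keep,
                               ~ state * population + batch, main, test))
  }
  for (ct in hybc) {
    assert_that(!is.null(state),
                "hybrid contrasts require a migratory state")
    parent <- if (ct == "hybrid_vs_coastal") "coastal" else "inland"
    keep <- cm$samples$state == state &
      cm$samples$population %in% c(parent, "hybrid")
    out <- c(out, fit_de_block(cm, sf, keep, ~ population + batch,
                               ct, test))
  }
  res <- do.call(rbind, out)
  res$qvalue <- NA_real_
  for (ct in unique(res$contrast)) {
    i <- res$contrast == ct
    res$qvalue[i] <- bh_adjust(res$pvalue[i])
  }
  res$sig <- !is.na(res$qvalue) & res$qvalue < fdr
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

fit_de_block <- function(cm, sf, keep, formula, contrasts, test) {
  samples <- cm$samples[keep, , drop = FALSE]
  counts <- cm$counts[, keep, drop = FALSE]
  off <- log(sf[keep])
  mm <- design_matrix(samples, formula)
  assert_that(qr(mm)$rank == ncol(mm), "design matrix is rank deficient")
  coefs <- lapply(contrasts, contrast_coef, coefs = colnames(mm))
  names(coefs) <- contrasts

  n_genes <- nrow(counts)
  res <- lapply(contrasts, function(ct)
    data.frame(gene_id = rownames(counts), contrast = ct,
               log2fc = NA_real_, se = NA_real_, stat = NA_real_,
               pvalue = NA_real_, converged = FALSE,
               stringsAsFactors = FALSE))
  names(res) <- contrasts

  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == y[1])) {
      # flat gene: fold changes are exactly zero, no evidence either way
      for (ct in contrasts) {
        res[[ct]]$log2fc[g] <- 0
        res[[ct]]$pvalue[g] <- 1
        res[[ct]]$converged[g] <- TRUE
      }
      next
    }
    fit <- fit_nb_gene(y, mm, off)
    if (is.null(fit)) next
    sm <- summary(fit$fit, dispersion = 1)$coefficients
    rownames(sm) <- sub("^mm", "", rownames(sm))
    for (ct in contrasts) {
      cf <- coefs[[ct]]
      if (!cf %in% rownames(sm)) next
      est <- sm[cf, 1]; se <- sm[cf, 2]
      res[[ct]]$log2fc[g] <- est / log(2)
      res[[ct]]$se[g] <- se / log(2)
      res[[ct]]$converged[g] <- fit$converged
      if (test == "wald") {
        # t reference with residual df: small-sample calibration of the
        # Wald test under estimated dispersion
        z <- est / se
        res[[ct]]$stat[g] <- z
        res[[ct]]$pvalue[g] <- 2 * pt(-abs(z), df = fit$df)
      } else {
        mm_red <- mm[, colnames(mm) != cf, drop = FALSE]
        red <- tryCatch(suppressWarnings(
          glm(y ~ mm_red - 1 + offset(off),
              family = MASS::negative.binomial(theta = fit$theta))),
          error = function(e) NULL)
        full <- tryCatch(suppressWarnings(
          glm(y ~ mm - 1 + offset(off),
              family = MASS::negative.binomial(theta = fit$theta))),
          error = function(e) NULL)
        if (is.null(red) || is.null(full)) next
        lr <- max(0, 2 * (as.numeric(logLik(full)) -
                            as.numeric(logLik(red))))
        res[[ct]]$stat[g] <- lr
        res[[ct]]$pvalue[g] <- pchisq(lr, df = 1, lower.tail = FALSE)
      }
    }
  }
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; missing
#' p-values stay missing and do not count towards the number of tests.
#'
#' @param pvalues numeric vector in [0, 1], `NA` allowed.
#' @return adjusted q-values, same length.
#' @export
adjust_fdr <- function(pvalues) {
  assert_that(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)),
              "p-values must lie in [0, 1]")
  bh_adjust(pvalues)
}

#' Classify genes by which contrasts are significant
#'
#' Maps the significance pattern over the state (environment, E),
#' subspecies (genotype, G) and interaction (GxE) contrasts to a label:
#' `"E"`, `"G"`, `"GxE"`, combinations joined with `+`, or `"none"`.
#'
#' @param de a `de_result` containing the three main contrasts.
#' @return data.frame `gene_id`, `category`.
#' @export
classify_gene_effects <- function(de) {
  need <- c("state", "subspecies", "interaction")
  assert_that(all(need %in% de$contrast),
              "de must contain state, subspecies and interaction contrasts")
  wide <- lapply(need, function(ct) {
    x <- de[de$contrast == ct, c("gene_id", "sig")]
    setNames(x$sig, x$gene_id)
  })
  genes <- unique(de$gene_id)
  lab <- vapply(genes, function(g) {
    parts <- c(if (isTRUE(wide[[2]][g])) "G",
               if (isTRUE(wide[[1]][g])) "E",
               if (isTRUE(wide[[3]][g])) "GxE")
    if (length(parts)) paste(parts, collapse = "+") else "none"
  }, character(1))
  data.frame(gene_id = genes, category = unname(lab),
             stringsAsFactors = FALSE)
}

#' Size-factor-normalized group mean expression
#'
#' @param cm a [count_matrix()].
#' @param sf size factors.
#' @param by metadata columns to group samples by.
#' @return matrix of genes x groups mean normalized counts; group names
#'   join the `by` values with `.`.
#' @export
group_means <- function(cm, sf = NULL, by = c("population", "state")) {
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  norm <- sweep(cm$counts, 2, sf[cm$samples$sample], "/")
  key <- interaction(cm$samples[by], drop = TRUE, sep = ".")
  sapply(levels(key), function(k)
    rowMeans(norm[, key == k, drop = FALSE]))
}
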