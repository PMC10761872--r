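# Transgressive (mis)expression in hybrids: expression significantly
# outside the range of both parental forms, called per migratory state.

#' Call transgressive expression per gene within one state
#'
#' A gene is called `over` when the hybrid is significantly differentially
#' expressed against both parents (q below `fdr` in each contrast), both
#' fold changes are positive, and the hybrid normalized group mean exceeds
#' both parental means; `under` is symmetric. Discordant directions
#' (above one parent, below the other) give `none`.
#'
#' @param de_hc,de_hi `de_result` rows for the `hybrid_vs_coastal` and
#'   `hybrid_vs_inland` contrasts fit within the same state.
#' @param means data.frame with `gene_id`, `hybrid`, `coastal`, `inland`
#'   normalized group means for that state.
#' @param state the migratory state the contrasts were fit in.
#' @param fdr significance threshold (default 0.10).
#' @return data.frame of class `transgressive_calls`: `gene_id`, `state`,
#'   `call`, `q_hybrid_vs_coastal`, `q_hybrid_vs_inland`, the means.
#' @export
call_transgressive <- function(de_hc, de_hi, means, state, fdr = 0.10) {
  hc <- de_hc[de_hc$contrast == "hybrid_vs_coastal", ]
  hi <- de_hi[de_hi$contrast == "hybrid_vs_inland", ]
  assert_that(nrow(hc) > 0 && nrow(hi) > 0,
              "both hybrid-vs-parent contrasts are required")
  m <- merge(merge(hc[, c("gene_id", "log2fc", "qvalue")],
                   hi[, c("gene_id", "log2fc", "qvalue")],
                   by = "gene_id", suffixes = c("_hc", "_hi")),
             means, by = "gene_id")
  sig_both <- !is.na(m$qvalue_hc) & !is.na(m$qvalue_hi) &
    m$qvalue_hc < fdr & m$qvalue_hi < fdr
  over <- sig_both & m$log2fc_hc > 0 & m$log2fc_hi > 0 &
    m$hybrid > m$coastal & m$hybrid > m$inland
  under <- sig_both & m$log2fc_hc < 0 & m$log2fc_hi < 0 &
    m$hybrid < m$coastal & m$hybrid < m$inland
  out <- data.frame(gene_id = m$gene_id, state = state,
                    call = ifelse(over, "over",
                                  ifelse(under, "under", "none")),
                    q_hybrid_vs_coastal = m$qvalue_hc,
                    q_hybrid_vs_inland = m$qvalue_hi,
                    mean_hybrid = m$hybrid, mean_coastal = m$coastal,
                    mean_inland = m$inland,
                    stringsAsFactors = FALSE)
  class(out) <- c("transgressive_calls", "data.frame")
  out
}

#' Run the transgressive analysis for one state
#'
#' Convenience wrapper: fits the two hybrid-vs-parent contrasts within
#' `state`, computes normalized group means, and calls transgression.
#'
#' @inheritParams fit_de
#' @param state migratory state to analyse.
#' @export
transgressive_analysis <- function(cm, sf = NULL, state, fdr = 0.10) {
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  de <- fit_de(cm, sf,
               contrasts = c("hybrid_vs_coastal", "hybrid_vs_inland"),
               state = state, fdr = fdr)
  keep <- cm$samples$state == state
  cm_st <- count_matrix(cm$counts[, keep, drop = FALSE],
                        cm$samples[keep, , drop = FALSE])
  gm <- group_means(cm_st, sf[cm_st$samples$sample], by = "population")
  means <- data.frame(gene_id = rownames(gm),
                      hybrid = gm[, "hybrid"],
                      coastal = gm[, "coastal"],
                      inland = gm[, "inland"],
                      stringsAsFactors = FALSE)
  call_transgressive(de, de, means, state = state, fdr = fdr)
}

#' Tally transgressive calls per brain region and state
#'
#' @param calls a `transgressive_calls` table (rows from one or more
#'   states), optionally with a `region` column (defaults to `"all"`).
#' @param de_subspecies_genes optional character vector of subspecies-DE
#'   gene ids; their overlap with transgressive genes is reported.
#' @return list with `counts` (region x state x call tallies, long
#'   data.frame) and `overlap_with_subspecies_de` (count or `NA`).
#' @export
summarize_transgressive <- function(calls, de_subspecies_genes = NULL) {
  if (is.null(calls$region)) calls$region <- "all"
  tg <- calls[calls$call != "none", , drop = FALSE]
  grid <- expand.grid(region = unique(calls$region),
                      state = unique(calls$state),
                      call = c("over", "under"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(r, s, cl)
    sum(tg$region == r & tg$state == s & tg$call == cl),
    grid$region, grid$state, grid$call)
  ov <- if (is.null(de_subspecies_genes)) NA_integer_ else
    length(intersect(unique(tg$gene_id), de_subspecies_genes))
  list(counts = grid, overlap_with_subspecies_de = ov)
}
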