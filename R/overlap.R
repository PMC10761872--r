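# Chance-overlap arithmetic and exact enrichment test for gene lists.

#' Expected chance overlap between two gene sets
#'
#' With `K` of `N` background genes in one set and `n` draws in the
#' other, the expected overlap under independence is `n * K / N`
#' (the hypergeometric mean). Returned exactly, with the two rounding
#' styles used in reporting.
#'
#' @param N background gene count.
#' @param K size of the first set.
#' @param n size of the second set (draws).
#' @return list: `expected`, `expected_2dp`, `expected_int`.
#' @export
expected_overlap <- function(N, K, n) {
  assert_that(N > 0, "background size N must be positive")
  assert_that(K >= 0 && n >= 0 && K <= N && n <= N,
              "need 0 <= K, n <= N")
  e <- n * K / N
  list(expected = e, expected_2dp = round(e, 2),
       expected_int = round(e))
}

#' Exact hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the given overlap when
#' `n` genes are drawn without replacement from `N` of which `K` are in
#' the first set.
#'
#' @inheritParams expected_overlap
#' @param observed observed overlap.
#' @return list of class `overlap_test`: `N`, `K`, `n`, `observed`,
#'   `expected`, `p_value`.
#' @export
hypergeom_overlap_test <- function(N, K, n, observed) {
  e <- expected_overlap(N, K, n)
  assert_that(observed >= 0 && observed <= min(K, n),
              "observed overlap must lie in [0, min(K, n)]")
  p <- phyper(observed - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, observed = observed,
                 expected = e$expected, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap %d of draws %d vs set %d (background %d): expected %.2f by chance, upper-tail p = %.3g\n",
    x$observed, x$n, x$K, x$N, x$expected, x$p_value))
  invisible(x)
}

#' Overlap test from gene lists
#'
#' @param set1,set2 character vectors of gene ids.
#' @param background character vector of all testable genes; `set1` and
#'   `set2` are intersected with it first.
#' @return an [hypergeom_overlap_test()] result.
#' @export
overlap_test <- function(set1, set2, background) {
  s1 <- intersect(unique(set1), background)
  s2 <- intersect(unique(set2), background)
  hypergeom_overlap_test(length(unique(background)), length(s1),
                         length(s2), length(intersect(s1, s2)))
}
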