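# Migratory-restlessness (zugunruhe) scoring from passive-infrared
# activity traces, and the field RFLP ancestry score.

#' Correct raw motion detections for sensor dead time
#'
#' The PIR sensors re-arm three seconds after a detection, so raw records
#' are divided by three to approximate true movement counts. No rounding
#' is applied.
#'
#' @param raw_detections non-negative numeric vector.
#' @return real-valued movement counts.
#' @export
correct_counts <- function(raw_detections) {
  assert_that(all(raw_detections >= 0), "detections must be non-negative")
  raw_detections / 3
}

#' Classify nights as migratory, non-migratory or intermediate
#'
#' A 10-minute bin is active when its corrected movement count strictly
#' exceeds `active_threshold`. The nightly active fraction is computed
#' over dark bins only; a night is non-migratory strictly below `low`,
#' migratory strictly above `high`, intermediate otherwise (boundary
#' fractions fall to intermediate).
#'
#' @param trace data.frame `bird`, `night`, `bin_index`, `detections`
#'   (raw), optionally a logical `dark` column (all bins dark when
#'   absent, i.e. the trace covers the scotophase only).
#' @param active_threshold movements per 10 min above which a bin is
#'   active (default 20, strict).
#' @param low,high nightly active-fraction cutoffs (defaults 0.05 and
#'   0.40, both strict).
#' @return data.frame of class `migratory_state_calls`: `bird`, `night`,
#'   `n_dark_bins`, `active_bin_fraction`, `call`.
#' @export
classify_nights <- function(trace, active_threshold = 20,
                            low = 0.05, high = 0.40) {
  needed <- c("bird", "night", "bin_index", "detections")
  assert_that(all(needed %in% names(trace)),
              paste("trace needs columns:", paste(needed, collapse = ", ")))
  if (is.null(trace$dark)) trace$dark <- TRUE
  dk <- trace[trace$dark, , drop = FALSE]
  assert_that(nrow(dk) > 0, "no dark bins in trace")
  active <- correct_counts(dk$detections) > active_threshold
  key <- interaction(dk$bird, dk$night, drop = TRUE, sep = "\r")
  frac <- tapply(active, key, mean)
  nb <- tapply(active, key, length)
  ids <- do.call(rbind, strsplit(names(frac), "\r", fixed = TRUE))
  out <- data.frame(bird = ids[, 1],
                    night = type.convert(ids[, 2], as.is = TRUE),
                    n_dark_bins = as.integer(nb),
                    active_bin_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  out$call <- ifelse(out$active_bin_fraction < low, "nonmigratory",
                     ifelse(out$active_bin_fraction > high, "migratory",
                            "intermediate"))
  out <- out[order(out$bird, out$night), ]
  rownames(out) <- NULL
  class(out) <- c("migratory_state_calls", "data.frame")
  out
}

#' Flag nights with a stable trailing state
#'
#' A night's call is stable when it is identical on that night and each
#' of the `required_nights` preceding nights — the rule used to ensure
#' birds held the desired behavior for at least ten days before sampling.
#'
#' @param calls `migratory_state_calls` (or any data.frame with `bird`,
#'   `night`, `call`), chronologically orderable by `night` within bird.
#' @param required_nights preceding nights that must match (default 10).
#' @return `calls` with a logical `stability_ok` column.
#' @export
stability_window <- function(calls, required_nights = 10) {
  calls <- calls[order(calls$bird, calls$night), ]
  ok <- logical(nrow(calls))
  for (b in unique(calls$bird)) {
    i <- which(calls$bird == b)
    cl <- calls$call[i]
    for (k in seq_along(i)) {
      ok[i[k]] <- k > required_nights &&
        all(cl[(k - required_nights):k] == cl[k])
    }
  }
  calls$stability_ok <- ok
  rownames(calls) <- NULL
  calls
}

#' RFLP ancestry score
#'
#' Fraction of inland alleles over a small panel of diagnostic
#' restriction-site markers: 0 = homozygous coastal at every locus,
#' 1 = homozygous inland at every locus, 0.5 = heterozygous throughout.
#'
#' @param genotypes integer vector of inland-allele counts (0, 1 or 2)
#'   per locus, typically length 3.
#' @return ancestry score in [0, 1].
#' @export
rflp_ancestry <- function(genotypes) {
  assert_that(length(genotypes) >= 1, "at least one locus required")
  assert_that(all(genotypes %in% 0:2),
              "each locus must carry 0, 1 or 2 inland alleles")
  sum(genotypes) / (2 * length(genotypes))
}
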