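#' Construct a count matrix with sample metadata
#'
#' The substrate of all expression stages: a genes x samples matrix of raw
#' read counts plus one metadata record per sample column.
#'
#' @param counts integer matrix, genes as rows (rownames are gene
#'   identifiers, unique), samples as columns.
#' @param samples data.frame with one row per column of `counts`, containing
#'   at least `sample`, `population` (one of `"coastal"`, `"inland"`,
#'   `"hybrid"`), `state` (one of `"nonmigratory"`, `"migratory"`) and
#'   `batch`. An optional `region` column records the brain region.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) > 0 && ncol(counts) > 0, "empty count matrix")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(all(abs(counts - round(counts)) < 1e-8),
              "counts must be integral")
  assert_that(!is.null(rownames(counts)), "counts must have gene rownames")
  assert_that(!anyDuplicated(rownames(counts)),
              "duplicate gene identifiers in counts")
  assert_that(is.data.frame(samples) && nrow(samples) == ncol(counts),
              "samples metadata must have one row per sample column")
  needed <- c("sample", "population", "state", "batch")
  assert_that(all(needed %in% names(samples)),
              paste("samples metadata must contain columns:",
                    paste(needed, collapse = ", ")))
  assert_that(all(samples$population %in% c("coastal", "inland", "hybrid")),
              "population must be coastal, inland or hybrid")
  assert_that(all(samples$state %in% c("nonmigratory", "migratory")),
              "state must be nonmigratory or migratory")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("populations:",
      paste(names(table(x$samples$population)), table(x$samples$population),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct an allele-origin read count table
#'
#' Per hybrid individual and diagnostic SNP, the number of reads carrying
#' the coastal and the inland allele (ASEReadCounter-style), with the SNP to
#' gene mapping and the individual's migratory state.
#'
#' @param df data.frame with columns `individual`, `snp_id`, `gene_id`,
#'   `coastal_count`, `inland_count`, `state`, and optionally `het_flag`
#'   (defaults to `TRUE`; only heterozygous rows enter ASE analyses).
#' @return The validated data.frame with class `allele_count_table`.
#' @export
allele_count_table <- function(df) {
  needed <- c("individual", "snp_id", "gene_id", "coastal_count",
              "inland_count", "state")
  assert_that(all(needed %in% names(df)),
              paste("allele count table needs columns:",
                    paste(needed, collapse = ", ")))
  assert_that(all(df$coastal_count >= 0) && all(df$inland_count >= 0),
              "allele counts must be non-negative")
  assert_that(all(df$state %in% c("nonmigratory", "migratory")),
              "state must be nonmigratory or migratory")
  map <- unique(df[, c("snp_id", "gene_id")])
  if (anyDuplicated(map$snp_id)) {
    bad <- map$snp_id[duplicated(map$snp_id)][1]
    stop("SNP mapped to multiple genes: ", bad, call. = FALSE)
  }
  if (is.null(df$het_flag)) df$het_flag <- TRUE
  class(df) <- c("allele_count_table", "data.frame")
  df
}

#' Construct a diploid genotype matrix for two parental panels
#'
#' @param gt integer matrix of alternate-allele dosages (0, 1, 2 or `NA`
#'   for missing), sites as rows, diploid individuals as columns.
#' @param pos 1-based site positions (VCF convention), strictly increasing
#'   within a contig.
#' @param contig contig name(s), length 1 or `nrow(gt)`.
#' @param pop population label per individual; exactly two levels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, pos, contig = "chr1", pop) {
  gt <- as.matrix(gt)
  assert_that(all(gt %in% c(0L, 1L, 2L) | is.na(gt)),
              "genotypes must be 0, 1, 2 or NA")
  assert_that(length(pos) == nrow(gt), "one position per site")
  assert_that(length(pop) == ncol(gt), "one population label per individual")
  assert_that(length(unique(pop)) == 2L,
              "genotype matrix requires exactly two populations")
  if (length(contig) == 1L) contig <- rep(contig, nrow(gt))
  for (ctg in unique(contig)) {
    p <- pos[contig == ctg]
    assert_that(all(diff(p) > 0),
                "positions must be strictly increasing within a contig")
  }
  structure(list(gt = gt, pos = as.integer(pos), contig = contig,
                 pop = as.character(pop)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$gt), "sites x", ncol(x$gt),
      "individuals (", paste(unique(x$pop), collapse = " vs "), ")\n")
  invisible(x)
}
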