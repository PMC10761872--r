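# Plain-text readers and writers for the pipeline's standard formats:
# count/metadata TSV, allele-count TSV, GT-only VCF, BED, activity CSV.
# Readers validate and report malformed lines with line numbers.

#' Read a count matrix and its sample metadata
#'
#' @param counts_path TSV with genes as rows (first column gene id) and
#'   samples as columns.
#' @param samples_path TSV of sample metadata (`sample`, `population`,
#'   `state`, `batch`, ...).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  samples <- samples[match(colnames(counts), samples$sample), ,
                     drop = FALSE]
  assert_that(!anyNA(samples$sample),
              "sample metadata does not cover every count column")
  count_matrix(counts, samples)
}

#' Write a count matrix and its sample metadata
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output TSV paths.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read / write allele-origin count tables
#'
#' TSV with columns `individual`, `snp_id`, `gene_id`, `coastal_count`,
#' `inland_count`, `state`, optional `het_flag`.
#'
#' @param path file path.
#' @return an [allele_count_table()].
#' @export
read_allele_counts <- function(path) {
  allele_count_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_allele_counts
#' @param act an [allele_count_table()].
#' @export
write_allele_counts <- function(act, path) {
  write.table(act, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Columns: contig, start, end, then optional `name`, `element_type`,
#' `gene_id` as given in `extra_cols`. Malformed lines (fewer than three
#' fields, non-numeric coordinates, end <= start) raise an error naming
#' the line number.
#'
#' @param path BED path (0-based half-open coordinates).
#' @param extra_cols names for columns beyond the first three.
#' @return data.frame `contig`, `start`, `end`, plus extras.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3) {
      stop("BED line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("BED line ", i, ": non-numeric coordinates", call. = FALSE)
    }
    if (end <= start) {
      stop("BED line ", i, ": end must exceed start", call. = FALSE)
    }
    out[[i]] <- c(f[1], start, end, f[-(1:3)])
  }
  ncols <- max(lengths(out))
  mat <- t(vapply(out, function(x) c(x, rep(NA, ncols - length(x))),
                  character(ncols)))
  df <- data.frame(contig = mat[, 1],
                   start = as.numeric(mat[, 2]),
                   end = as.numeric(mat[, 3]),
                   stringsAsFactors = FALSE)
  if (ncols > 3) {
    extras <- mat[, -(1:3), drop = FALSE]
    nm <- extra_cols %||% paste0("V", 4:ncols)
    for (k in seq_len(ncol(extras))) {
      df[[nm[k]]] <- type.convert(extras[, k], as.is = TRUE)
    }
  }
  df
}

#' @rdname read_bed
#' @param bed data.frame with `contig`, `start`, `end` and any extra
#'   columns, written in order.
#' @export
write_bed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Emits unphased diploid genotypes with `./.` for missing calls; the
#' population panel membership goes in a sidecar not the VCF (sample
#' names keep their panel prefix).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(gm$gt)),
                     collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow(gm$gt))
  gt_str[is.na(gm$gt)] <- "./."
  body <- paste(gm$contig, gm$pos, ".", "A", "T", ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Uses vcfR when available, else a minimal tab parser. Only the GT field
#' is used; `./.` (or `.`) become missing calls, never reference.
#'
#' @param path VCF path.
#' @param pop population label per sample column; when `NULL`, inferred
#'   from the sample-name prefix before the first underscore.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, pop = NULL) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    contig <- vcfR::getCHROM(v)
    pos <- vcfR::getPOS(v)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    assert_that(length(hdr) == 1, "no #CHROM header line in VCF")
    cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
    body <- strsplit(lines[(hdr + 1):length(lines)], "\t", fixed = TRUE)
    mat <- do.call(rbind, body)
    contig <- mat[, 1]
    pos <- as.integer(mat[, 2])
    gt_raw <- mat[, 10:ncol(mat), drop = FALSE]
    colnames(gt_raw) <- cols[10:length(cols)]
    gt_raw <- sub(":.*", "", gt_raw)
  }
  dose <- function(x) {
    x[is.na(x)] <- "."
    a <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (!length(al) || anyNA(al) || any(al == ".")) return(NA_integer_)
      sum(as.integer(al))
    }, integer(1))
  }
  gt <- apply(gt_raw, 2, dose)
  if (is.null(pop)) pop <- sub("_.*", "", colnames(gt_raw))
  genotype_matrix(gt, pos = pos, contig = contig, pop = pop)
}

#' Read / write nightly activity traces
#'
#' CSV with columns `bird`, `night`, `bin_index`, `detections`.
#'
#' @param path file path.
#' @export
read_activity <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bird", "night", "bin_index", "detections")
  assert_that(all(needed %in% names(tr)),
              paste("activity CSV needs columns:",
                    paste(needed, collapse = ", ")))
  assert_that(all(tr$detections >= 0), "detections must be non-negative")
  tr
}

#' @rdname read_activity
#' @param trace data.frame as returned by [simulate_activity()].
#' @export
write_activity <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
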