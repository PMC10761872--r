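# End-to-end orchestration: simulate every input, run each analysis stage
# in dependency order, write plain-text outputs and a manifest with file
# hashes so reruns under the same seed are verifiably identical.

#' Build and validate a pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; every stage derives its own seed from
#'   it.
#' @param n_genes genes to simulate.
#' @param fdr DE significance threshold on q-values.
#' @param min_het,min_reads ASE eligibility thresholds.
#' @param cpm,min_samples expression-filter thresholds.
#' @param mask_fst strict per-site FST threshold for the mask.
#' @param flank element-to-gene assignment window (bp).
#' @param active_threshold,night_low,night_high behavior thresholds.
#' @param fst_target differentiation level of the simulated panels.
#' @param design a [sim_design()]; defaults to the study layout.
#' @param arch_proportions category proportions for the architecture
#'   table (defaults of [simulate_regulatory_architectures()] when NULL).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_genes = 2000, fdr = 0.10,
                       min_het = 3, min_reads = 10, cpm = 1,
                       min_samples = 4, mask_fst = 0.90, flank = 10000,
                       active_threshold = 20, night_low = 0.05,
                       night_high = 0.40, fst_target = 0.3,
                       design = NULL, arch_proportions = NULL) {
  assert_that(fdr > 0 && fdr < 1, "fdr must be in (0, 1)")
  assert_that(min_het >= 1 && min_reads >= 0, "invalid ASE thresholds")
  assert_that(mask_fst >= 0 && mask_fst <= 1, "invalid mask threshold")
  assert_that(night_low < night_high, "night_low must be below night_high")
  assert_that(!missing(out_dir) && is.character(out_dir),
              "out_dir is required")
  cfg <- list(out_dir = out_dir, seed = seed, n_genes = n_genes,
              fdr = fdr, min_het = min_het, min_reads = min_reads,
              cpm = cpm, min_samples = min_samples, mask_fst = mask_fst,
              flank = flank, active_threshold = active_threshold,
              night_low = night_low, night_high = night_high,
              fst_target = fst_target, design = design,
              arch_proportions = arch_proportions)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Simulates all inputs under the configured seed, then runs differential
#' expression, the ASE cis/trans regressions, transgressive calling,
#' interval population-genetic statistics with the DE association model,
#' behavioral scoring, and the chance-overlap test, writing each stage's
#' outputs under `out_dir` and a JSON manifest with per-file MD5 hashes.
#' Reruns with an identical config and seed produce identical hashes.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  # --- simulate ---
  sim <- stage("simulate", {
    arch <- do.call(simulate_regulatory_architectures, c(
      list(n_genes = config$n_genes, seed = derive_seed(config$seed, 1L)),
      if (!is.null(config$arch_proportions))
        list(proportions = config$arch_proportions)))
    design <- config$design %||% sim_design(seed = derive_seed(config$seed,
                                                               2L))
    out <- simulate_expression_counts(arch, design)
    write_count_matrix(out$cm, emit("counts.tsv"), emit("samples.tsv"))
    write_allele_counts(out$alleles, emit("allele_counts.tsv"))
    write.table(arch, emit("truth_architectures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$gm <- simulate_genotypes(config$fst_target,
                                 seed = derive_seed(config$seed, 3L))
    write_vcf(out$gm, emit("panels.vcf"))
    out$act <- simulate_activity(seed = derive_seed(config$seed, 4L))
    write_activity(out$act$trace, emit("activity.csv"))
    out
  })

  # --- differential expression ---
  de <- stage("de", {
    cm <- filter_low_expression(sim$cm, config$cpm, config$min_samples)
    sf <- estimate_size_factors(cm)
    de <- fit_de(cm, sf, fdr = config$fdr)
    write.table(de, emit("de_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cls <- classify_gene_effects(de)
    write.table(cls, emit("gene_effect_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(cm = cm, sf = sf, de = de, classes = cls)
  })

  # --- allele-specific expression ---
  ase <- stage("ase", {
    gs <- aggregate_to_genes(sim$alleles, config$min_het,
                             config$min_reads)
    rt <- build_ratio_table(allelic_log2fc(gs),
                            parental_log2fc(de$cm, de$sf))
    write.table(rt, emit("ratio_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    reg <- list(overall = regress_ratios(rt, "overall"),
                gxe = regress_ratios(rt, "gxe"))
    write_json(reg, emit("ase_regressions.json"), auto_unbox = TRUE,
               digits = NA)
    list(gs = gs, rt = rt, reg = reg)
  })

  # --- transgressive ---
  stage("transgressive", {
    calls <- rbind(
      transgressive_analysis(de$cm, de$sf, "nonmigratory", config$fdr),
      transgressive_analysis(de$cm, de$sf, "migratory", config$fdr))
    write.table(calls, emit("transgressive_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    subsp <- de$de$gene_id[de$de$contrast == "subspecies" & de$de$sig]
    summ <- summarize_transgressive(calls, subsp)
    write.table(summ$counts, emit("transgressive_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summ
  })

  # --- popgen ---
  stage("popgen", {
    gm <- sim$gm
    n_sites <- nrow(gm$gt)
    # tile the simulated contig into element intervals, one per 50 sites
    starts <- seq(0, n_sites - 1, by = 50)
    elements <- data.frame(contig = gm$contig[1], start = starts,
                           end = pmin(starts + 50, n_sites),
                           element_type = "CNE",
                           stringsAsFactors = FALSE)
    st <- interval_popgen_stats(gm, elements)
    write.table(st, emit("interval_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mask <- build_mask(gm, config$mask_fst)
    write_bed(mask, emit("fixed_snp_mask.bed"))
    list(stats = st, mask = mask)
  })

  # --- behavior ---
  stage("behavior", {
    calls <- classify_nights(sim$act$trace, config$active_threshold,
                             config$night_low, config$night_high)
    calls <- stability_window(calls)
    write.table(calls, emit("night_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    calls
  })

  # --- overlap ---
  stage("overlap", {
    state_de <- de$de$gene_id[de$de$contrast == "state" & de$de$sig]
    background <- rownames(de$cm$counts)
    set.seed(derive_seed(config$seed, 5L))
    candidates <- sample(background, min(300, length(background)))
    ot <- overlap_test(state_de, candidates, background)
    write_json(unclass(ot), emit("overlap_test.json"),
               auto_unbox = TRUE, digits = NA)
    ot
  })

  manifest <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = as.list(tools::md5sum(unlist(paths)))
  )
  names(manifest$files) <- names(paths)
  write_json(manifest, file.path(config$out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
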