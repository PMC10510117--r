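#' Run the full two-breed CNV analysis pipeline on a simulated landscape
#'
#' End-to-end demonstration driver: simulate a two-population CNV landscape,
#' filter the per-sample calls, merge them into CNVRs, apply the
#' carrier-count filter, partition by breed, build the copy-number matrix,
#' scan V_ST, threshold at the given percentile, confirm candidates with
#' ANOVA/Tukey, cluster samples on CNVR presence/absence with bootstrap
#' support, and (when annotations are supplied) intersect CNVRs with genes
#' and QTLs. All stage outputs are pure functions of the configuration and
#' its seed; rerunning with the same config reproduces them exactly.
#'
#' @param config A [sim_config()] describing the landscape (and carrying the
#'   seed).
#' @param thresholds Call-level [filter_thresholds()].
#' @param carrier_mode Carrier-filter mode, see [carrier_filter()].
#' @param q Percentile for the V_ST threshold.
#' @param alpha Significance level for the ANOVA/Tukey confirmation.
#' @param nboot,r_grid,metric Clustering options, see
#'   [multiscale_bootstrap()].
#' @param genes,qtls Optional feature data.frames ([read_features()]
#'   layout).
#' @param min_qtl_overlap Strict QTL overlap bound in bp.
#' @param outdir Optional directory; when given, stage outputs and a
#'   `manifest.tsv` (package version, seed, thresholds) are written there.
#' @param quiet Suppress stage progress messages.
#' @return List with `sim`, `filtered_calls`, `regions` (post
#'   carrier-filter), `partition`, `cn`, `vst` (scan records), `threshold`,
#'   `above` (region ids above threshold), `confirmed` (ANOVA/Tukey table
#'   for candidates), `clustering` (`"msboot"` object), `summary`, and
#'   optionally `gene_overlaps` / `qtl_overlaps`.
#' @export
run_pipeline <- function(config = sim_config(),
                         thresholds = filter_thresholds(),
                         carrier_mode = "any_breed",
                         q = 0.98, alpha = 0.01,
                         nboot = 100, r_grid = seq(0.5, 1.4, by = 0.1),
                         metric = "jaccard",
                         genes = NULL, qtls = NULL, min_qtl_overlap = 1000,
                         outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  say("simulate: ", config$n_regions, " truth regions, ",
      2 * config$n_samples_per_pop, " samples (seed ", config$seed, ")")
  sim <- simulate_landscape(config)

  say("filter: call-level quality thresholds")
  filtered <- filter_calls(sim$calls, thresholds)

  say("merge: building CNVRs")
  regions <- merge_calls(filtered, chroms = names(config$chrom_lengths))
  say("carrier filter: >= ", thresholds$min_carriers, " carriers (",
      carrier_mode, ")")
  regions <- carrier_filter(regions, sim$labels, thresholds$min_carriers,
                            carrier_mode)
  part <- partition_by_breed(regions, sim$labels)

  say("genotype: copy-number matrix over ", nrow(regions), " CNVRs")
  cn_region <- region_cn_matrix(regions, sim)

  say("vst: scan + ", q * 100, "th-percentile threshold")
  scan <- vst_scan(cn_region, sim$labels)
  thr <- percentile_threshold(scan$vst, q)
  above <- scan$region_id[!is.na(scan$vst) & scan$vst >= thr]

  say("anova/tukey: confirming ", length(above), " candidates")
  confirmed <- anova_scan(cn_region[above, , drop = FALSE], sim$labels)
  confirmed$significant <- !is.na(confirmed$p) & confirmed$p < alpha

  say("cluster: multiscale bootstrap (nboot ", nboot, ")")
  pm <- presence_matrix(regions, names(sim$labels))
  clust <- multiscale_bootstrap(pm, r_grid = r_grid, nboot = nboot,
                                metric = metric, seed = config$seed + 4L)

  res <- list(sim = sim, filtered_calls = filtered, regions = regions,
              partition = part, cn = cn_region, vst = scan,
              threshold = thr, above = above, confirmed = confirmed,
              clustering = clust, thresholds = thresholds,
              summary = summarize_cnvr(regions, config$chrom_lengths))
  if (!is.null(genes)) {
    say("annotate: genes")
    res$gene_overlaps <- intersect_features(regions, genes, 0)
  }
  if (!is.null(qtls)) {
    say("annotate: QTLs (> ", min_qtl_overlap, " bp)")
    res$qtl_overlaps <- intersect_features(regions, qtls, min_qtl_overlap)
  }
  if (!is.null(outdir)) write_pipeline_outputs(res, config, outdir)
  say("done: ", nrow(regions), " CNVRs, ", length(above),
      " above V_ST threshold ", signif(thr, 4))
  res
}

# mean observed copy number per (CNVR, sample): average of the simulator's
# per-truth-region estimates over the truth regions a CNVR overlaps, diploid
# baseline otherwise
region_cn_matrix <- function(regions, sim) {
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
  gr_t <- GenomicRanges::GRanges(sim$truth$chrom,
                                 IRanges::IRanges(sim$truth$start + 1,
                                                  sim$truth$end))
  hit <- GenomicRanges::findOverlaps(gr_r, gr_t)
  m <- matrix(2, nrow(regions), ncol(sim$cn),
              dimnames = list(regions$region_id, colnames(sim$cn)))
  ri <- S4Vectors::queryHits(hit)
  ti <- S4Vectors::subjectHits(hit)
  sp <- split(ti, ri)
  idx <- as.integer(names(sp))
  for (j in seq_along(sp)) {
    rows <- sp[[j]]
    m[idx[j], ] <- if (length(rows) == 1) sim$cn[rows, ]
      else colMeans(sim$cn[rows, , drop = FALSE])
  }
  m
}

write_pipeline_outputs <- function(res, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_cnvr_bed(res$regions, file.path(outdir, "cnvr.bed"))
  write_matrix_tsv(res$cn, file.path(outdir, "copy_number.tsv"))
  utils::write.table(res$vst, file.path(outdir, "vst.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$confirmed, file.path(outdir, "confirmed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(res$sim$labels),
               population = unname(res$sim$labels)),
    file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_newick(res$clustering, file.path(outdir, "clustering.nwk"))
  manifest <- data.frame(
    key = c("package", "version", "seed", "max_pval", "max_q0", "min_size",
            "min_carriers", "vst_threshold"),
    value = c("cnvrpop",
              as.character(utils::packageVersion("cnvrpop")),
              config$seed, res$thresholds$max_pval, res$thresholds$max_q0,
              res$thresholds$min_size, res$thresholds$min_carriers,
              signif(res$threshold, 6))
  )
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
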