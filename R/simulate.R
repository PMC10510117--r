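#' Configuration for the two-population CNV landscape simulator
#'
#' Collects every tunable of the synthetic landscape: cohort layout, number
#' and sizes of true CNV regions, the deletion fraction, how many regions are
#' shared between the two populations versus private to one, how many are
#' strongly frequency-differentiated (and by how much), the read-depth noise,
#' and the caller-resolution boundary jitter. Defaults describe a two-breed
#' design of 10 + 10 individuals over 26 autosomes with ~5,000 regions, 69%
#' deletions, 92.5% shared regions, and 50 regions differentiated by a
#' carrier-frequency gap of at least 0.7, called at a 300 bp bin resolution.
#'
#' @param n_samples_per_pop Individuals per population.
#' @param pop_labels Two population labels; sample ids are
#'   `"<label>-<i>"`.
#' @param n_chroms Number of autosomes.
#' @param chrom_lengths Chromosome lengths in bp; default a linearly
#'   decreasing ladder from 275 Mb to 45 Mb (lets chromosome-length
#'   proportionality of region counts be probed without real karyotypes).
#' @param n_regions Number of true CNV regions.
#' @param del_fraction Fraction of regions that are deletions.
#' @param shared_fraction Fraction of regions polymorphic in both
#'   populations; the remainder are private to one population.
#' @param n_differentiated Number of regions flagged as strongly
#'   frequency-differentiated between the populations.
#' @param differentiation_gap Minimum carrier-frequency gap for
#'   differentiated regions.
#' @param size_range Region size range in bp. Sizes are drawn log-scale
#'   skewed toward small regions (median just under 10 kb).
#' @param boundary_jitter_sd SD (bp) of per-call boundary jitter, snapped to
#'   `bin_size` multiples — read-depth callers resolve breakpoints only to
#'   bins.
#' @param rd_noise_sd SD of Gaussian read-depth noise in copy-number units.
#' @param bin_size Caller bin size in bp.
#' @param pval_violation_rate Fraction of emitted calls drawn to fail the
#'   p < 0.01 quality filter.
#' @param q0_violation_rate Fraction of emitted calls drawn to fail the
#'   q0 < 0.5 filter.
#' @param decoy_rate Fraction of additional sub-1-kb decoy calls added to
#'   exercise the size filter.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output at every stage.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples_per_pop = 10, pop_labels = c("OL", "PO"),
                       n_chroms = 26, chrom_lengths = NULL,
                       n_regions = 5000, del_fraction = 0.69,
                       shared_fraction = 0.925, n_differentiated = 50,
                       differentiation_gap = 0.7,
                       size_range = c(1200, 400000),
                       boundary_jitter_sd = 300, rd_noise_sd = 0.25,
                       bin_size = 300, pval_violation_rate = 0.05,
                       q0_violation_rate = 0.05, decoy_rate = 0.05,
                       seed = 1) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- round(seq(275e6, 45e6, length.out = n_chroms) /
                             bin_size) * bin_size
  }
  stopifnot(length(pop_labels) == 2, n_samples_per_pop >= 1,
            length(chrom_lengths) == n_chroms, all(chrom_lengths > 0),
            n_regions >= 1,
            del_fraction >= 0, del_fraction <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            n_differentiated >= 0, n_differentiated <= n_regions,
            differentiation_gap > 0, differentiation_gap <= 1,
            length(size_range) == 2, size_range[1] >= bin_size,
            size_range[1] <= size_range[2],
            boundary_jitter_sd >= 0, rd_noise_sd >= 0, bin_size >= 1,
            pval_violation_rate >= 0, pval_violation_rate < 1,
            q0_violation_rate >= 0, q0_violation_rate < 1,
            decoy_rate >= 0, seed == round(seed))
  names(chrom_lengths) <- paste0("chr", seq_len(n_chroms))
  cfg <- list(n_samples_per_pop = n_samples_per_pop,
              pop_labels = pop_labels, n_chroms = n_chroms,
              chrom_lengths = chrom_lengths, n_regions = n_regions,
              del_fraction = del_fraction, shared_fraction = shared_fraction,
              n_differentiated = n_differentiated,
              differentiation_gap = differentiation_gap,
              size_range = size_range,
              boundary_jitter_sd = boundary_jitter_sd,
              rd_noise_sd = rd_noise_sd, bin_size = bin_size,
              pval_violation_rate = pval_violation_rate,
              q0_violation_rate = q0_violation_rate, decoy_rate = decoy_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Sample ids and population labels of a simulated cohort
#'
#' @param config A [sim_config()].
#' @return Named character vector mapping sample id to population label.
#' @export
sim_labels <- function(config) {
  ids <- unlist(lapply(config$pop_labels, function(p) {
    paste0(p, "-", seq_len(config$n_samples_per_pop))
  }))
  stats::setNames(rep(config$pop_labels, each = config$n_samples_per_pop),
                  ids)
}

#' Simulate the ground-truth CNV region landscape
#'
#' Places `n_regions` non-overlapping (within chromosome and svtype) regions
#' with log-scale sizes, assigns each a carrier copy number (deletions carry
#' 0 or 1 copies, duplications 3-6) and per-population carrier frequencies:
#' shared regions draw one frequency used in both populations (L-shaped,
#' bounded away from 0 so both breeds genuinely segregate them), private
#' regions a moderate frequency in one population and zero in the other, and
#' differentiated regions a near-fixation frequency in one population and a
#' frequency at least `differentiation_gap` lower in the other.
#'
#' @param config A [sim_config()].
#' @return Data.frame of truth regions sorted by (chrom, start) with columns
#'   `region_id`, `chrom`, `start`, `end` (0-based half-open), `svtype`,
#'   `carrier_cn`, per-population frequency columns `freq_<pop>`,
#'   `differentiated`, and `category`
#'   (`"shared"`/`"specific"`/`"differentiated"`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_regions
  bin <- config$bin_size
  pops <- config$pop_labels

  n_del <- round(config$del_fraction * n)
  svtype <- sample(rep(c("DEL", "DUP"), c(n_del, n - n_del)))

  n_spec <- round((1 - config$shared_fraction) * n)
  n_diff <- config$n_differentiated
  if (n_diff + n_spec > n) stop("n_differentiated plus private regions exceed n_regions")
  category <- sample(rep(c("differentiated", "specific", "shared"),
                         c(n_diff, n_spec, n - n_diff - n_spec)))

  # log-scale sizes skewed small: median just under 10 kb over [1.2, 400] kb
  lsz <- log10(config$size_range)
  size_bins <- pmax(ceiling(config$size_range[1] / bin),
                    ceiling(10^(lsz[1] + (lsz[2] - lsz[1]) *
                                  stats::rbeta(n, 1, 1.6)) / bin))

  chrom <- sample(names(config$chrom_lengths), n, replace = TRUE,
                  prob = config$chrom_lengths)

  start <- numeric(n)
  for (cs in split(seq_len(n), list(chrom = chrom, svtype = svtype))) {
    if (!length(cs)) next
    L <- config$chrom_lengths[[chrom[cs[1]]]] %/% bin
    sz <- size_bins[cs]
    free <- L - sum(sz)
    if (free < 0) {
      stop("cannot place ", length(cs), " non-overlapping regions on ",
           chrom[cs[1]], "; reduce n_regions or region sizes")
    }
    gaps <- sort(sample.int(free + 1, length(cs), replace = TRUE) - 1L)
    start[cs] <- (gaps + c(0, cumsum(sz[-length(sz)]))) * bin
  }
  end <- start + size_bins * bin

  carrier_cn <- ifelse(svtype == "DEL",
                       sample(c(1L, 0L), n, replace = TRUE, prob = c(.8, .2)),
                       sample(3:6, n, replace = TRUE,
                              prob = c(.5, .3, .1, .1)))

  # carrier frequencies by category
  f1 <- f2 <- numeric(n)
  sh <- category == "shared"
  p <- 0.1 + 0.8 * stats::rbeta(sum(sh), 1.2, 2.5)
  f1[sh] <- p; f2[sh] <- p
  sp <- category == "specific"
  psp <- stats::runif(sum(sp), 0.15, 0.35)
  side <- sample(c(TRUE, FALSE), sum(sp), replace = TRUE)
  f1[sp] <- ifelse(side, psp, 0); f2[sp] <- ifelse(side, 0, psp)
  di <- category == "differentiated"
  hi <- stats::runif(sum(di), max(0.85, config$differentiation_gap), 1)
  lo <- stats::runif(sum(di), 0, hi - config$differentiation_gap)
  side <- sample(c(TRUE, FALSE), sum(di), replace = TRUE)
  f1[di] <- ifelse(side, hi, lo); f2[di] <- ifelse(side, lo, hi)

  truth <- data.frame(chrom = chrom, start = start, end = end,
                      svtype = svtype, carrier_cn = carrier_cn,
                      f1 = f1, f2 = f2,
                      differentiated = di, category = category,
                      stringsAsFactors = FALSE)
  names(truth)[names(truth) == "f1"] <- paste0("freq_", pops[1])
  names(truth)[names(truth) == "f2"] <- paste0("freq_", pops[2])
  truth <- truth[order(chrom_rank(truth$chrom), truth$start), ]
  truth <- cbind(region_id = sprintf("R%05d", seq_len(n)), truth)
  rownames(truth) <- truth$region_id
  truth
}

#' Draw the carrier assignment for a simulated cohort
#'
#' One Bernoulli draw per (region, sample) at the sample's population
#' carrier frequency. Factored out of [emit_calls()] so that the call tables
#' and the copy-number matrix share a single carrier assignment.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The same [sim_config()].
#' @return Logical matrix regions x samples.
#' @export
draw_carriers <- function(truth, config) {
  set.seed(config$seed + 1L)
  labels <- sim_labels(config)
  freq <- as.matrix(truth[, paste0("freq_", config$pop_labels)])
  carriers <- matrix(FALSE, nrow(truth), length(labels),
                     dimnames = list(truth$region_id, names(labels)))
  for (j in seq_along(labels)) {
    p <- freq[, match(labels[j], config$pop_labels)]
    carriers[, j] <- stats::runif(nrow(truth)) < p
  }
  carriers
}

#' Emit per-sample CNV call tables from the truth landscape
#'
#' Every carrier emits one call whose boundaries are the truth boundaries
#' plus Gaussian jitter snapped to caller-bin multiples and clipped to the
#' chromosome. Call quality fields are drawn so that configurable fractions
#' of calls violate the p-value and q0 filters, and a configurable fraction
#' of sub-1-kb decoy calls is added to exercise the size filter.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The same [sim_config()].
#' @param carriers Carrier matrix from [draw_carriers()]; drawn afresh when
#'   omitted.
#' @return Named list mapping sample id to a call data.frame in the layout of
#'   [read_cnv_calls()].
#' @export
emit_calls <- function(truth, config, carriers = NULL) {
  if (is.null(carriers)) carriers <- draw_carriers(truth, config)
  set.seed(config$seed + 2L)
  bin <- config$bin_size
  labels <- sim_labels(config)
  idx <- which(carriers, arr.ind = TRUE)
  nc <- nrow(idx)
  r <- idx[, 1]
  clen <- unname(config$chrom_lengths[truth$chrom[r]])
  jit <- function(x) {
    round(stats::rnorm(nc, 0, config$boundary_jitter_sd) / bin) * bin + x
  }
  start <- pmin(pmax(jit(truth$start[r]), 0), clen - bin)
  end <- pmin(pmax(jit(truth$end[r]), bin), clen)
  end <- pmax(end, start + bin)
  draw_quality <- function(rate, lo_max, hi_min) {
    viol <- stats::runif(nc) < rate
    ifelse(viol, stats::runif(nc, hi_min, 1), stats::runif(nc, 0, lo_max))
  }
  pval <- draw_quality(config$pval_violation_rate, 0.0099, 0.01)
  q0 <- draw_quality(config$q0_violation_rate, 0.4999, 0.5)
  cn <- truth$carrier_cn[r]
  norm_rd <- pmax(0, cn / 2 + stats::rnorm(nc, 0, config$rd_noise_sd / 2))
  calls <- data.frame(
    sample_id = colnames(carriers)[idx[, 2]], chrom = truth$chrom[r],
    start = start, end = end, svtype = truth$svtype[r],
    size = end - start, norm_rd = norm_rd, pval = pval, q0 = q0,
    stringsAsFactors = FALSE
  )
  n_decoy <- round(config$decoy_rate * nc)
  if (n_decoy > 0) {
    dc <- sample(names(config$chrom_lengths), n_decoy, replace = TRUE,
                 prob = config$chrom_lengths)
    dsz <- sample(seq(bin, min(999, 3 * bin), by = bin), n_decoy,
                  replace = TRUE)
    dstart <- floor(stats::runif(n_decoy) *
                      (config$chrom_lengths[dc] - dsz) / bin) * bin
    dtype <- sample(c("DEL", "DUP"), n_decoy, replace = TRUE)
    decoys <- data.frame(
      sample_id = sample(names(labels), n_decoy, replace = TRUE),
      chrom = dc, start = dstart, end = dstart + dsz, svtype = dtype,
      size = dsz,
      norm_rd = ifelse(dtype == "DEL", 0.5, 1.5),
      pval = stats::runif(n_decoy, 0, 0.0099),
      q0 = stats::runif(n_decoy, 0, 0.4999),
      stringsAsFactors = FALSE
    )
    calls <- rbind(calls, decoys)
  }
  out <- lapply(names(labels), function(s) {
    cs <- calls[calls$sample_id == s, ]
    cs <- cs[order(chrom_rank(cs$chrom), cs$start), ]
    rownames(cs) <- NULL
    cs
  })
  stats::setNames(out, names(labels))
}

#' Emit the true-region copy-number matrix
#'
#' Each entry is the sample's underlying integer copy number (the region's
#' carrier copy number for carriers, 2 otherwise) plus Gaussian read-depth
#' noise, truncated at zero — emulating read-depth genotyping of each region
#' in each sample.
#'
#' @param truth Output of [simulate_truth()].
#' @param carriers Carrier matrix from [draw_carriers()].
#' @param config The same [sim_config()].
#' @return Numeric matrix regions x samples (rownames region ids, colnames
#'   sample ids).
#' @export
emit_copy_numbers <- function(truth, carriers, config) {
  set.seed(config$seed + 3L)
  base <- matrix(2, nrow(carriers), ncol(carriers),
                 dimnames = dimnames(carriers))
  base[carriers] <- truth$carrier_cn[row(carriers)[carriers]]
  noise <- matrix(stats::rnorm(length(base), 0, config$rd_noise_sd),
                  nrow(base), ncol(base))
  pmax(base + noise, 0)
}

#' Simulate a complete two-population CNV landscape
#'
#' Convenience wrapper running [simulate_truth()], [draw_carriers()],
#' [emit_calls()] and [emit_copy_numbers()] under one config.
#'
#' @param config A [sim_config()].
#' @return List with elements `truth`, `carriers`, `calls` (per-sample list),
#'   `cn` (copy-number matrix), `labels` (sample to population map), and
#'   `config`.
#' @export
simulate_landscape <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  carriers <- draw_carriers(truth, config)
  list(truth = truth, carriers = carriers,
       calls = emit_calls(truth, config, carriers),
       cn = emit_copy_numbers(truth, carriers, config),
       labels = sim_labels(config), config = config)
}
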