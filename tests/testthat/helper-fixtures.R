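# in-code fixtures and independent oracles shared across test files

two_pop_labels <- function(n = 10, pops = c("OL", "PO")) {
  ids <- c(paste0(pops[1], "-", seq_len(n)), paste0(pops[2], "-", seq_len(n)))
  setNames(rep(pops, each = n), ids)
}

make_calls <- function(sample_id, chrom, start, end, svtype = "DEL",
                       norm_rd = 0.5, pval = 1e-4, q0 = 0) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             svtype = svtype, size = end - start, norm_rd = norm_rd,
             pval = pval, q0 = q0, stringsAsFactors = FALSE)
}

# random calls on a small toy genome
random_calls <- function(n, chroms = paste0("chr", 1:3), chrom_len = 1e6,
                         samples = paste0("S", 1:6)) {
  start <- floor(runif(n, 0, chrom_len - 20000))
  size <- floor(runif(n, 1100, 20000))
  make_calls(sample(samples, n, replace = TRUE),
             sample(chroms, n, replace = TRUE),
             start, pmin(start + size, chrom_len),
             svtype = sample(c("DEL", "DUP"), n, replace = TRUE))
}

# per-base sweep oracle for CNVR merging: mark every covered base per
# (chrom, stratum), extract maximal runs
sweep_merge_oracle <- function(calls, chrom_len = 1e6,
                               same_type_only = TRUE) {
  stratum <- if (same_type_only) calls$svtype else rep("ALL", nrow(calls))
  out <- list()
  for (key in split(seq_len(nrow(calls)),
                    paste(calls$chrom, stratum, sep = "|"))) {
    cs <- calls[key, ]
    cov <- logical(chrom_len)
    for (i in seq_len(nrow(cs))) {
      cov[(cs$start[i] + 1):cs$end[i]] <- TRUE  # base b is index b+1
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = cs$chrom[1],
      start = starts[keep] - 1, end = ends[keep],
      svtype = if (same_type_only) cs$svtype[1] else "ALL",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start, out$svtype), ]
}

# independent two-pass variance V_ST oracle
vst_oracle <- function(values, groups) {
  var2 <- function(x) {
    m <- sum(x) / length(x)
    sum((x - m)^2) / (length(x) - 1)
  }
  vt <- var2(values)
  vs <- mean(vapply(split(values, groups), var2, numeric(1)))
  if (vt == 0) NA_real_ else (vt - vs) / vt
}

# quadratic all-pairs interval-overlap oracle
quad_overlap_oracle <- function(regions, features, min_overlap = 0) {
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (cnvrpop::norm_chrom(regions$chrom[i]) !=
          cnvrpop::norm_chrom(features$chrom[j])) next
      ov <- min(regions$end[i], features$end[j]) -
        max(regions$start[i], features$start[j])
      if (ov > min_overlap) {
        out <- rbind(out, data.frame(region_id = regions$region_id[i],
                                     feature_id = features$feature_id[j],
                                     overlap_bp = ov,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

toy_features <- function(n, chrom = "chr1", kind = "gene", prefix = "G",
                         max_pos = 1e6) {
  start <- floor(runif(n, 0, max_pos - 30000))
  end <- start + floor(runif(n, 500, 30000))
  data.frame(feature_id = paste0(prefix, seq_len(n)), kind = kind,
             chrom = chrom, start = start, end = end,
             name = paste0(prefix, seq_len(n)), trait_class = NA_character_,
             stringsAsFactors = FALSE)
}
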