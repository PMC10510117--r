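#' The V_ST copy-number differentiation statistic
#'
#' `V_ST = (V_T - V_S) / V_T`, where `V_T` is the total variance in copy
#' number across all individuals of both populations and `V_S` is the mean
#' of the within-population variances. Analogous to FST: near 0 when the
#' populations share the copy-number distribution, 1 when all variance lies
#' between populations. Both variances use the unbiased (n-1) estimator and
#' `V_S` is the unweighted mean across groups; with integer copy-number
#' configurations this convention yields exact small-denominator rationals.
#' Negative values (within-variance exceeding total) are reported as-is.
#'
#' @param values Numeric copy-number vector.
#' @param groups Population label per value; at least 2 groups with at least
#'   2 samples each.
#' @return List with `vst` (`NA` when undefined), `v_t`, `v_s`, and
#'   `defined` (`FALSE` iff `v_t == 0`, i.e. all values identical).
#' @examples
#' # ten diploid samples vs five diploid and five three-copy samples
#' vst(c(rep(2, 10), rep(2, 5), rep(3, 5)), rep(c("OL", "PO"), each = 10))
#' @export
vst <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.factor(groups)
  n_by <- table(groups)
  if (length(n_by) < 2) stop("need at least 2 groups")
  if (any(n_by < 2)) {
    stop("every group needs >= 2 samples; too few in: ",
         paste(names(n_by)[n_by < 2], collapse = ", "))
  }
  v_t <- stats::var(values)
  v_s <- mean(tapply(values, groups, stats::var))
  if (v_t == 0) {
    list(vst = NA_real_, v_t = v_t, v_s = v_s, defined = FALSE)
  } else {
    list(vst = (v_t - v_s) / v_t, v_t = v_t, v_s = v_s, defined = TRUE)
  }
}

#' Genome-wide V_ST scan over a copy-number matrix
#'
#' Applies [vst()] to every row of a regions x samples copy-number matrix.
#' Regions where all samples share one value are retained with an undefined
#' flag (and excluded from thresholding downstream).
#'
#' @param values Copy-number matrix (rows regions, columns samples).
#' @param groups Named population vector covering the matrix columns, or an
#'   unnamed vector in column order.
#' @return Data.frame with one row per region: `region_id`, `v_t`, `v_s`,
#'   `vst`, `defined`, in the matrix's (genome) row order.
#' @export
vst_scan <- function(values, groups) {
  stopifnot(is.matrix(values))
  groups <- align_groups(groups, colnames(values), ncol(values))
  g <- as.factor(groups)
  recs <- apply(values, 1, vst, groups = g)
  data.frame(
    region_id = rownames(values),
    v_t = vapply(recs, `[[`, numeric(1), "v_t"),
    v_s = vapply(recs, `[[`, numeric(1), "v_s"),
    vst = vapply(recs, `[[`, numeric(1), "vst"),
    defined = vapply(recs, `[[`, logical(1), "defined"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Nearest-rank percentile threshold
#'
#' Sorts the defined values ascending and returns the element at rank
#' `ceiling(q * n)` (no interpolation — reproducible and exact on ties).
#' Values greater than or equal to the returned threshold are "above
#' threshold".
#'
#' @param values Numeric vector; `NA`s (undefined V_ST) are dropped.
#' @param q Percentile as a fraction (default 0.98, the top-2% rule).
#' @return The threshold value.
#' @export
percentile_threshold <- function(values, q = 0.98) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no defined values to threshold")
  stopifnot(q > 0, q <= 1)
  sort(values)[ceiling(q * length(values))]
}

#' Lift region-level V_ST to genes
#'
#' Each gene overlapping at least one region (by at least 1 bp) is assigned
#' the maximum V_ST over its overlapping regions; genes overlapping no
#' region are absent from the result. Chromosome names are matched after
#' "chr"-prefix normalization.
#'
#' @param records [vst_scan()] output.
#' @param regions Region data.frame supplying coordinates for `records`.
#' @param genes Gene features ([read_features()] layout).
#' @return Data.frame `feature_id`, `name`, `chrom`, `start`, `end`, `vst`,
#'   `n_regions` for genes with at least one overlapping defined-V_ST
#'   region.
#' @export
gene_level_vst <- function(records, regions, genes) {
  stopifnot(all(records$region_id %in% regions$region_id))
  if (!nrow(genes) || !nrow(records)) {
    return(data.frame(feature_id = character(), name = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), vst = numeric(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  }
  reg <- regions[match(records$region_id, regions$region_id), ]
  gr_r <- GenomicRanges::GRanges(norm_chrom(reg$chrom),
                                 IRanges::IRanges(reg$start + 1, reg$end))
  gr_g <- GenomicRanges::GRanges(norm_chrom(genes$chrom),
                                 IRanges::IRanges(genes$start + 1,
                                                  genes$end))
  hit <- GenomicRanges::findOverlaps(gr_g, gr_r)
  if (!length(hit)) {
    return(gene_level_vst(records[0, ], regions, genes[0, ]))
  }
  gi <- S4Vectors::queryHits(hit)
  vv <- records$vst[S4Vectors::subjectHits(hit)]
  keep <- !is.na(vv)
  gi <- gi[keep]; vv <- vv[keep]
  agg <- tapply(vv, gi, max)
  idx <- as.integer(names(agg))
  n_hit <- as.integer(table(factor(gi, levels = idx)))
  data.frame(
    feature_id = genes$feature_id[idx], name = genes$name[idx],
    chrom = genes$chrom[idx], start = genes$start[idx],
    end = genes$end[idx], vst = as.numeric(agg), n_regions = n_hit,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Fixed-effects one-way ANOVA of copy number on population
#' (`F = MSB / MSE` with `(k - 1, N - k)` degrees of freedom) followed by
#' Tukey's honestly-significant-difference pairwise comparisons from the
#' studentized range distribution (via [stats::aov()] and
#' [stats::TukeyHSD()]). With two equal groups the Tukey p-value equals the
#' ANOVA p-value. When the within-group mean square is zero the F statistic
#' is reported as `Inf` with p = 0 if group means differ, and the record is
#' flagged undefined if all values are identical.
#'
#' @param values Numeric vector.
#' @param groups Group label per value, each group with at least 2 samples.
#' @return List with `F`, `p`, `df` (numerator, denominator), `tukey`
#'   (named pairwise p-values), `defined`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  n_by <- table(groups)
  if (length(n_by) < 2) stop("need at least 2 groups")
  if (any(n_by < 2)) stop("every group needs >= 2 samples")
  k <- length(n_by)
  N <- length(values)
  dfree <- c(k - 1, N - k)
  gm <- tapply(values, groups, mean)
  ssb <- sum(n_by * (gm - mean(values))^2)
  sse <- sum((values - gm[groups])^2)
  pairs <- utils::combn(names(n_by), 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  if (sse == 0) {
    if (ssb == 0) {
      return(list(F = NA_real_, p = NA_real_, df = dfree,
                  tukey = stats::setNames(rep(NA_real_, ncol(pairs)),
                                          pair_names),
                  defined = FALSE))
    }
    # zero within-group variance: any pair with differing means separates
    tk <- vapply(seq_len(ncol(pairs)), function(j) {
      if (gm[pairs[1, j]] == gm[pairs[2, j]]) 1 else 0
    }, numeric(1))
    return(list(F = Inf, p = 0, df = dfree,
                tukey = stats::setNames(tk, pair_names), defined = TRUE))
  }
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(F = tab["g", "F value"], p = tab["g", "Pr(>F)"], df = dfree,
       tukey = stats::setNames(tk[, "p adj"], rownames(tk)),
       defined = TRUE)
}

#' ANOVA/Tukey confirmation scan over matrix rows
#'
#' Runs [anova_tukey()] on every row (region or gene) of a copy-number
#' matrix — the confirmation step applied to candidates above the V_ST
#' threshold.
#'
#' @param values Copy-number matrix.
#' @param groups Named population vector covering the columns.
#' @return Data.frame `region_id`, `F`, `p`, `tukey_min` (smallest pairwise
#'   Tukey p), `defined`.
#' @export
anova_scan <- function(values, groups) {
  stopifnot(is.matrix(values))
  groups <- align_groups(groups, colnames(values), ncol(values))
  recs <- apply(values, 1, anova_tukey, groups = groups)
  data.frame(
    region_id = rownames(values),
    F = vapply(recs, `[[`, numeric(1), "F"),
    p = vapply(recs, `[[`, numeric(1), "p"),
    tukey_min = vapply(recs, function(r) {
      if (all(is.na(r$tukey))) NA_real_ else min(r$tukey, na.rm = TRUE)
    }, numeric(1)),
    defined = vapply(recs, `[[`, logical(1), "defined"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

align_groups <- function(groups, ids, n) {
  if (!is.null(names(groups)) && !is.null(ids)) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) {
      stop("sample(s) missing a population label: ",
           paste(miss, collapse = ", "))
    }
    groups <- groups[ids]
  }
  stopifnot(length(groups) == n)
  unname(groups)
}
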