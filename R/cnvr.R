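#' CNV call quality thresholds
#'
#' The call-level quality filter retains calls with p-value below `max_pval`,
#' zero-mapping-quality fraction below `max_q0`, and size above `min_size` —
#' all strict inequalities. `min_carriers` is the region-level carrier-count
#' filter applied later by [carrier_filter()].
#'
#' @param max_pval Retain calls with `pval < max_pval`.
#' @param max_q0 Retain calls with `q0 < max_q0`.
#' @param min_size Retain calls with `size > min_size` (bp).
#' @param min_carriers Region-level minimum carrier count.
#' @return List of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(max_pval = 0.01, max_q0 = 0.5,
                              min_size = 1000, min_carriers = 3) {
  stopifnot(max_pval > 0, max_q0 > 0, max_q0 <= 1, min_size >= 0,
            min_carriers >= 1)
  structure(list(max_pval = max_pval, max_q0 = max_q0, min_size = min_size,
                 min_carriers = min_carriers), class = "filter_thresholds")
}

#' Filter CNV calls on quality fields
#'
#' Applies the three strict call-level predicates (`pval < max_pval`,
#' `q0 < max_q0`, `size > min_size`), preserving input order. A call of size
#' exactly `min_size` is removed.
#'
#' @param calls Call data.frame ([read_cnv_calls()] layout) or a per-sample
#'   list of such data.frames.
#' @param thresholds A [filter_thresholds()].
#' @return Filtered calls in the same shape as the input.
#' @export
filter_calls <- function(calls, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (is.data.frame(calls)) {
    keep <- calls$pval < thresholds$max_pval &
      calls$q0 < thresholds$max_q0 &
      calls$size > thresholds$min_size
    out <- calls[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    lapply(calls, filter_calls, thresholds = thresholds)
  }
}

#' Merge per-sample CNV calls into CNV regions
#'
#' Within each chromosome (and svtype, unless `same_type_only = FALSE`),
#' every maximal set of transitively overlapping call intervals (any overlap
#' of at least 1 bp) becomes one region spanning their union — the standard
#' CNVR construction. Each region records its carrier set (the contributing
#' samples). With cross-type merging, regions built from both deletion and
#' duplication calls are labelled `"MIXED"`.
#'
#' @param calls Call data.frame or per-sample list (filtered; see
#'   [filter_calls()]).
#' @param same_type_only Merge DEL and DUP calls separately (default) or
#'   together.
#' @param chroms Optional vector of known chromosome names; calls on other
#'   chromosomes raise an error naming the chromosome.
#' @return Data.frame of regions sorted by (chrom, start): `region_id`,
#'   `chrom`, `start`, `end`, `svtype`, `n_carriers`, and a list-column
#'   `carriers` of sample ids.
#' @export
merge_calls <- function(calls, same_type_only = TRUE, chroms = NULL) {
  if (!is.data.frame(calls)) calls <- do.call(rbind, unname(calls))
  if (!is.null(chroms)) {
    bad <- setdiff(unique(calls$chrom), chroms)
    if (length(bad)) {
      stop("calls on unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
  }
  if (!nrow(calls)) return(empty_regions())
  stratum <- if (same_type_only) calls$svtype else rep("ALL", nrow(calls))
  pieces <- lapply(split(seq_len(nrow(calls)), stratum), function(i) {
    cs <- calls[i, ]
    gr <- GenomicRanges::GRanges(
      cs$chrom, IRanges::IRanges(cs$start + 1, cs$end))
    # min.gapwidth = 0: abutting calls share no base and must not merge
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, red)
    stopifnot(length(hit) == length(gr))  # every call in exactly one region
    grp <- S4Vectors::subjectHits(hit)
    carriers <- lapply(split(cs$sample_id, grp),
                       function(s) sort(unique(s)))
    types <- vapply(split(cs$svtype, grp),
                    function(t) {
                      u <- unique(t)
                      if (length(u) == 1) u else "MIXED"
                    }, character(1))
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1,
      end = GenomicRanges::end(red),
      svtype = unname(types),
      n_carriers = unname(lengths(carriers)),
      stringsAsFactors = FALSE
    )
    out$carriers <- unname(carriers)
    out
  })
  regions <- do.call(rbind, unname(pieces))
  regions <- regions[order(chrom_rank(regions$chrom), regions$start,
                           regions$svtype), ]
  regions <- cbind(region_id = sprintf("CNVR%05d", seq_len(nrow(regions))),
                   regions)
  rownames(regions) <- NULL
  regions
}

empty_regions <- function() {
  out <- data.frame(region_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), svtype = character(),
                    n_carriers = integer(), stringsAsFactors = FALSE)
  out$carriers <- list()
  out
}

#' Per-population carrier counts of CNV regions
#'
#' @param regions Region data.frame from [merge_calls()].
#' @param labels Named character vector mapping sample id to population.
#' @return Integer matrix regions x populations.
#' @export
carrier_counts <- function(regions, labels) {
  pops <- sort(unique(unname(labels)))
  m <- t(vapply(regions$carriers, function(s) {
    unknown <- setdiff(s, names(labels))
    if (length(unknown)) {
      stop("sample(s) missing a population label: ",
           paste(unknown, collapse = ", "))
    }
    table(factor(unname(labels[s]), levels = pops))
  }, integer(length(pops))))
  if (!nrow(regions)) m <- matrix(0L, 0, length(pops))
  colnames(m) <- pops
  rownames(m) <- regions$region_id
  m
}

#' Region-level carrier-count filter
#'
#' Removes likely false-positive regions carried by too few individuals.
#' Under `mode = "any_breed"` (default) a region is kept when at least one
#' population has `min_carriers` or more carriers; `"each_breed"` requires
#' it in every population.
#'
#' @param regions Region data.frame from [merge_calls()].
#' @param labels Named sample-to-population vector.
#' @param min_carriers Minimum carriers per population.
#' @param mode `"any_breed"` or `"each_breed"`.
#' @return The surviving regions.
#' @export
carrier_filter <- function(regions, labels, min_carriers = 3,
                           mode = c("any_breed", "each_breed")) {
  mode <- match.arg(mode)
  if (!nrow(regions)) return(regions)
  cc <- carrier_counts(regions, labels)
  keep <- if (mode == "any_breed") {
    apply(cc >= min_carriers, 1, any)
  } else {
    apply(cc >= min_carriers, 1, all)
  }
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition regions into shared and breed-specific sets
#'
#' A region with at least one carrier in both populations is shared; a
#' region with carriers in only one population is specific to it. The three
#' sets partition the input (Venn-diagram view of the two-breed landscape).
#'
#' @param regions Region data.frame.
#' @param labels Named sample-to-population vector.
#' @return List with `shared` (data.frame) and `specific` (named list of
#'   data.frames, one per population).
#' @export
partition_by_breed <- function(regions, labels) {
  pops <- sort(unique(unname(labels)))
  cc <- carrier_counts(regions, labels)
  both <- rowSums(cc > 0) == length(pops)
  specific <- lapply(pops, function(p) {
    only <- cc[, p] > 0 & rowSums(cc[, setdiff(pops, p), drop = FALSE]) == 0
    out <- regions[only, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  shared <- regions[both, , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared, specific = stats::setNames(specific, pops))
}

#' Summaries of a CNVR set
#'
#' Produces the descriptive tables of a two-breed CNVR landscape: counts and
#' mean sizes by svtype, a size-class histogram with bins \[1, 10) kb,
#' \[10, 50) kb and >= 50 kb, per-chromosome counts by svtype, and (when
#' chromosome lengths are supplied) the Pearson correlation between
#' chromosome length and CNVR count.
#'
#' @param regions Region data.frame.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @return List with `by_svtype`, `size_hist`, `per_chrom`, and
#'   `length_correlation` (`NA` without `chrom_lengths`).
#' @export
summarize_cnvr <- function(regions, chrom_lengths = NULL) {
  svtypes <- c("DEL", "DUP", "MIXED")
  size <- regions$end - regions$start
  sv <- factor(regions$svtype, levels = svtypes)
  by_svtype <- data.frame(
    svtype = svtypes,
    n = as.integer(table(sv)),
    mean_size = as.numeric(tapply(size, sv, mean)[svtypes])
  )
  cls <- cut(size / 1000, c(-Inf, 10, 50, Inf), right = FALSE,
             labels = c("[1,10)kb", "[10,50)kb", ">=50kb"))
  size_hist <- as.data.frame.matrix(table(cls, sv))
  size_hist <- cbind(size_class = rownames(size_hist), size_hist,
                     stringsAsFactors = FALSE)
  rownames(size_hist) <- NULL
  chroms <- if (is.null(chrom_lengths)) unique(regions$chrom)
    else names(chrom_lengths)
  per_chrom <- as.data.frame.matrix(
    table(factor(regions$chrom, levels = chroms), sv))
  per_chrom <- cbind(chrom = rownames(per_chrom), per_chrom,
                     total = rowSums(per_chrom), stringsAsFactors = FALSE)
  rownames(per_chrom) <- NULL
  length_correlation <- NA_real_
  if (!is.null(chrom_lengths) && length(chrom_lengths) >= 3) {
    length_correlation <- stats::cor(unname(chrom_lengths),
                                     per_chrom$total)
  }
  list(by_svtype = by_svtype, size_hist = size_hist, per_chrom = per_chrom,
       length_correlation = length_correlation)
}
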