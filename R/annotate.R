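#' Intersect CNVRs with genomic features
#'
#' Records every (region, feature) pair whose intervals overlap by strictly
#' more than `min_overlap` bp. The defaults reflect the two annotation
#' rules of the pipeline: gene assignment uses any overlap
#' (`min_overlap = 0`, i.e. >= 1 bp) while QTL overlap requires more than
#' 1 kb (`min_overlap = 1000`). Chromosome names are matched after
#' "chr"-prefix normalization; overlaps are found by a sorted interval
#' sweep (\pkg{GenomicRanges}).
#'
#' @param regions Region data.frame (`region_id`, `chrom`, `start`, `end`).
#' @param features Feature data.frame from [read_features()].
#' @param min_overlap Strict lower bound on the overlap width in bp.
#' @return Data.frame with one row per qualifying pair: `region_id`,
#'   `feature_id`, `kind`, `name`, `overlap_bp`, `trait_class`.
#' @export
intersect_features <- function(regions, features, min_overlap = 0) {
  stopifnot(min_overlap >= 0)
  empty <- data.frame(region_id = character(), feature_id = character(),
                      kind = character(), name = character(),
                      overlap_bp = numeric(), trait_class = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(features)) return(empty)
  gr_r <- GenomicRanges::GRanges(norm_chrom(regions$chrom),
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
  gr_f <- GenomicRanges::GRanges(norm_chrom(features$chrom),
                                 IRanges::IRanges(features$start + 1,
                                                  features$end))
  hit <- GenomicRanges::findOverlaps(gr_r, gr_f)
  if (!length(hit)) return(empty)
  ri <- S4Vectors::queryHits(hit)
  fi <- S4Vectors::subjectHits(hit)
  ov <- GenomicRanges::width(IRanges::pintersect(gr_r[ri], gr_f[fi]))
  keep <- ov > min_overlap
  data.frame(
    region_id = regions$region_id[ri[keep]],
    feature_id = features$feature_id[fi[keep]],
    kind = features$kind[fi[keep]],
    name = features$name[fi[keep]],
    overlap_bp = ov[keep],
    trait_class = features$trait_class[fi[keep]],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Tabulate region/feature overlap counts
#'
#' Summaries supporting statements like "how many CNVRs are annotated to
#' exactly one gene": per-region feature counts and per-feature region
#' counts from an [intersect_features()] table.
#'
#' @param overlaps Output of [intersect_features()].
#' @return List with `per_region` (data.frame `region_id`, `n_features`)
#'   and `per_feature` (data.frame `feature_id`, `n_regions`).
#' @export
overlap_counts <- function(overlaps) {
  pr <- as.data.frame(table(region_id = overlaps$region_id),
                      stringsAsFactors = FALSE)
  names(pr)[2] <- "n_features"
  pf <- as.data.frame(table(feature_id = overlaps$feature_id),
                      stringsAsFactors = FALSE)
  names(pf)[2] <- "n_regions"
  list(per_region = pr, per_feature = pf)
}

#' Hypergeometric over-representation test
#'
#' One-sided over-representation of each gene set among a hit list: with
#' `N` universe genes of which `K` carry the term, and `k` hits among the
#' `n` selected genes, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the exact tail sum
#' `sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)` (computed via
#' [stats::phyper()]). Terms with `p < alpha` are flagged; no multiple-
#' testing correction is applied by default (a Benjamini-Hochberg column is
#' available via `adjust`).
#'
#' @param hit_genes Character vector of selected genes (subset of
#'   `universe`).
#' @param gene_sets Named list mapping term to character vector of genes.
#' @param universe Character vector of all genes considered.
#' @param alpha Significance level for the flag.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @return Data.frame per term: `term`, `K` (term size in universe), `k`
#'   (hits in term), `n` (number of hits), `N` (universe size), `p`,
#'   `significant`, and optionally `p_adj`.
#' @export
overrepresentation <- function(hit_genes, gene_sets, universe,
                               alpha = 0.05, adjust = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  hit_genes <- unique(hit_genes)
  extra <- setdiff(hit_genes, universe)
  if (length(extra)) {
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(set)
    k <- length(intersect(hit_genes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, K = K, k = k, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), K = integer(), k = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p < alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
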