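#' Read-depth copy-number genotyping
#'
#' The standard read-depth genotyping rule: the copy number of a region is
#' twice its mean normalized read depth relative to the genome-wide mean,
#' `CN = 2 * region_mean_rd / global_mean_rd`. A region at the genome
#' average is diploid (CN 2); at half the average, CN 1.
#'
#' @param region_mean_rd Mean read depth over the region (vectorized).
#' @param global_mean_rd Genome-wide mean read depth (positive scalar or
#'   vector recycled against `region_mean_rd`).
#' @return Copy-number estimate(s).
#' @export
genotype_from_rd <- function(region_mean_rd, global_mean_rd) {
  if (any(global_mean_rd <= 0)) stop("global_mean_rd must be positive")
  if (any(region_mean_rd < 0)) stop("region_mean_rd must be non-negative")
  2 * region_mean_rd / global_mean_rd
}

#' Assemble the regions x samples copy-number matrix
#'
#' Builds the matrix consumed by the differentiation scan from a long table
#' of per-(region, sample) copy-number estimates. Cells without an estimate
#' default to the autosomal diploid baseline of 2. Rows are ordered by
#' genome position, columns by the given sample order.
#'
#' @param regions Region data.frame (`region_id`, `chrom`, `start`, ...).
#' @param samples Character vector of sample ids (column order).
#' @param cn_source Optional data.frame with columns `region_id`,
#'   `sample_id`, `cn`.
#' @param labels Optional named sample-to-population vector; when given,
#'   every sample must have a label.
#' @param default_cn Value for cells absent from `cn_source`.
#' @param round_cn Round estimates to integers (reproduces exact rational
#'   V_ST values from integer copy-number configurations).
#' @return Numeric matrix regions x samples.
#' @export
build_matrix <- function(regions, samples, cn_source = NULL, labels = NULL,
                         default_cn = 2, round_cn = FALSE) {
  if (!is.null(labels)) {
    miss <- setdiff(samples, names(labels))
    if (length(miss)) {
      stop("sample(s) missing a population label: ",
           paste(miss, collapse = ", "))
    }
  }
  o <- order(chrom_rank(regions$chrom), regions$start)
  ids <- regions$region_id[o]
  m <- matrix(default_cn, length(ids), length(samples),
              dimnames = list(ids, samples))
  if (!is.null(cn_source) && nrow(cn_source)) {
    stopifnot(all(c("region_id", "sample_id", "cn") %in% names(cn_source)))
    ri <- match(cn_source$region_id, ids)
    ci <- match(cn_source$sample_id, samples)
    keep <- !is.na(ri) & !is.na(ci)
    m[cbind(ri[keep], ci[keep])] <- cn_source$cn[keep]
  }
  if (round_cn) m <- round(m)
  stopifnot(all(m >= 0))
  m
}
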