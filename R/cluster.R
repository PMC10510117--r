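#' CNVR presence/absence matrix
#'
#' The 0/1 scoring matrix used for sample clustering: entry (region, sample)
#' is 1 iff the sample carries the region. Rows follow the genome order of
#' `regions`; columns follow `samples`. A sample carrying no region at all
#' gets a zero column with a warning.
#'
#' @param regions Region data.frame from [merge_calls()] (with the
#'   `carriers` list-column).
#' @param samples Character vector of sample ids.
#' @return Integer 0/1 matrix regions x samples.
#' @export
presence_matrix <- function(regions, samples) {
  m <- matrix(0L, nrow(regions), length(samples),
              dimnames = list(regions$region_id, samples))
  for (i in seq_len(nrow(regions))) {
    hit <- match(regions$carriers[[i]], samples)
    m[i, hit[!is.na(hit)]] <- 1L
  }
  empty <- colSums(m) == 0
  if (any(empty) && nrow(regions)) {
    warning("sample(s) carry no region: ",
            paste(samples[empty], collapse = ", "))
  }
  m
}

#' Pairwise distances between samples on a binary matrix
#'
#' Distances over the columns (samples) of a presence/absence matrix.
#' Jaccard distance is `1 - |intersection| / |union|` over the regions
#' present in either sample (0 when both samples are all-zero); euclidean
#' and correlation (`1 - r`) are available for sensitivity analysis.
#'
#' @param m Binary matrix (rows features, columns samples).
#' @param metric `"jaccard"`, `"euclidean"` or `"correlation"`.
#' @return A `dist` object over samples.
#' @export
binary_distance <- function(m, metric = c("jaccard", "euclidean",
                                          "correlation")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(m), ncol(m) >= 2)
  if (metric == "euclidean") return(stats::dist(t(m)))
  if (metric == "correlation") {
    d <- 1 - stats::cor(m)
    d[is.na(d)] <- 0
    return(stats::as.dist(d))
  }
  inter <- crossprod(m)
  tot <- colSums(m)
  union <- outer(tot, tot, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  stats::as.dist(d)
}

#' UPGMA (average-linkage) clustering
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters, with the distance from a merged
#' cluster to any other equal to the size-weighted mean of its members'
#' distances; merge heights are recorded and non-decreasing toward the
#' root. Delegates to [stats::hclust()] with `method = "average"`.
#'
#' @param d A `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @return An `hclust` object.
#' @export
upgma <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      stop("distance matrix must be symmetric with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  stopifnot(inherits(d, "dist"))
  stats::hclust(d, method = "average")
}

#' Member sets and heights of a dendrogram's internal edges
#'
#' Each internal node (cluster) of an `hclust` tree is identified by the
#' sorted set of leaf labels under it — the identity used to match clusters
#' across bootstrap trees.
#'
#' @param hc An `hclust` object with labels.
#' @return List with one element per merge: `members` (sorted labels) and
#'   `height`.
#' @export
tree_edges <- function(hc) {
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_along(hc$order))
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labs[-j] else members[[j]]$members
    members[[i]] <- list(
      members = sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))),
      height = hc$height[i]
    )
  }
  members
}

edge_keys <- function(hc) {
  vapply(tree_edges(hc), function(e) paste(e$members, collapse = "\r"),
         character(1))
}

#' Multiscale bootstrap support for CNVR presence/absence clustering
#'
#' Clusters samples by UPGMA on a binary regions x samples matrix and
#' attaches two support values to every cluster: the ordinary bootstrap
#' probability BP and the approximately unbiased p-value AU estimated by
#' multiscale bootstrap. For each scale factor `r` in `r_grid`, `nboot`
#' resamples of `round(r * n_rows)` rows are drawn with replacement, the
#' samples reclustered, and `BP_r` recorded as the fraction of resampled
#' trees containing the cluster (matched by member set). For each cluster
#' the probit-transformed supports `z_r = qnorm(1 - BP_r)` are fitted by
#' weighted least squares to `z_r = v * sqrt(r) + c / sqrt(r)` (weights the
#' inverse sampling variances of `z_r`; `BP_r` saturated at 0 or 1 is
#' clamped `1/(2 * nboot)` from the boundary), giving the signed-distance
#' and curvature parameters `v` and `c` and the supports
#' `AU = 1 - pnorm(v - c)` and `BP = 1 - pnorm(v + c)`.
#'
#' Clusters observed at fewer than two non-saturated scales (including the
#' trivial case `r_grid = 1.0` only, where AU degenerates to the counted
#' BP) are flagged `degenerate` and report the clamped BP at the scale
#' closest to 1.
#'
#' @param m Binary matrix (rows regions resampled, columns samples
#'   clustered), at least 3 samples and 2 rows.
#' @param r_grid Scale factors (default 0.5 to 1.4 in steps of 0.1).
#' @param nboot Bootstrap replicates per scale.
#' @param metric Distance metric, see [binary_distance()].
#' @param seed Integer seed; same seed reproduces every support value
#'   exactly.
#' @return List of class `"msboot"`: `hclust` (the observed tree), `edges`
#'   (data.frame with `members` list-column, `height`, `au`, `bp`,
#'   `bp_raw` — counted BP at the scale nearest 1 — `fit_v`, `fit_c`,
#'   `degenerate`), `bp_table` (edges x scales raw BP), `r_grid`, `nboot`.
#' @export
multiscale_bootstrap <- function(m, r_grid = seq(0.5, 1.4, by = 0.1),
                                 nboot = 1000,
                                 metric = c("jaccard", "euclidean",
                                            "correlation"),
                                 seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(m), ncol(m) >= 3, nrow(m) >= 2, nboot >= 1,
            length(r_grid) >= 1, all(r_grid > 0))
  if (!is.null(seed)) set.seed(seed)
  hc <- upgma(binary_distance(m, metric))
  keys <- edge_keys(hc)
  n_edges <- length(keys)
  n_rows <- nrow(m)

  bp_table <- matrix(0, n_edges, length(r_grid),
                     dimnames = list(NULL, sprintf("r=%g", r_grid)))
  for (si in seq_along(r_grid)) {
    n_star <- max(2L, round(r_grid[si] * n_rows))
    hits <- numeric(n_edges)
    for (b in seq_len(nboot)) {
      mb <- m[sample.int(n_rows, n_star, replace = TRUE), , drop = FALSE]
      kb <- edge_keys(upgma(binary_distance(mb, metric)))
      hits <- hits + (keys %in% kb)
    }
    bp_table[, si] <- hits / nboot
  }

  eps <- 1 / (2 * nboot)
  r_near1 <- which.min(abs(r_grid - 1))
  fit_v <- fit_c <- au <- bp <- numeric(n_edges)
  degenerate <- logical(n_edges)
  for (e in seq_len(n_edges)) {
    raw <- bp_table[e, ]
    usable <- raw > 0 & raw < 1
    clamped <- pmin(pmax(raw, eps), 1 - eps)
    if (sum(usable) < 2 || length(r_grid) < 2) {
      degenerate[e] <- TRUE
      au[e] <- clamped[r_near1]
      bp[e] <- clamped[r_near1]
      fit_v[e] <- NA_real_; fit_c[e] <- NA_real_
      next
    }
    z <- stats::qnorm(1 - clamped)
    # delta-method variance of z_r; inverse as WLS weight
    w <- nboot * stats::dnorm(z)^2 / (clamped * (1 - clamped))
    X <- cbind(sqrt(r_grid), 1 / sqrt(r_grid))
    coef <- stats::lm.wfit(X, z, w)$coefficients
    fit_v[e] <- coef[1]; fit_c[e] <- coef[2]
    au[e] <- 1 - stats::pnorm(coef[1] - coef[2])
    bp[e] <- 1 - stats::pnorm(coef[1] + coef[2])
  }

  edges <- tree_edges(hc)
  edf <- data.frame(height = vapply(edges, `[[`, numeric(1), "height"),
                    au = au, bp = bp, bp_raw = bp_table[, r_near1],
                    fit_v = fit_v, fit_c = fit_c, degenerate = degenerate)
  edf$members <- lapply(edges, `[[`, "members")
  # the all-samples root is in every tree: support 1 by convention
  root <- which(vapply(edf$members, length, integer(1)) == ncol(m))
  edf$au[root] <- 1; edf$bp[root] <- 1; edf$degenerate[root] <- FALSE
  structure(list(hclust = hc, edges = edf, bp_table = bp_table,
                 r_grid = r_grid, nboot = nboot, metric = metric),
            class = "msboot")
}

#' @export
print.msboot <- function(x, ...) {
  cat("Multiscale-bootstrap UPGMA clustering (", x$metric, " distance)\n",
      sep = "")
  cat("  ", length(x$hclust$labels), " samples, ", x$nboot,
      " resamples at ", length(x$r_grid), " scales\n", sep = "")
  sizes <- vapply(x$edges$members, length, integer(1))
  df <- data.frame(size = sizes, height = round(x$edges$height, 4),
                   au = round(x$edges$au, 3), bp = round(x$edges$bp, 3))
  print(df)
  invisible(x)
}

#' Serialize a supported dendrogram as Newick
#'
#' Writes the UPGMA tree with `au|bp` support annotations as internal node
#' labels, in plain Newick. Branch lengths are derived from merge heights.
#'
#' @param x An `"msboot"` object from [multiscale_bootstrap()].
#' @param path Output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "msboot"))
  hc <- x$hclust
  lab <- hc$labels
  build <- function(j, parent_h) {
    if (j < 0) {
      return(sprintf("%s:%.6g", lab[-j], parent_h))
    }
    l <- build(hc$merge[j, 1], hc$height[j])
    r <- build(hc$merge[j, 2], hc$height[j])
    sprintf("(%s,%s)%.3f|%.3f:%.6g", l, r, x$edges$au[j], x$edges$bp[j],
            parent_h - hc$height[j])
  }
  n <- nrow(hc$merge)
  nwk <- paste0(sub(":[^:]*$", "", build(n, hc$height[n])), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
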