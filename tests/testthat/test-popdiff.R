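two_groups <- rep(c("OL", "PO"), each = 10)

test_that("integer copy-number configurations give exact rational V_ST", {
  # ten diploids vs five diploids + five triploids -> 8/27
  r1 <- vst(c(rep(2, 10), rep(2, 5), rep(3, 5)), two_groups)
  expect_equal(r1$vst, 8 / 27, tolerance = 1e-12)
  expect_equal(round(r1$vst, 6), 0.296296)
  # ten diploids vs four diploids + six haploids -> 25/63
  r2 <- vst(c(rep(2, 10), rep(2, 4), rep(1, 6)), two_groups)
  expect_equal(r2$vst, 25 / 63, tolerance = 1e-12)
  expect_equal(round(r2$vst, 6), 0.396825)
  # zero within-group variance with differing means -> exactly 1
  r3 <- vst(c(rep(2, 10), rep(4, 10)), two_groups)
  expect_equal(r3$vst, 1)
})

test_that("V_ST domain rules: undefined at zero total variance, group size checks", {
  r <- vst(rep(2, 20), two_groups)
  expect_false(r$defined)
  expect_true(is.na(r$vst))
  expect_error(vst(1:5, c("a", "a", "a", "a", "b")), "2 samples")
  expect_error(vst(1:4, rep("a", 4)), "2 groups")
})

test_that("V_ST agrees with an independent two-pass oracle and is affine-invariant", {
  set.seed(41)
  for (i in 1:200) {
    v <- runif(20, 0, 5)
    r <- vst(v, two_groups)
    expect_lt(abs(r$vst - vst_oracle(v, two_groups)), 1e-12)
    expect_lte(r$vst, 1)
    a <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    b <- runif(1, -2, 2)
    expect_equal(vst(a * v + b, two_groups)$vst, r$vst, tolerance = 1e-9)
  }
})

test_that("the scan maps rows to records and ignores sample order", {
  m <- rbind(R1 = c(rep(2, 10), rep(2, 5), rep(3, 5)),
             R2 = c(rep(2, 10), rep(2, 4), rep(1, 6)),
             R3 = rep(2, 20))
  colnames(m) <- names(two_pop_labels())
  scan <- vst_scan(m, two_pop_labels())
  expect_equal(round(scan$vst[1:2], 6), c(0.296296, 0.396825))
  expect_false(scan$defined[3])
  perm <- sample(ncol(m))
  scan2 <- vst_scan(m[, perm], two_pop_labels())
  expect_equal(scan2$vst, scan$vst)

  const <- matrix(2, 3, 20, dimnames = list(paste0("R", 1:3), colnames(m)))
  expect_true(all(!vst_scan(const, two_pop_labels())$defined))
})

test_that("percentile threshold is nearest-rank without interpolation", {
  expect_equal(percentile_threshold(seq(0.01, 1, by = 0.01), 0.98), 0.98)
  expect_equal(percentile_threshold(0.42, 0.98), 0.42)
  expect_error(percentile_threshold(NA_real_), "no defined")
  # counting check against a sort oracle: top 2% of 1000 distinct values
  set.seed(42)
  v <- runif(1000)
  thr <- percentile_threshold(v, 0.98)
  expect_equal(sum(v > thr), 20)       # strictly above the rank-980 element
  expect_true(sum(v >= thr) %in% c(20, 21))
})

test_that("gene-level V_ST takes the max over overlapping regions", {
  reg <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                    start = c(1000, 8000), end = c(5000, 12000),
                    svtype = "DEL", n_carriers = 3L,
                    stringsAsFactors = FALSE)
  recs <- data.frame(region_id = c("r1", "r2"), v_t = 1, v_s = 1,
                     vst = c(0.1, 0.4), defined = TRUE,
                     stringsAsFactors = FALSE)
  genes <- data.frame(feature_id = c("gA", "gB", "gC"), kind = "gene",
                      chrom = c("1", "chr1", "chr1"),
                      start = c(4000, 900, 50000),
                      end = c(9000, 1500, 60000),
                      name = c("A", "B", "C"),
                      trait_class = NA_character_, stringsAsFactors = FALSE)
  gl <- gene_level_vst(recs, reg, genes)
  expect_equal(gl$vst[gl$feature_id == "gA"], 0.4)  # max of 0.1, 0.4
  expect_equal(gl$vst[gl$feature_id == "gB"], 0.1)
  expect_false("gC" %in% gl$feature_id)             # no overlapping region
})

test_that("one-way ANOVA matches the closed form and is symmetric", {
  v <- c(rep(2, 10), rep(2, 5), rep(3, 5))
  r <- anova_tukey(v, two_groups)
  expect_equal(r$F, 9)
  expect_equal(r$df, c(1, 18))
  # MSB = 1.25, MSE = 2.5/18
  expect_equal(r$p, stats::pf(9, 1, 18, lower.tail = FALSE))
  swapped <- c(v[11:20], v[1:10])
  expect_equal(anova_tukey(swapped, two_groups)$F, r$F)
})

test_that("for two groups Tukey p equals ANOVA p and q equals sqrt(2)|t|", {
  set.seed(43)
  for (i in 1:50) {
    v <- rnorm(20, 2, 0.5)
    r <- anova_tukey(v, two_groups)
    expect_lt(abs(r$tukey[[1]] - r$p), 1e-6)
    tt <- stats::t.test(v[1:10], v[11:20], var.equal = TRUE)
    q <- sqrt(2) * abs(unname(tt$statistic))
    expect_equal(r$tukey[[1]],
                 stats::ptukey(q, 2, 18, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("Tukey p-values match a direct studentized-range computation for k = 3", {
  set.seed(44)
  g3 <- rep(c("a", "b", "c"), c(6, 8, 5))
  for (i in 1:20) {
    v <- rnorm(length(g3), 2, 0.4)
    r <- anova_tukey(v, g3)
    gm <- tapply(v, g3, mean)
    n_by <- table(g3)
    mse <- sum((v - gm[g3])^2) / (length(v) - 3)
    for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
      se <- sqrt(mse / 2 * (1 / n_by[pair[1]] + 1 / n_by[pair[2]]))
      q <- abs(gm[pair[1]] - gm[pair[2]]) / se
      p_direct <- unname(stats::ptukey(q, 3, length(v) - 3,
                                       lower.tail = FALSE))
      expect_equal(unname(r$tukey[[paste(pair, collapse = "-")]]), p_direct,
                   tolerance = 1e-8)
    }
  }
})

test_that("degenerate variance structures are handled explicitly", {
  r_inf <- anova_tukey(c(rep(2, 10), rep(3, 10)), two_groups)
  expect_equal(r_inf$F, Inf)
  expect_equal(r_inf$p, 0)
  r_na <- anova_tukey(rep(2, 20), two_groups)
  expect_false(r_na$defined)
})
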