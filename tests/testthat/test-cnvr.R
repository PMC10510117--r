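test_that("call filter applies the three strict predicates", {
  # crossed fixture over the three predicates
  fx <- expand.grid(pval = c(0.001, 0.5), q0 = c(0.1, 0.9),
                    size = c(500, 5000))
  calls <- make_calls("S1", "chr1", 1000, 1000 + fx$size,
                      pval = fx$pval, q0 = fx$q0)
  kept <- filter_calls(calls, filter_thresholds())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$pval, 0.001)
  expect_equal(kept$q0, 0.1)
  expect_equal(kept$size, 5000)

  # boundary: size exactly 1000 is removed (strict >)
  boundary <- make_calls("S1", "chr1", 0, 1000)
  expect_equal(nrow(filter_calls(boundary)), 0)
  expect_equal(nrow(filter_calls(make_calls("S1", "chr1", 0, 1001))), 1)

  # vacuous thresholds return the input unchanged
  vac <- filter_thresholds(max_pval = 1, max_q0 = 1, min_size = 0)
  shuffled <- calls[sample(nrow(calls)), ]
  rownames(shuffled) <- NULL
  expect_equal(filter_calls(shuffled, vac), shuffled)
})

test_that("overlapping same-type calls merge into one region spanning the union", {
  calls <- rbind(make_calls("A", "chr1", 1000, 5000),
                 make_calls("B", "chr1", 4000, 9000))
  reg <- merge_calls(calls)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1000)
  expect_equal(reg$end, 9000)
  expect_equal(reg$n_carriers, 2L)
  expect_setequal(reg$carriers[[1]], c("A", "B"))
})

test_that("DEL and DUP strata merge separately unless cross-type merging is on", {
  calls <- rbind(make_calls("A", "chr1", 1000, 2000, "DEL"),
                 make_calls("B", "chr1", 1500, 3000, "DUP"))
  reg <- merge_calls(calls, same_type_only = TRUE)
  expect_equal(nrow(reg), 2)
  expect_setequal(reg$svtype, c("DEL", "DUP"))
  mixed <- merge_calls(calls, same_type_only = FALSE)
  expect_equal(nrow(mixed), 1)
  expect_equal(mixed$svtype, "MIXED")
})

test_that("abutting calls sharing no base do not merge", {
  calls <- rbind(make_calls("A", "chr1", 1000, 2000),
                 make_calls("B", "chr1", 2000, 3000))
  expect_equal(nrow(merge_calls(calls)), 2)
  # one base of overlap suffices
  calls$end[1] <- 2001
  expect_equal(nrow(merge_calls(calls)), 1)
})

test_that("merging matches the per-base sweep oracle on random instances", {
  set.seed(21)
  for (i in 1:20) {
    calls <- random_calls(60)
    got <- merge_calls(calls)
    exp <- sweep_merge_oracle(calls)
    expect_equal(got$chrom, exp$chrom)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$svtype, exp$svtype)
  }
})

test_that("merging is idempotent and conserves every input interval", {
  set.seed(22)
  calls <- random_calls(80)
  reg <- merge_calls(calls)
  pseudo <- make_calls("X", reg$chrom, reg$start, reg$end,
                       svtype = reg$svtype)
  again <- merge_calls(pseudo)
  expect_equal(again[, c("chrom", "start", "end", "svtype")],
               reg[, c("chrom", "start", "end", "svtype")])
  # every call is contained in exactly one region of its stratum
  for (i in seq_len(nrow(calls))) {
    host <- reg$chrom == calls$chrom[i] & reg$svtype == calls$svtype[i] &
      reg$start <= calls$start[i] & reg$end >= calls$end[i]
    expect_equal(sum(host), 1)
  }
})

test_that("calls on unknown chromosomes are rejected by name", {
  calls <- make_calls("A", "chrUn", 0, 2000)
  expect_error(merge_calls(calls, chroms = paste0("chr", 1:26)), "chrUn")
})

test_that("carrier filter distinguishes any-breed from each-breed", {
  labels <- two_pop_labels(5)
  reg <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                    start = c(0, 10000), end = c(5000, 15000),
                    svtype = "DEL", n_carriers = c(6L, 3L),
                    stringsAsFactors = FALSE)
  reg$carriers <- list(c(paste0("OL-", 1:2), paste0("PO-", 1:4)),
                       paste0("OL-", 1:3))
  any_kept <- carrier_filter(reg, labels, 3, "any_breed")
  expect_setequal(any_kept$region_id, c("r1", "r2"))
  each_kept <- carrier_filter(reg, labels, 3, "each_breed")
  expect_equal(nrow(each_kept), 0)
  expect_error(carrier_filter(reg, labels, 3, "both"), "arg")
})

test_that("carrier filter equals a brute-force recount on simulated regions", {
  sim <- simulate_landscape(sim_config(n_regions = 120, seed = 13))
  reg <- merge_calls(filter_calls(sim$calls))
  kept <- carrier_filter(reg, sim$labels, 3, "any_breed")
  manual <- vapply(reg$carriers, function(s) {
    counts <- table(sim$labels[s])
    any(counts >= 3)
  }, logical(1))
  expect_setequal(kept$region_id, reg$region_id[manual])
})

test_that("breed partition is a true partition", {
  labels <- two_pop_labels(5)
  reg <- data.frame(region_id = paste0("r", 1:3), chrom = "chr1",
                    start = c(0, 10000, 20000),
                    end = c(5000, 15000, 25000), svtype = "DEL",
                    n_carriers = c(5L, 2L, 1L), stringsAsFactors = FALSE)
  reg$carriers <- list(paste0("OL-", 1:5),
                       c("OL-1", "PO-1"),
                       "PO-2")
  p <- partition_by_breed(reg, labels)
  expect_equal(p$specific$OL$region_id, "r1")
  expect_equal(p$shared$region_id, "r2")
  expect_equal(p$specific$PO$region_id, "r3")
  expect_equal(nrow(p$shared) + sum(vapply(p$specific, nrow, integer(1))),
               nrow(reg))

  sim <- simulate_landscape(sim_config(n_regions = 150, seed = 14))
  reg <- carrier_filter(merge_calls(filter_calls(sim$calls)), sim$labels)
  p <- partition_by_breed(reg, sim$labels)
  expect_equal(nrow(p$shared) + sum(vapply(p$specific, nrow, integer(1))),
               nrow(reg))
})

test_that("summaries report size classes, per-chromosome counts and length correlation", {
  reg <- data.frame(region_id = paste0("r", 1:3), chrom = "chr1",
                    start = 0, end = c(2000, 20000, 200000),
                    svtype = "DEL", n_carriers = 3L,
                    stringsAsFactors = FALSE)
  reg$carriers <- rep(list("S1"), 3)
  s <- summarize_cnvr(reg)
  expect_equal(s$size_hist$DEL, c(1, 1, 1))
  expect_equal(s$size_hist$DUP, c(0, 0, 0))
  expect_equal(s$by_svtype$n, c(3L, 0L, 0L))

  sim <- simulate_landscape(sim_config(n_regions = 800, seed = 15))
  reg <- carrier_filter(merge_calls(filter_calls(sim$calls)), sim$labels)
  s <- summarize_cnvr(reg, sim$config$chrom_lengths)
  expect_gt(s$length_correlation, 0.5)
})
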