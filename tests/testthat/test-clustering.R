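test_that("presence matrix is the exact carriage indicator", {
  reg <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                    start = c(0, 10000), end = c(5000, 15000),
                    svtype = "DEL", n_carriers = c(1L, 2L),
                    stringsAsFactors = FALSE)
  reg$carriers <- list("A", c("A", "B"))
  m <- presence_matrix(reg, c("A", "B"))
  expect_equal(m["r1", ], c(A = 1L, B = 0L))
  expect_equal(m["r2", ], c(A = 1L, B = 1L))
  expect_warning(presence_matrix(reg, c("A", "B", "C")), "C")
})

test_that("column sums equal per-sample carried-region recounts", {
  sim <- simulate_landscape(sim_config(n_regions = 100, seed = 23))
  reg <- carrier_filter(merge_calls(filter_calls(sim$calls)), sim$labels)
  m <- presence_matrix(reg, names(sim$labels))
  manual <- vapply(names(sim$labels), function(s) {
    sum(vapply(reg$carriers, function(cc) s %in% cc, logical(1)))
  }, numeric(1))
  expect_equal(colSums(m), manual)
})

test_that("jaccard distance follows shared-over-union on binary profiles", {
  m <- cbind(X = c(1, 1, 0, 0), Y = c(1, 1, 1, 0), Z = c(0, 0, 0, 1))
  d <- as.matrix(binary_distance(m, "jaccard"))
  expect_equal(d["X", "Y"], 1 / 3)   # 2 shared of 3 present
  expect_equal(d["X", "Z"], 1)       # disjoint
  expect_equal(d["X", "X"], 0)
  m2 <- cbind(A = c(1, 0), B = c(1, 0), C = c(0, 0), D = c(0, 0))
  d2 <- as.matrix(binary_distance(m2, "jaccard"))
  expect_equal(d2["A", "B"], 0)      # identical
  expect_equal(d2["C", "D"], 0)      # both all-zero by convention
  expect_error(binary_distance(m, "hamming"), "arg")
})

test_that("UPGMA reproduces the hand-executed three-sample merge", {
  d <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  d["X", "Y"] <- d["Y", "X"] <- 1 / 3
  d["X", "Z"] <- d["Z", "X"] <- 1
  d["Y", "Z"] <- d["Z", "Y"] <- 0.75
  hc <- upgma(d)
  edges <- tree_edges(hc)
  expect_equal(edges[[1]]$members, c("X", "Y"))
  expect_equal(edges[[1]]$height, 1 / 3)
  expect_equal(edges[[2]]$members, c("X", "Y", "Z"))
  expect_equal(edges[[2]]$height, (1 + 0.75) / 2)

  d2 <- as.dist(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                       dimnames = list(c("A", "B"), c("A", "B"))))
  hc2 <- upgma(d2)
  expect_equal(tree_edges(hc2)[[1]]$height, 0.4)

  bad <- matrix(runif(9), 3, 3)
  expect_error(upgma(bad), "symmetric")
})

test_that("UPGMA heights are monotone non-decreasing toward the root", {
  set.seed(24)
  for (i in 1:20) {
    d <- matrix(0, 8, 8, dimnames = list(paste0("S", 1:8), paste0("S", 1:8)))
    d[lower.tri(d)] <- runif(28)
    d <- d + t(d)
    hc <- upgma(d)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("saturated clusters get full support; all supports lie in [0, 1]", {
  set.seed(25)
  m <- matrix(0L, 40, 9,
              dimnames = list(NULL, paste0("S", 1:9)))
  m[1:20, 1:4] <- 1L
  m[21:40, 5:9] <- 1L
  m[cbind(sample(40, 15), sample(9, 15, replace = TRUE))] <- 1L
  mb <- multiscale_bootstrap(m, nboot = 200, seed = 7)
  expect_true(all(mb$edges$au >= 0 & mb$edges$au <= 1))
  expect_true(all(mb$edges$bp >= 0 & mb$edges$bp <= 1))
  root <- which(vapply(mb$edges$members, length, integer(1)) == 9)
  expect_equal(mb$edges$au[root], 1)
  expect_equal(mb$edges$bp[root], 1)
  # without noise, the two clean blocks are supported at saturation
  m0 <- m; m0[] <- 0L; m0[1:20, 1:4] <- 1L; m0[21:40, 5:9] <- 1L
  mb0 <- multiscale_bootstrap(m0, nboot = 200, seed = 7)
  sizes <- vapply(mb0$edges$members, length, integer(1))
  blocks <- which(sizes %in% c(4, 5))
  expect_true(all(mb0$edges$au[blocks] > 0.95))
})

test_that("with a single scale AU degenerates to the counted BP", {
  set.seed(26)
  m <- matrix(rbinom(200, 1, 0.4), 40, 5,
              dimnames = list(NULL, paste0("S", 1:5)))
  mb <- multiscale_bootstrap(m, r_grid = 1, nboot = 300, seed = 9)
  eps <- 1 / (2 * 300)
  nonroot <- vapply(mb$edges$members, length, integer(1)) < 5
  expect_true(all(mb$edges$degenerate[nonroot]))
  expect_equal(mb$edges$au[nonroot],
               pmin(pmax(mb$edges$bp_raw[nonroot], eps), 1 - eps))
})

test_that("bootstrap support is reproducible from the seed", {
  set.seed(27)
  m <- matrix(rbinom(300, 1, 0.3), 50, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  a <- multiscale_bootstrap(m, nboot = 100, seed = 5)
  b <- multiscale_bootstrap(m, nboot = 100, seed = 5)
  expect_identical(a$edges$au, b$edges$au)
  expect_identical(a$bp_table, b$bp_table)
})

test_that("newick serialization carries au|bp labels and parses as a tree", {
  m <- matrix(0L, 30, 6, dimnames = list(NULL, paste0("S", 1:6)))
  m[1:15, 1:3] <- 1L; m[16:30, 4:6] <- 1L
  mb <- multiscale_bootstrap(m, nboot = 50, seed = 3)
  nwk <- write_newick(mb)
  expect_match(nwk, "^\\(.*\\).*;$")
  expect_true(all(vapply(paste0("S", 1:6), grepl, logical(1), nwk,
                         fixed = TRUE)))
  expect_match(nwk, "[0-9.]+\\|[0-9.]+")
})
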