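wt_tree <- function() {
  gating_tree(data.frame(
    name = c("GC", "DZ", "LZ", "hi_DZ", "lo_DZ", "hi_LZ", "lo_LZ"),
    parent = c(NA, "GC", "GC", "DZ", "DZ", "LZ", "LZ"),
    fraction_of_parent = c(1, 0.5, 0.5, 0.8, 0.2, 0.9, 0.1)))
}

test_that("gating tree validation catches structural errors", {
  expect_error(gating_tree(data.frame(name = c("a", "b"), parent = c(NA, NA),
                                      fraction_of_parent = 1)), "one root")
  expect_error(gating_tree(data.frame(name = c("a", "b"), parent = c(NA, "x"),
                                      fraction_of_parent = c(1, 1))), "unknown parent")
  expect_error(gating_tree(data.frame(name = c("a", "b", "c"),
                                      parent = c(NA, "a", "a"),
                                      fraction_of_parent = c(1, 0.5, 0.4))),
               "summing")
  expect_error(gating_tree(data.frame(name = c("a", "b"), parent = c(NA, "a"),
                                      fraction_of_parent = c(1, 1),
                                      n_sequenced = c(NA, 5), n_stop = c(NA, 6))),
               "exceeds")
})

test_that("leaf frequency is the simple percentage", {
  expect_equal(leaf_frequency(0, 25), 0)
  expect_equal(leaf_frequency(3, 60), 5)
  expect_equal(leaf_frequency(1, 1), 100)
  expect_error(leaf_frequency(1, 0), "> 0")
})

test_that("rollup is the fraction-weighted sum and matches hand computation", {
  tree <- gating_tree(data.frame(
    name = c("P", "a", "b"), parent = c(NA, "P", "P"),
    fraction_of_parent = c(1, 0.2, 0.8)))
  tallies <- data.frame(gate = c("a", "b"), n_sequenced = c(100, 100),
                        n_stop = c(10, 2))
  est <- rollup_frequency(tree, "P", tallies = tallies)
  expect_equal(est$frequency, 0.2 * 10 + 0.8 * 2)  # 3.6%
  expect_equal(est$n_effective, 200)
  # all leaves at the same frequency f -> every node at f
  same <- data.frame(gate = c("hi_DZ", "lo_DZ", "hi_LZ", "lo_LZ"),
                     n_sequenced = 50, n_stop = 5)
  for (node in c("GC", "DZ", "LZ")) {
    expect_equal(rollup_frequency(wt_tree(), node, tallies = same)$frequency, 10)
  }
})

test_that("rollup instantiates the four-quadrant cell-cycle formula", {
  # BCR-low DZ split into four cell-cycle quadrants with distinct frequencies
  tree <- gating_tree(data.frame(
    name = c("BCRlowDZ", "q_earlyG1", "q_lateG1", "q_S", "q_G2M"),
    parent = c(NA, rep("BCRlowDZ", 4)),
    fraction_of_parent = c(1, 0.4, 0.3, 0.2, 0.1)))
  tallies <- data.frame(gate = c("q_earlyG1", "q_lateG1", "q_S", "q_G2M"),
                        n_sequenced = c(40, 30, 20, 10),
                        n_stop = c(8, 3, 1, 0))
  est <- rollup_frequency(tree, tallies = tallies)
  direct <- 20 * 0.4 + 10 * 0.3 + 5 * 0.2 + 0 * 0.1
  expect_equal(est$frequency, direct)
})

test_that("rollup is associative: level-by-level equals flattened leaf weights", {
  tree <- wt_tree()
  tallies <- data.frame(gate = c("hi_DZ", "lo_DZ", "hi_LZ", "lo_LZ"),
                        n_sequenced = c(200, 100, 150, 80),
                        n_stop = c(4, 17, 1, 3))
  dz <- rollup_frequency(tree, "DZ", tallies = tallies)$frequency
  lz <- rollup_frequency(tree, "LZ", tallies = tallies)$frequency
  gc_direct <- rollup_frequency(tree, "GC", tallies = tallies)$frequency
  expect_equal(gc_direct, 0.5 * dz + 0.5 * lz)
})

test_that("proportional sampling makes rollup equal the pooled naive frequency", {
  set.seed(41)
  tree <- wt_tree()
  # sequenced counts proportional to pre-enrichment fractions
  n <- c(hi_DZ = 400, lo_DZ = 100, hi_LZ = 450, lo_LZ = 50)
  p <- c(hi_DZ = 0.02, lo_DZ = 0.17, hi_LZ = 0.01, lo_LZ = 0.03)
  tallies <- data.frame(gate = names(n), n_sequenced = as.integer(n),
                        n_stop = vapply(names(n), function(g)
                          rbinom(1, n[[g]], p[[g]]), integer(1)))
  expect_equal(rollup_frequency(tree, "GC", tallies = tallies)$frequency,
               pooled_frequency(tree, "GC", tallies = tallies))
})

test_that("rollup corrects deliberate oversampling of a rare high-frequency leaf", {
  set.seed(42)
  tree <- wt_tree()
  truth <- c(hi_DZ = 0.02, lo_DZ = 0.20)
  dz_truth <- 100 * (0.8 * truth[["hi_DZ"]] + 0.2 * truth[["lo_DZ"]])
  # 10x oversampling of lo_DZ relative to its 20% fraction
  covered <- 0
  hits <- 0
  for (rep in 1:10) {
    tallies <- data.frame(
      gate = c("hi_DZ", "lo_DZ"),
      n_sequenced = c(300, 700),
      n_stop = c(rbinom(1, 300, truth[["hi_DZ"]]), rbinom(1, 700, truth[["lo_DZ"]])))
    est <- rollup_frequency(tree, "DZ", tallies = tallies)
    pooled <- pooled_frequency(tree, "DZ", tallies = tallies)
    covered <- covered + (est$ci_low <= dz_truth && dz_truth <= est$ci_high)
    hits <- hits + (abs(pooled - dz_truth) > abs(est$frequency - dz_truth))
  }
  expect_gte(covered, 8)   # rollup CI covers the truth
  expect_gte(hits, 9)      # pooling is further from the truth than rollup
})

test_that("leaves without data trigger the configured policy", {
  tree <- gating_tree(data.frame(
    name = c("P", "a", "b"), parent = c(NA, "P", "P"),
    fraction_of_parent = c(1, 0.5, 0.5)))
  expect_error(rollup_frequency(tree, "P"), "lack tallies")
  tallies <- data.frame(gate = c("a", "b"), n_sequenced = c(100, 0),
                        n_stop = c(10, 0))
  expect_error(rollup_frequency(tree, "P", tallies = tallies), "zero sequenced")
  est <- rollup_frequency(tree, "P", tallies = tallies,
                          zero_policy = "renormalize")
  expect_equal(est$frequency, 10)
})

test_that("index join preserves labels and reports unmatched and duplicate ids", {
  idx <- data.frame(cell_id = c("c1", "c2", "c3"), gate = "DZ",
                    ch1 = c(1.2, 3.4, 5.6))
  calls <- data.frame(cell_id = c("c2", "c3", "c4"),
                      premature_stop = c(TRUE, FALSE, FALSE))
  j <- join_index_data(idx, calls)
  expect_equal(nrow(j$joined), 2L)
  expect_equal(j$unmatched$index_only, "c1")
  expect_equal(j$unmatched$calls_only, "c4")
  disjoint <- join_index_data(idx, data.frame(cell_id = "z", premature_stop = TRUE))
  expect_equal(nrow(disjoint$joined), 0L)
  expect_equal(disjoint$unmatched$index_only, c("c1", "c2", "c3"))
  expect_error(join_index_data(rbind(idx, idx[1, ]), calls), "duplicate")
  tal <- tally_gates(j$joined)
  expect_equal(tal$n_sequenced, 2L)
  expect_equal(tal$n_stop, 1L)
})

test_that("gating trees round-trip through YAML", {
  dir <- withr::local_tempdir()
  tree <- wt_tree()
  write_gating_tree(tree, file.path(dir, "tree.yaml"))
  back <- read_gating_tree(file.path(dir, "tree.yaml"))
  expect_equal(back$name, tree$name)
  expect_equal(back$fraction_of_parent, tree$fraction_of_parent)
})
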