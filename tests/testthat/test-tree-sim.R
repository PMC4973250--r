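test_that("a burst stops at exactly target_n leaves with all leaf depths T1+T2", {
  p <- burst_params(gamma = 15, delta = 0.4, T1 = 0.8, T2 = 0.3)
  for (n in c(2, 7, 200)) {
    tr <- simulate_burst(p, n, seed = n)
    expect_identical(tr$n_leaves, as.integer(n))
    ph <- ape::as.phylo(tr)
    depth <- ape::node.depth.edgelength(ph) + ph$root.edge
    expect_equal(unname(depth[seq_len(n)]), rep(p$T1 + p$T2, n),
                 tolerance = 1e-12)
  }
})

test_that("identical config and seed give byte-identical Newick output", {
  p <- burst_params(gamma = 30, delta = 0.7, T1 = 0.2, T2 = 0.05)
  a <- write_newick(simulate_burst(p, 150, seed = 99))
  b <- write_newick(simulate_burst(p, 150, seed = 99))
  expect_identical(a, b)
  other <- write_newick(simulate_burst(p, 150, seed = 100))
  expect_false(identical(a, other))
})

test_that("the master-gene limit produces a caterpillar with unit clone sizes", {
  p <- burst_params(gamma = 10, delta = 0, T1 = 1, T2 = 0.2)
  tr <- simulate_burst(p, 11, seed = 4)
  expect_identical(tr$n_leaves, 11L)
  ss <- subtree_sizes(tr)
  expect_identical(ss$size, rep(1L, 10))
  # only the founder chain is active
  expect_identical(sum(tr$leaf_active), 1L)
})

test_that("clone sizes of the root's children partition the leaves", {
  p <- burst_params(gamma = 20, delta = 1, T1 = 0.5, T2 = 0)
  tr <- simulate_burst(p, 300, seed = 12)
  counts <- repeatburst:::leaf_counts(tr)
  root <- tr$n_leaves + 1L
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  expect_identical(sum(counts[kids]), 300L)
  # clone-size list has one entry per duplication event
  expect_identical(nrow(subtree_sizes(tr)), tr$Nnode)
})

test_that("counts through time start at (1,1), end at the leaf counts, and are monotone", {
  p <- burst_params(gamma = 12, delta = 0.5, T1 = 0.6, T2 = 0.2)
  tr <- simulate_burst(p, 120, seed = 5)
  ct <- counts_at_time(tr, c(0, p$T1 + p$T2))
  expect_identical(ct$total, c(1L, 120L))
  expect_identical(ct$active[1], 1L)
  expect_identical(ct$active[2], sum(tr$leaf_active))
  grid <- counts_at_time(tr, seq(0, p$T1 + p$T2, length.out = 40))
  expect_true(all(diff(grid$total) >= 0))
  expect_true(all(diff(grid$active) >= 0))
  # constant after T1
  expect_identical(counts_at_time(tr, p$T1)$total, 120L)
  expect_error(counts_at_time(tr, p$T1 + p$T2 + 1),
               class = "repeatburst_domain_error")
})

test_that("ensemble totals at a fixed time match the growth curve and stopping times the Yule harmonic sum", {
  p <- burst_params(gamma = 10, delta = 1, T1 = 1, T2 = 0)
  ct <- sample_burst_counts(p, 0.45, 2000, seed = 31)
  m <- mean(ct$total)
  se <- stats::sd(ct$total) / sqrt(nrow(ct))
  expect_lt(abs(m - expected_copies(0.45, p)) / se, 3)
  # stopping time of a size-stopped pure-birth burst: E[T_N] = H_{N-1}/gamma
  N <- 200
  tts <- vapply(1:400, function(s) {
    simulate_burst(p, N, seed = 5000 + s)$t_last_raw
  }, numeric(1))
  expected_t <- sum(1 / (1:(N - 1))) / p$gamma
  se_t <- stats::sd(tts) / sqrt(length(tts))
  expect_lt(abs(mean(tts) - expected_t) / se_t, 3)
})

test_that("active lineages proliferate at rate delta*gamma on the raw clock", {
  p <- burst_params(gamma = 40, delta = 0.5, T1 = 1, T2 = 0)
  # ensemble-averaged log active count vs raw time
  grid <- seq(0.05, 0.35, by = 0.025)
  acc <- matrix(0, length(grid), 30)
  for (r in 1:30) {
    tr <- simulate_burst(p, 2500, seed = 800 + r)
    keep <- grid <= tr$t_last_raw
    acc[keep, r] <- counts_at_time(tr, grid[keep], time_scale = "raw")$active
  }
  ok <- rowSums(acc == 0) == 0
  slope <- stats::coef(stats::lm(log(rowMeans(acc[ok, ])) ~ grid[ok]))[2]
  expect_equal(unname(slope), p$delta * p$gamma, tolerance = 0.1)
})

test_that("single-element bursts degenerate to a bare founder edge", {
  p <- burst_params(gamma = 10, delta = 1, T1 = 0.3, T2 = 0.1)
  tr <- simulate_burst(p, 1, seed = 1)
  expect_identical(tr$n_leaves, 1L)
  expect_equal(tr$root_edge, 0.4)
  expect_identical(write_newick(tr), "L1[&active=1]:0.4;")
  expect_identical(nrow(subtree_sizes(tr)), 0L)
})
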