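test_that("a zero mutation rate or zero time leaves every leaf identical to the ancestor", {
  p0 <- burst_params(gamma = 10, delta = 1, T1 = 0.4, T2 = 0.2, mu0 = 1e-12)
  p0$mu0 <- 0 # exactly zero; constructor guards against it as a default
  tr <- simulate_burst(burst_params(gamma = 10, T1 = 0.4, T2 = 0.2), 15,
                       seed = 2)
  anc <- make_ancestral(120, 8, seed = 3)
  els <- evolve_sequences(tr, anc, params = p0, seed = 4)
  expect_identical(unique(els$sequence), anc)
  expect_identical(nrow(els), 15L)
})

test_that("sequence length and alphabet are conserved across the tree", {
  p <- burst_params(gamma = 10, delta = 0.6, T1 = 0.2, T2 = 0.1)
  tr <- simulate_burst(p, 40, seed = 6)
  anc <- make_ancestral(150, 10, seed = 7)
  els <- evolve_sequences(tr, anc, seed = 8)
  expect_true(all(nchar(els$sequence) == 150))
  expect_true(all(grepl("^[ACGT]+$", els$sequence)))
  expect_error(evolve_sequences(tr, "ACGNT"),
               class = "repeatburst_input_error")
})

test_that("single-edge substitution fractions match the 4-state Markov closed form", {
  # uniform 3-alternative model (cpg_factor = 1; with hypermutability on, CG
  # dinucleotides created en route would push the rate above the closed form):
  # P(site unchanged) = 1/4 + 3/4 exp(-4 mu0 t / 3)
  p <- burst_params(gamma = 1, cpg_factor = 1)
  anc <- paste(rep(c("A", "T"), 150), collapse = "") # no C or G at all
  t_edge <- 0.35
  set.seed(10)
  div <- vapply(1:300, function(i) {
    pairwise_divergence(anc, mutate_sequence(anc, t_edge, p))
  }, numeric(1))
  n_sites <- 300 * 300
  p_diff <- 1 - jc_p_same(1, t_edge)
  se <- sqrt(p_diff * (1 - p_diff) / n_sites)
  expect_lt(abs(mean(div) - p_diff) / se, 3)
})

test_that("divergence between two leaves matches the closed form at separation 2t", {
  p <- burst_params(gamma = 1, cpg_factor = 1)
  anc <- paste(rep(c("A", "T"), 100), collapse = "")
  t_edge <- 0.2
  set.seed(20)
  div <- vapply(1:300, function(i) {
    a <- mutate_sequence(anc, t_edge, p)
    b <- mutate_sequence(anc, t_edge, p)
    pairwise_divergence(a, b)
  }, numeric(1))
  p_diff <- 1 - jc_p_same(1, 2 * t_edge)
  se <- sqrt(p_diff * (1 - p_diff) / (300 * 200))
  expect_lt(abs(mean(div) - p_diff) / se, 3.5)
})

test_that("pairwise divergence is the Hamming fraction", {
  expect_identical(pairwise_divergence("ACGT", "ACGT"), 0)
  expect_identical(pairwise_divergence("ACGT", "ACGA"), 0.25)
  expect_error(pairwise_divergence("ACG", "ACGT"),
               class = "repeatburst_input_error")
})

test_that("CpG sites realise about six times the background event rate", {
  # short edges so the CpG pool barely decays during an edge
  p <- burst_params(gamma = 1, cpg_factor = 6)
  anc <- make_ancestral(300, 24, seed = 30)
  cg <- gregexpr("CG", anc)[[1]]
  cpg_sites <- sort(c(cg, cg + 1L))
  t_edge <- 0.001
  set.seed(31)
  ev_cpg <- 0; ev_bg <- 0
  for (i in 1:4000) {
    r <- mutate_sequence(anc, t_edge, p, count_events = TRUE)
    ev_cpg <- ev_cpg + sum(r$events[cpg_sites])
    ev_bg <- ev_bg + sum(r$events[-cpg_sites])
  }
  n_cpg_sites <- length(cpg_sites)
  n_bg_sites <- 300 - n_cpg_sites
  rate_cpg <- ev_cpg / (4000 * t_edge * n_cpg_sites)
  rate_bg <- ev_bg / (4000 * t_edge * n_bg_sites)
  se_ratio <- (rate_cpg / rate_bg) * sqrt(1 / ev_cpg + 1 / ev_bg)
  expect_lt(abs(rate_cpg / rate_bg - 6) / se_ratio, 3)
  # and the overall per-site rate is the effective 1.8 mu0
  rate_all <- (ev_cpg + ev_bg) / (4000 * t_edge * 300)
  se_all <- rate_all / sqrt(ev_cpg + ev_bg)
  expect_lt(abs(rate_all - 1.8) / se_all, 3.5)
})

test_that("with cpg_factor = 1 the process is the uniform 3-alternative model", {
  # substitution counts on a CpG-rich ancestor should be statistically
  # indistinguishable between CpG and non-CpG sites
  p <- burst_params(gamma = 1, cpg_factor = 1)
  anc <- make_ancestral(300, 24, seed = 40)
  cg <- gregexpr("CG", anc)[[1]]
  cpg_sites <- sort(c(cg, cg + 1L))
  t_edge <- 0.02
  set.seed(41)
  ev_cpg <- 0; ev_bg <- 0
  for (i in 1:500) {
    r <- mutate_sequence(anc, t_edge, p, count_events = TRUE)
    ev_cpg <- ev_cpg + sum(r$events[cpg_sites])
    ev_bg <- ev_bg + sum(r$events[-cpg_sites])
  }
  n1 <- length(cpg_sites); n2 <- 300 - n1
  chi <- stats::chisq.test(c(ev_cpg, ev_bg), p = c(n1, n2) / 300)
  expect_gt(chi$p.value, 1e-3)
})

test_that("dynamic CpG context: a CG created by mutation becomes hypermutable", {
  # deterministic check on the internal rate refresh
  p <- burst_params(gamma = 1, cpg_factor = 6)
  s <- repeatburst:::seq_to_int("ACGTT")
  r0 <- repeatburst:::site_rates(s, 1, 6)
  expect_equal(r0, c(1, 6, 6, 1, 1))
  s2 <- repeatburst:::seq_to_int("ATGTT") # CpG destroyed
  expect_equal(repeatburst:::site_rates(s2, 1, 6), rep(1, 5))
  s3 <- repeatburst:::seq_to_int("ACGCG")
  expect_equal(repeatburst:::site_rates(s3, 1, 6), c(1, 6, 6, 6, 6))
})
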