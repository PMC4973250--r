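test_that("the Hill formula reproduces its closed-form value on degenerate samples", {
  a <- hill_exponent(c(3, 3, 3), s_min = 3)
  expect_equal(as.numeric(a), 1 + 1 / log(1.2))
  expect_identical(attr(a, "n_tail"), 3L)
  # scale-free in n: duplicating every tail point leaves the estimate fixed
  set.seed(1)
  s <- sample(3:50, 40, replace = TRUE)
  expect_equal(as.numeric(hill_exponent(c(s, s))),
               as.numeric(hill_exponent(s)))
  # sub-cutoff observations are ignored
  expect_equal(as.numeric(hill_exponent(c(1, 1, 2, s))),
               as.numeric(hill_exponent(s)))
  expect_error(hill_exponent(c(1, 2, 3)), class = "repeatburst_estimation_error")
})

test_that("the Hill estimate converges to its exact asymptotic expectation on power-law samples", {
  # The half-shift formula is an approximation to the discrete ML estimator;
  # its large-n limit under the exact zeta-normalised pmf is the honest
  # oracle (computed by direct expectation, independent of the estimator).
  for (alpha in c(2.1, 2.5, 3)) {
    x <- sample_discrete_powerlaw(1e5, alpha, s_min = 3, seed = 50 + alpha * 10)
    a <- hill_exponent(x, s_min = 3)
    limit <- hill_asymptotic(alpha, 3)
    se <- (limit - 1) / sqrt(1e5)
    expect_lt(abs(as.numeric(a) - limit) / se, 4)
  }
})

test_that("exponent_curve recovers the clone-size exponent of a constructed element set", {
  # clones built by copying one random sequence per clone; every 30-mer of a
  # clone then has abundance ~ clone size (collisions are negligible)
  sizes <- sample_discrete_powerlaw(150, 2.5, s_min = 3, seed = 60)
  bases <- random_seqs(150, 80, seed = 61)
  els <- rep(bases, sizes)
  crv <- exponent_curve(els, k_values = 30, s_min = 3)
  expect_equal(crv$alpha_hat, as.numeric(hill_exponent(sizes, 3)),
               tolerance = 0.02)
  # duplicate-free random sequences have no tail at all
  expect_error(exponent_curve(random_seqs(30, 60, seed = 62), k_values = 20),
               class = "repeatburst_estimation_error")
})

test_that("fit_ratio is exact on a noiseless analytic curve and robust to noise", {
  kk <- seq(35, 75, by = 5)
  crv <- tibble::tibble(k = kk, alpha_hat = alpha_of_k(kk, ratio = 0.009))
  f <- fit_ratio(crv)
  expect_equal(f$ratio_hat, 0.009, tolerance = 1e-6)
  expect_lt(f$residual_norm, 1e-12)
  expect_identical(f$n_points, length(kk))
  # broom-style accessors
  td <- tidy(f)
  expect_identical(td$term, "ratio")
  expect_equal(td$estimate, f$ratio_hat)
  gl <- glance(f)
  expect_named(gl, c("ratio_hat", "std.error", "residual_norm", "n_points",
                     "k_lo", "k_hi"))
  # Gaussian noise sigma = 0.05: ratio recovered within 10%
  set.seed(70)
  rel_err <- replicate(100, {
    noisy <- tibble::tibble(k = kk,
                            alpha_hat = alpha_of_k(kk, ratio = 0.009) +
                              stats::rnorm(length(kk), 0, 0.05))
    abs(fit_ratio(noisy)$ratio_hat - 0.009) / 0.009
  })
  expect_lt(mean(rel_err), 0.10)
  expect_lt(stats::median(rel_err), 0.10)
  expect_error(fit_ratio(crv[1, ]), class = "repeatburst_estimation_error")
})

test_that("element-count estimation is exact for equal-length sets and predictable for mixed lengths", {
  seqs <- random_seqs(40, 300, seed = 80)
  expect_equal(estimate_N(seqs), 40)
  expect_equal(estimate_N(seqs, k_values = c(5, 50, 90)), 40)
  expect_equal(estimate_N(random_seqs(1, 300, seed = 81)), 1)
  # mixed lengths: hand-computed window totals
  mixed <- c(random_seqs(1, 280, seed = 82), random_seqs(1, 320, seed = 83))
  for (k in c(10, 60)) {
    hand <- ((280 - k + 1) + (320 - k + 1)) / (300 - k + 1)
    expect_equal(estimate_N(mixed, k_values = k), hand)
  }
  expect_error(estimate_N(seqs, k_values = 5:400, L = 300),
               class = "repeatburst_domain_error")
})

test_that("T2 fitting recovers the truth on self-generated references and is not flat", {
  p <- small_alu_params(600, T2 = 0.03)
  anc <- make_ancestral(300, 24, seed = 90)
  grid <- c(0.0075, 0.03, 0.12)
  hits <- 0L
  for (s in 1:3) {
    ref <- simulate_elements(p, 600, anc, seed = 900 + s)
    ref_binned <- log_bin(kmer_spectra(ref, c(30, 40)))
    t2 <- fit_T2(ref_binned, p, grid, target_n = 600, ancestor = anc,
                 k_values = c(30, 40), n_seeds = 1, seed = 910 + s)
    prof <- tidy(t2)
    expect_identical(nrow(prof), 3L)
    expect_gt(max(prof$distance) / min(prof$distance), 1) # profile not flat
    if (t2$best_T2 == 0.03) hits <- hits + 1L
  }
  expect_gte(hits, 2L) # majority of seeds pick the true grid point
})

test_that("identical binned spectra are at distance zero", {
  sp <- log_bin(spectrum_from_counts(c(1, 1, 2, 9, 30, 30), k = 5))
  key <- repeatburst:::spectrum_key(sp)
  expect_identical(repeatburst:::spectrum_distance(key, key), 0)
})
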