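test_that("effective mutation rate is the CpG-weighted average", {
  expect_equal(effective_mu(300, 24, 6), 1.8)
  expect_equal(effective_mu(300, 0, 6), 1.0)
  expect_equal(effective_mu(100, 25, 2), 1.5)
  expect_error(effective_mu(10, 6, 6), class = "repeatburst_domain_error")
})

test_that("expected copy number starts at one, grows monotonically, and has the right limits", {
  p <- burst_params(gamma = 200, delta = 1)
  expect_identical(expected_copies(0, p), 1)
  # delta = 1: pure exponential growth
  expect_equal(expected_copies(0.05, p), exp(200 * 0.05))
  # delta = 0: linear master-gene growth
  p0 <- burst_params(gamma = 7, delta = 0)
  expect_equal(expected_copies(2, p0), 15)
  # monotone on a grid, for several delta
  for (d in c(0, 0.3, 1)) {
    pd <- burst_params(gamma = 50, delta = d)
    v <- expected_copies(seq(0, 0.1, length.out = 25), pd)
    expect_true(all(diff(v) > 0))
  }
  expect_error(expected_copies(-1, p), class = "repeatburst_domain_error")
})

test_that("inverting the growth curve matches the printed Alu burst-duration range", {
  p <- burst_params(gamma = 0.2e3, delta = 1)
  T1 <- estimate_T1(776710, p)
  expect_lte(T1, 6.9e-2)
  expect_gte(T1, 5.3e-2)
})

test_that("estimate_T1 round-trips expected_copies to high accuracy", {
  set.seed(11)
  for (d in c(0.05, 0.4, 1)) {
    p <- burst_params(gamma = 120 / d, delta = d)
    N <- 10^stats::runif(5, 0.5, 6)
    t <- estimate_T1(N, p)
    expect_equal(expected_copies(t, p), N, tolerance = 1e-9)
  }
  expect_identical(estimate_T1(1, burst_params(gamma = 5)), 0)
  expect_error(estimate_T1(0.5, burst_params(gamma = 5)),
               class = "repeatburst_domain_error")
})

test_that("alpha(k) has the Yule limit 2, grows with k and ratio, and stops at the tail boundary", {
  expect_equal(alpha_of_k(1e-9, ratio = 0.009), 2, tolerance = 1e-6)
  expect_equal(alpha_of_k(40, ratio = 0), 2) # mutation-free limit
  grid <- alpha_of_k(1:110, ratio = 1.8 / 200)
  expect_true(all(grid >= 2))
  expect_true(all(diff(grid) > 0))
  expect_true(all(diff(alpha_of_k(50, ratio = c(0.001, 0.005, 0.01, 0.019))) > 0))
  expect_error(alpha_of_k(120, ratio = 0.009),
               class = "repeatburst_no_tail_error")
  # params interface agrees with the ratio interface
  p <- alu_params()
  expect_equal(alpha_of_k(40, rates = p), alpha_of_k(40, ratio = 0.009))
})

test_that("k-mer survival probability is exponential with the semigroup property", {
  expect_identical(survival_prob(40, 1.8, 0), 1)
  expect_equal(survival_prob(10, 2, log(2) / 20), 0.5)
  k <- c(5, 40, 90)
  expect_equal(survival_prob(k, 1.8, 0.01) * survival_prob(k, 1.8, 0.025),
               survival_prob(k, 1.8, 0.035))
  expect_error(survival_prob(-1, 1, 1), class = "repeatburst_domain_error")
})

test_that("tail density decays as the predicted power law and is linear in N", {
  p <- alu_params()
  a40 <- alpha_of_k(40, rates = p)
  s <- c(20, 40, 80, 160)
  d <- tail_density(s, 40, p)
  expect_true(all(d > 0))
  expect_equal(d[-1] / d[-4], rep(2^(-a40), 3))
  # doubling N doubles the density
  p2 <- p
  p2$T1 <- estimate_T1(2 * expected_copies(p$T1, p), p)
  expect_equal(tail_density(s, 40, p2) / d, rep(2, 4), tolerance = 1e-9)
  # log-log slope equals -alpha
  sg <- exp(seq(log(10), log(200), length.out = 30))
  fitl <- stats::lm(log(tail_density(sg, 40, p)) ~ log(sg))
  expect_equal(unname(stats::coef(fitl)[2]), -a40, tolerance = 1e-9)
  bad <- burst_params(gamma = 1, delta = 1, T1 = 1, T2 = 1)
  expect_error(tail_density(10, 40, bad), class = "repeatburst_no_tail_error")
})

test_that("ensemble-mean burst size matches the expected copy number across delta", {
  # fixed-time KMC ensembles against the closed form, three regimes
  for (d in c(0.05, 0.5, 1)) {
    p <- burst_params(gamma = 10, delta = d)
    bc <- sample_burst_counts(p, 0.3, 3000, seed = 700 + round(100 * d))
    m <- mean(bc$total)
    se <- stats::sd(bc$total) / sqrt(nrow(bc))
    expect_lt(abs(m - expected_copies(0.3, p)) / se, 3)
  }
})

test_that("predict_tail tabulates alpha, p_k and N over k and drops non-tail k", {
  p <- alu_params()
  tp <- predict_tail(p, k = seq(5, 90, by = 5))
  expect_s3_class(tp, "tbl_df")
  expect_named(tp, c("k", "alpha", "p_k", "N"))
  expect_true(all(diff(tp$alpha) > 0))
  expect_equal(tp$p_k, survival_prob(tp$k, 1.8, p$T2))
  expect_warning(predict_tail(p, k = c(40, 150)), "dropping")
  pbad <- burst_params(gamma = 0.01, delta = 1, T1 = 1, T2 = 0)
  expect_error(predict_tail(pbad, k = c(40, 80)),
               class = "repeatburst_no_tail_error")
})

test_that("model-unit reporting helpers convert to calendar units", {
  expect_equal(mu0_from_age(7.7e-2, 80e6), 7.7e-2 / 80e6)
  expect_equal(time_in_years(0.024, 1e-9), 2.4e7)
})
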