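#' Expected element count under the branching model
#'
#' During the burst every active element duplicates at rate `gamma` and each
#' new copy is active with probability `delta`, so the expected number of
#' active elements grows as `exp(delta * gamma * t)` and the expected total
#' count is
#' \deqn{N(t) = 1 + \frac{e^{\delta\gamma t} - 1}{\delta},}
#' the founder plus the accumulated copies. At `delta = 1` this is pure
#' exponential growth `exp(gamma t)`; in the master-gene limit `delta = 0`
#' it reduces to linear growth `1 + gamma t`.
#'
#' @param t Time since the start of the burst, units `1/mu0`; vectorised.
#' @param params A [burst_params()] object (only `gamma` and `delta` are used).
#' @return Expected total element count at each `t`.
#' @examples
#' expected_copies(0, burst_params(gamma = 200)) # 1
#' expected_copies(log(776710) / 200, burst_params(gamma = 200, delta = 1))
#' @export
expected_copies <- function(t, params) {
  stop_domain_if(any(t < 0), "`t` must be non-negative.")
  dg <- params$delta * params$gamma
  if (params$delta == 0) {
    1 + params$gamma * t
  } else {
    1 + expm1(dg * t) / params$delta
  }
}

#' Power-law exponent of the k-mer abundance tail
#'
#' Under the model a k-mer lineage is duplicated at the effective rate
#' `delta * gamma` and destroyed (mutated away) at rate `mu * k`, and new
#' variants are seeded continuously into the exponentially growing
#' population. The abundance distribution then has a power-law tail
#' `n_k(s) ~ s^-alpha(k)` with
#' \deqn{\alpha(k) = 1 + \frac{\delta\gamma}{\delta\gamma - \mu k}
#'               = 1 + \frac{1}{1 - k\,\mu/(\delta\gamma)},}
#' provided a k-mer duplicates faster than it mutates, `mu * k <
#' delta * gamma`. The exponent equals 2 in the small-`k` (or mutation-free)
#' limit and increases with both `k` and the ratio `mu/(delta*gamma)`.
#'
#' @param k K-mer length in bp; vectorised.
#' @param rates Either a one-row tibble from [effective_rates()], a
#'   [burst_params()] object, or a plain ratio can be given via `ratio`.
#' @param ratio Optional direct value of `mu / (delta * gamma)`; overrides
#'   `rates`.
#' @return The exponent `alpha(k)` for each `k`.
#' @examples
#' alpha_of_k(40, ratio = 0.009)
#' @export
alpha_of_k <- function(k, rates = NULL, ratio = NULL) {
  if (is.null(ratio)) {
    if (inherits(rates, "burst_params")) rates <- effective_rates(rates)
    stop_domain_if(is.null(rates), "supply `rates` or `ratio`.")
    ratio <- rates$ratio[[1]]
  }
  stop_domain_if(any(k < 0), "`k` must be non-negative.")
  stop_domain_if(ratio < 0, "`ratio` must be non-negative.")
  bad <- k * ratio >= 1
  if (any(bad)) {
    stop_no_tail(sprintf(
      "no power-law tail: mu*k >= delta*gamma for k = %s (ratio = %g).",
      paste(utils::head(k[bad], 3), collapse = ", "), ratio))
  }
  1 + 1 / (1 - k * ratio)
}

#' Probability that a k-mer survives the silent phase unmutated
#'
#' A k-mer mutates at rate `mu * k`, so the chance it keeps its sequence over
#' a time `T2` is `exp(-mu * k * T2)`.
#'
#' @param k K-mer length; vectorised.
#' @param mu Effective per-nucleotide mutation rate (units `mu0`).
#' @param T2 Duration of the silent phase (units `1/mu0`).
#' @return Survival probability in (0, 1].
#' @examples
#' survival_prob(40, 1.8, 0.024)
#' @export
survival_prob <- function(k, mu, T2) {
  stop_domain_if(any(k < 1) || any(mu < 0) || any(T2 < 0),
                 "need k >= 1, mu >= 0, T2 >= 0.")
  exp(-mu * k * T2)
}

#' Predicted k-mer abundance-tail density
#'
#' Expected number of distinct k-mers with abundance `s` in the tail of the
#' spectrum:
#' \deqn{n_k(s) = (\alpha(k) - 1)\,(L - k + 1)\,N\,p_k\,s^{-\alpha(k)},}
#' where `N` is the expected element count at the end of the burst
#' ([expected_copies()] at `T1`), `L - k + 1` the k-mers per element, and
#' `p_k` the silent-phase survival probability. The `s` dependence (the
#' exponent) and the linearity in `N` are the load-bearing features; the
#' constant in front normalises the tail mass to the surviving k-mer pool.
#'
#' @param s Abundance (positive); vectorised.
#' @param k K-mer length.
#' @param params A [burst_params()] object.
#' @return Expected count `n_k(s)` for each `s`.
#' @examples
#' p <- alu_params()
#' tail_density(c(10, 20), 40, p)
#' @export
tail_density <- function(s, k, params) {
  stop_domain_if(any(s < 1), "`s` must be >= 1.")
  stop_domain_if(k < 1 || k > params$L, "`k` must lie in [1, L].")
  r <- effective_rates(params)
  alpha <- alpha_of_k(k, rates = r)
  N <- expected_copies(params$T1, params)
  p_k <- survival_prob(k, r$mu, params$T2)
  (alpha - 1) * (params$L - k + 1) * N * p_k * s^(-alpha)
}

#' Analytic tail predictions over a grid of k
#'
#' @param params A [burst_params()] object.
#' @param k Vector of k-mer lengths.
#' @return A tibble with columns `k`, `alpha`, `p_k`, `N`; rows for which no
#'   power-law tail exists (`mu * k >= delta * gamma`) are dropped with a
#'   warning.
#' @examples
#' predict_tail(alu_params(), k = seq(5, 90, by = 5))
#' @export
predict_tail <- function(params, k = seq(5, 90, by = 5)) {
  r <- effective_rates(params)
  ok <- k * r$ratio < 1
  if (!any(ok)) {
    stop_no_tail("no power-law tail exists for any requested k.")
  }
  if (any(!ok)) {
    warning(sprintf("dropping %d k value(s) with mu*k >= delta*gamma.",
                    sum(!ok)))
  }
  k <- k[ok]
  tibble::tibble(
    k = k,
    alpha = alpha_of_k(k, rates = r),
    p_k = survival_prob(k, r$mu, params$T2),
    N = expected_copies(params$T1, params)
  )
}

#' Burst duration implied by a present-day element count
#'
#' Inverts the expected-copy-number curve: returns the unique time `t` with
#' `expected_copies(t) = N`, i.e.
#' `t = log(1 + delta (N - 1)) / (delta * gamma)` (and `(N - 1)/gamma` in the
#' `delta = 0` limit).
#'
#' @param N Present-day element count (>= 1); vectorised.
#' @param params A [burst_params()] object.
#' @return Time in units of `1/mu0`.
#' @examples
#' estimate_T1(776710, burst_params(gamma = 200, delta = 1)) # ~6.8e-2
#' @export
estimate_T1 <- function(N, params) {
  stop_domain_if(any(N < 1), "`N` must be >= 1.")
  stop_domain_if(params$gamma <= 0, "`gamma` must be positive.")
  if (params$delta == 0) {
    (N - 1) / params$gamma
  } else {
    log1p(params$delta * (N - 1)) / (params$delta * params$gamma)
  }
}
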