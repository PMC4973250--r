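#' Generate a synthetic CpG-matched ancestral sequence
#'
#' Builds a random sequence of length `L` containing exactly `n_cpg`
#' occurrences of the CpG dinucleotide, as a synthetic stand-in for a
#' SINE-family consensus (the Alu-like defaults are 300 bp with 24 CpG).
#' `n_cpg` non-overlapping CG blocks are placed at random positions and the
#' remaining positions are filled left to right with letters drawn to match
#' `gc_content`, excluding any G that would follow a C (which would create an
#' extra CpG). The CpG count contract is exact, not approximate.
#'
#' @param L Sequence length in bp.
#' @param n_cpg Exact number of CpG dinucleotides.
#' @param gc_content Target G+C fraction of the non-CpG positions.
#' @param seed Optional integer seed; output is deterministic per seed.
#' @return A single A/C/G/T string of length `L`.
#' @examples
#' a <- make_ancestral(300, 24, seed = 1)
#' lengths(regmatches(a, gregexpr("CG", a))) # 24
#' @export
make_ancestral <- function(L = 300, n_cpg = 24, gc_content = 0.5,
                           seed = NULL) {
  stop_domain_if(n_cpg < 0 || 2 * n_cpg > L,
                 "infeasible: need 0 <= 2 * n_cpg <= L.")
  stop_domain_if(gc_content < 0 || gc_content > 1,
                 "`gc_content` must lie in [0, 1].")
  L <- as.integer(L)
  n_cpg <- as.integer(n_cpg)
  with_seed(seed, {
    s <- character(L)
    is_block <- logical(L)
    if (n_cpg > 0L) {
      # non-overlapping block starts: s_i = q_i + 2*(i-1) with q_i a sorted
      # sample (with replacement) from 1..L-2*n_cpg+1
      q <- sort(sample.int(L - 2L * n_cpg + 1L, n_cpg, replace = TRUE))
      starts <- q + 2L * (seq_len(n_cpg) - 1L)
      s[starts] <- "C"
      s[starts + 1L] <- "G"
      is_block[starts] <- TRUE
      is_block[starts + 1L] <- TRUE
    }
    w <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
           G = gc_content / 2, T = (1 - gc_content) / 2)
    for (i in which(!is_block)) {
      wi <- w
      if (i > 1L && s[i - 1L] == "C") wi["G"] <- 0
      if (sum(wi) == 0) wi <- c(A = 1, C = 0, G = 0, T = 1)
      s[i] <- sample(names(wi), 1L, prob = wi)
    }
    paste(s, collapse = "")
  })
}

# Hurwitz zeta function zeta(a, q) = sum_{j>=0} (q + j)^-a via
# Euler-Maclaurin with M explicit terms; accurate to ~1e-12 for a > 1.
hurwitz_zeta <- function(a, q, M = 25L) {
  stop_domain_if(a <= 1, "`a` must exceed 1 for convergence.")
  j <- 0:(M - 1L)
  head_sum <- sum((q + j)^(-a))
  x <- q + M
  tail <- x^(1 - a) / (a - 1) + 0.5 * x^(-a) + a * x^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * x^(-a - 3) / 720
  head_sum + tail
}

#' Sample from a discrete power law
#'
#' Draws i.i.d. samples from `P(s) = s^-alpha / zeta(alpha, s_min)` for
#' integer `s >= s_min`, by inverse-CDF on the Hurwitz-zeta-normalised mass
#' function. The bulk of the support uses an explicit probability table;
#' draws landing beyond the table are resolved exactly by bisecting the
#' zeta-function tail.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param s_min Support minimum (integer >= 1).
#' @param seed Optional integer seed.
#' @param table_size Size of the explicit inverse-CDF table.
#' @return Integer (double when huge) vector of length `n`, all `>= s_min`.
#' @examples
#' x <- sample_discrete_powerlaw(1000, 2.5, s_min = 3, seed = 1)
#' min(x) >= 3
#' @export
sample_discrete_powerlaw <- function(n, alpha, s_min = 1, seed = NULL,
                                     table_size = 20000L) {
  stop_domain_if(alpha <= 1, "`alpha` must exceed 1 (non-normalisable otherwise).")
  stop_domain_if(s_min < 1, "`s_min` must be >= 1.")
  stop_domain_if(n < 1, "`n` must be >= 1.")
  s_min <- as.integer(s_min)
  Z <- hurwitz_zeta(alpha, s_min)
  svals <- s_min:(s_min + table_size - 1L)
  cdf <- cumsum(svals^(-alpha) / Z)
  with_seed(seed, {
    u <- stats::runif(n)
    out <- svals[findInterval(u, c(0, cdf))]
    beyond <- u > cdf[table_size]
    if (any(beyond)) {
      out[beyond] <- vapply(u[beyond], function(ui) {
        # smallest s with P(S <= s) >= ui, i.e. zeta(alpha, s+1)/Z <= 1 - ui
        target <- (1 - ui) * Z
        lo <- svals[table_size]
        hi <- lo * 2
        while (hurwitz_zeta(alpha, hi + 1) > target) hi <- hi * 2
        while (hi - lo > 1) {
          mid <- floor((lo + hi) / 2)
          if (hurwitz_zeta(alpha, mid + 1) <= target) hi <- mid else lo <- mid
        }
        hi
      }, numeric(1))
    }
    out
  })
}
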