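# Independent oracles used across the test files.

# brute-force k-mer counting: nested loops, no vectorised tricks
brute_force_kmers <- function(seqs, k) {
  out <- new.env(parent = emptyenv())
  for (s in toupper(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      cur <- if (is.null(out[[w]])) 0L else out[[w]]
      out[[w]] <- cur + 1L
    }
  }
  counts <- unlist(as.list(out))
  if (is.null(counts)) return(integer(0))
  counts[order(names(counts))]
}

# Jukes-Cantor style closed form for the 4-state chain with total leave rate
# mu (uniform over the 3 alternatives): P(same after t)
jc_p_same <- function(mu, t) 0.25 + 0.75 * exp(-4 * mu * t / 3)

# exact pmf of the discrete power law P(s) = s^-alpha / zeta(alpha, s_min),
# normalised by direct summation (independent of the package's zeta)
powerlaw_pmf <- function(alpha, s_min, s_max_eval, S = 2e6) {
  s <- s_min:S
  w <- s^(-alpha)
  w <- w / sum(w)
  w[seq_len(s_max_eval - s_min + 1)]
}

# asymptotic expectation of the half-shift Hill formula under the exact
# discrete power-law pmf
hill_asymptotic <- function(alpha, s_min = 3, S = 2e6) {
  s <- s_min:S
  w <- s^(-alpha)
  w <- w / sum(w)
  1 + 1 / sum(w * log(s / (s_min - 0.5)))
}

# random A/C/G/T sequences
random_seqs <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Alu-like test parameters at reduced census size
small_alu_params <- function(n_final, delta = 1, T2 = 0.024) {
  burst_params(gamma = 200 / delta, delta = delta,
               T1 = log(1 + delta * (n_final - 1)) / 200, T2 = T2)
}
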