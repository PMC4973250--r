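# nucleotide codes used internally: 1=A, 2=C, 3=G, 4=T
NUC <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], NUC)
  if (anyNA(x)) {
    stop_input("sequence contains letters outside {A,C,G,T}.")
  }
  x
}

int_to_seq <- function(x) paste(NUC[x], collapse = "")

# per-site total mutation rates given the current sequence; positions inside
# a CpG (a C followed by G, or that G) get cpg_factor * mu0, others mu0
site_rates <- function(s, mu0, cpg_factor) {
  L <- length(s)
  r <- rep(mu0, L)
  if (L >= 2 && cpg_factor > 1) {
    cg <- which(s[-L] == 2L & s[-1] == 3L)
    if (length(cg)) {
      r[cg] <- cpg_factor * mu0
      r[cg + 1L] <- cpg_factor * mu0
    }
  }
  r
}

#' Mutate a sequence for a given time
#'
#' Exact (Gillespie) simulation of the site-level continuous-time Markov
#' process used along every tree edge: each position mutates to one of the
#' other three nucleotides with total background rate `mu0` (uniform over the
#' three targets); in addition, the C of a CpG dinucleotide gains extra
#' C>T events and its G extra G>A events so that the total rate at a CpG
#' position is `cpg_factor * mu0`. CpG context is dynamic: a CG created by
#' mutation becomes hypermutable and a destroyed one reverts to the
#' background rate. Only the literal CG on the stored strand is treated.
#'
#' @param sequence A single A/C/G/T string.
#' @param time Edge duration in units of `1/mu0`.
#' @param params A [burst_params()] object (`mu0` and `cpg_factor` are used).
#' @param seed Optional integer seed.
#' @param count_events Also return the number of realised mutation events per
#'   site (useful for rate diagnostics).
#' @return The mutated sequence as a string, or (with `count_events = TRUE`)
#'   a list with elements `sequence` and `events` (integer per-site counts).
#' @examples
#' mutate_sequence("ACGTACGT", 0.5, burst_params(gamma = 1), seed = 1)
#' @export
mutate_sequence <- function(sequence, time, params, seed = NULL,
                            count_events = FALSE) {
  stop_domain_if(time < 0, "`time` must be non-negative.")
  s <- seq_to_int(sequence)
  with_seed(seed, {
    out <- mutate_int(s, time, params$mu0, params$cpg_factor,
                      count_events = count_events)
    if (count_events) {
      list(sequence = int_to_seq(out$seq), events = out$events)
    } else {
      int_to_seq(out$seq)
    }
  })
}

# Gillespie loop on the integer-coded sequence. Channel weights at a
# hypermutable position: the background mu0 split evenly over the three
# alternatives plus (cpg_factor - 1) * mu0 on the deamination channel
# (C>T at the C, G>A at the G).
mutate_int <- function(s, time, mu0, cpg_factor, count_events = FALSE) {
  L <- length(s)
  ev <- if (count_events) integer(L) else NULL
  if (L == 0L || time == 0 || mu0 == 0) {
    return(list(seq = s, events = ev))
  }
  extra <- (cpg_factor - 1) * mu0
  rates <- site_rates(s, mu0, cpg_factor)
  total <- sum(rates)
  t <- stats::rexp(1) / total
  while (t <= time) {
    i <- sample.int(L, 1L, prob = rates)
    hyper <- rates[i] > mu0
    cur <- s[i]
    targets <- (1:4)[-cur]
    if (!hyper) {
      s[i] <- targets[sample.int(3L, 1L)]
    } else if (cur == 2L) {         # C in CpG: deamination boosts C>T
      w <- mu0 / 3 + c(0, 0, extra) # targets A, G, T
      s[i] <- targets[sample.int(3L, 1L, prob = w)]
    } else {                        # G in CpG: boosts G>A
      w <- mu0 / 3 + c(extra, 0, 0) # targets A, C, T
      s[i] <- targets[sample.int(3L, 1L, prob = w)]
    }
    if (count_events) ev[i] <- ev[i] + 1L
    # refresh the rates of the site and its neighbours (CpG context change)
    lo <- max(1L, i - 1L)
    hi <- min(L, i + 1L)
    for (j in lo:hi) {
      in_cpg <- (s[j] == 2L && j < L && s[j + 1L] == 3L) ||
        (s[j] == 3L && j > 1L && s[j - 1L] == 2L)
      new_r <- if (in_cpg) cpg_factor * mu0 else mu0
      total <- total + new_r - rates[j]
      rates[j] <- new_r
    }
    t <- t + stats::rexp(1) / total
  }
  list(seq = s, events = ev)
}

#' Evolve sequences along a burst tree
#'
#' Starting from the ancestral sequence at the root, mutates along every edge
#' under the CpG-aware model of [mutate_sequence()] (including the founder's
#' pre-first-duplication root edge) and duplicates at the nodes, returning
#' one present-day sequence per leaf. The model has no indels, so all
#' sequences keep the ancestral length.
#'
#' @param tree A [simulate_burst()] tree.
#' @param ancestor Ancestral sequence (A/C/G/T string), e.g. from
#'   [make_ancestral()].
#' @param params A [burst_params()] object; defaults to the tree's.
#' @param seed Optional integer seed.
#' @return An `element_set`: a tibble with columns `id` (leaf label) and
#'   `sequence`, carrying the ancestor and parameters as attributes.
#' @examples
#' p <- burst_params(gamma = 10, T1 = 0.05, T2 = 0.02)
#' tr <- simulate_burst(p, 10, seed = 1)
#' evolve_sequences(tr, make_ancestral(seed = 1), seed = 2)
#' @export
evolve_sequences <- function(tree, ancestor, params = tree$params,
                             seed = NULL) {
  root_seq <- seq_to_int(ancestor)   # validates the alphabet
  stop_input_if_empty(root_seq)
  n <- tree$n_leaves
  with_seed(seed, {
    leaves <- vector("list", n)
    if (tree$Nnode == 0L) {
      leaves[[1]] <- mutate_int(root_seq, tree$root_edge, params$mu0,
                                params$cpg_factor)$seq
    } else {
      m <- nrow(tree$edge)
      kids <- vector("list", n + tree$Nnode)
      for (i in seq_len(m)) {
        p <- tree$edge[i, 1]
        kids[[p]] <- c(kids[[p]], i)
      }
      root <- n + 1L
      sroot <- mutate_int(root_seq, tree$root_edge, params$mu0,
                          params$cpg_factor)$seq
      stack_node <- integer(n + 1L)
      stack_seq <- vector("list", n + 1L)
      top <- 1L
      stack_node[1] <- root
      stack_seq[[1]] <- sroot
      while (top > 0L) {
        v <- stack_node[top]
        sv <- stack_seq[[top]]
        stack_seq[top] <- list(NULL)
        top <- top - 1L
        for (k in kids[[v]]) {
          child <- tree$edge[k, 2]
          sc <- mutate_int(sv, tree$edge.length[k], params$mu0,
                           params$cpg_factor)$seq
          if (child <= n) {
            leaves[[child]] <- sc
          } else {
            top <- top + 1L
            stack_node[top] <- child
            stack_seq[[top]] <- sc
          }
        }
      }
    }
    element_set(vapply(leaves, int_to_seq, character(1)),
                ids = paste0("L", seq_len(n)),
                ancestor = ancestor, params = params)
  })
}

stop_input_if_empty <- function(x) {
  if (length(x) == 0L) stop_input("`ancestor` must be non-empty.")
  invisible(NULL)
}

#' Construct an element set
#'
#' @param sequences Character vector of A/C/G/T sequences.
#' @param ids Sequence identifiers (default `L1..Ln`).
#' @param ancestor Optional ancestral sequence.
#' @param params Optional [burst_params()].
#' @return A tibble of class `element_set` with columns `id`, `sequence`.
#' @export
element_set <- function(sequences, ids = paste0("L", seq_along(sequences)),
                        ancestor = NULL, params = NULL) {
  out <- tibble::tibble(id = unname(as.character(ids)),
                        sequence = unname(toupper(sequences)))
  class(out) <- c("element_set", class(out))
  attr(out, "ancestor") <- ancestor
  attr(out, "params") <- params
  out
}

#' Pairwise divergence of two equal-length sequences
#'
#' Hamming distance divided by the sequence length.
#'
#' @param a,b A/C/G/T strings of equal length.
#' @return Fraction of differing sites, in `[0, 1]`.
#' @examples
#' pairwise_divergence("ACGT", "ACGA") # 0.25
#' @export
pairwise_divergence <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) {
    stop_input("sequences must have equal length.")
  }
  mean(x != y)
}
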