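# Coerce the accepted sequence containers to an upper-case character vector.
as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(toupper(as.character(x)))
  }
  if (is.data.frame(x)) {
    stop_input_if(!"sequence" %in% names(x),
                  "data-frame input must have a `sequence` column.")
    return(toupper(x$sequence))
  }
  if (is.character(x)) {
    return(toupper(x))
  }
  stop_input("`sequences` must be a character vector, an element_set/tibble or a DNAStringSet.")
}

stop_input_if <- function(cond, msg) {
  if (isTRUE(cond)) stop_input(msg)
  invisible(NULL)
}

#' Count k-mers in a sequence set
#'
#' Every length-`k` window of every sequence (forward strand, overlapping)
#' contributes one occurrence. Windows containing letters outside
#' \{A,C,G,T\} are skipped rather than raising an error, so degenerate
#' bases in real repeat FASTA are tolerated. No reverse-complement
#' canonicalisation is performed: repeat elements are analysed in their
#' extracted orientation.
#'
#' @param sequences Character vector, `element_set` (or any data frame with a
#'   `sequence` column), or a `Biostrings::DNAStringSet`.
#' @param k K-mer length (>= 1).
#' @return A tibble with columns `kmer` and `count`, one row per distinct
#'   k-mer in first-occurrence order; the `k` used is kept as an attribute.
#' @examples
#' count_kmers(c("ACGT", "AAAA"), 2)
#' @export
count_kmers <- function(sequences, k) {
  stop_domain_if(k < 1, "`k` must be >= 1.")
  k <- as.integer(k)
  seqs <- as_sequences(sequences)
  len <- nchar(seqs)
  seqs <- seqs[len >= k]
  len <- len[len >= k]
  if (length(seqs) == 0L) {
    out <- tibble::tibble(kmer = character(0), count = integer(0))
    attr(out, "k") <- k
    return(out)
  }
  dirty <- grepl("[^ACGT]", seqs)
  max_start <- max(len) - k + 1L
  chunks <- vector("list", max_start)
  for (i in seq_len(max_start)) {
    w <- substr(seqs[len >= i + k - 1L], i, i + k - 1L)
    chunks[[i]] <- w
  }
  kmers <- unlist(chunks, use.names = FALSE)
  if (any(dirty)) {
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
  }
  kmer <- count <- NULL # appease R CMD check; data.table NSE
  dt <- data.table::data.table(kmer = kmers)
  tab <- dt[, list(count = .N), by = kmer]
  out <- tibble::tibble(kmer = tab$kmer, count = tab$count)
  attr(out, "k") <- k
  out
}

# number of clean length-k windows, without enumerating them
total_kmer_windows <- function(sequences, k) {
  seqs <- as_sequences(sequences)
  clean <- !grepl("[^ACGT]", seqs)
  tot <- sum(pmax(0L, nchar(seqs[clean]) - k + 1L))
  for (s in seqs[!clean]) {
    runs <- regmatches(s, gregexpr("[ACGT]+", s))[[1]]
    tot <- tot + sum(pmax(0L, nchar(runs) - k + 1L))
  }
  tot
}

#' Abundance spectrum from k-mer counts
#'
#' Tabulates `n_k(s)`: the number of distinct k-mers whose abundance is
#' exactly `s`. The conservation identity `sum(s * n)` = total number of
#' counted windows holds by construction.
#'
#' @param counts Output of [count_kmers()] (tibble with `count`), or a bare
#'   numeric vector of abundances.
#' @param k K-mer length (taken from the `counts` attribute when absent).
#' @return A tibble of class `abundance_spectrum` with columns `k`, `s`, `n`,
#'   sorted by `s`; total window count kept as attribute `total_kmers`.
#' @examples
#' spectrum_from_counts(count_kmers(c("ACGTACGT"), 4))
#' @export
spectrum_from_counts <- function(counts, k = NULL) {
  if (is.data.frame(counts)) {
    k <- k %||% attr(counts, "k")
    ab <- counts$count
  } else {
    ab <- counts
  }
  stop_input_if(is.null(k), "supply `k` (not present on `counts`).")
  tab <- table(ab)
  out <- tibble::tibble(
    k = as.integer(k),
    s = as.integer(names(tab)),
    n = as.integer(tab)
  )
  out <- dplyr::arrange(out, .data$s)
  class(out) <- c("abundance_spectrum", class(out))
  attr(out, "total_kmers") <- sum(as.numeric(out$s) * out$n)
  out
}

#' Abundance spectra over a grid of k
#'
#' @param sequences Any input accepted by [count_kmers()].
#' @param k_values Vector of k-mer lengths.
#' @return A single tibble of class `abundance_spectrum` with columns
#'   `k`, `s`, `n` (rows for every k).
#' @examples
#' kmer_spectra(c("ACGTACGTACGT"), k_values = c(2, 4))
#' @export
kmer_spectra <- function(sequences, k_values) {
  seqs <- as_sequences(sequences)
  out <- purrr::map(k_values, function(k) {
    spectrum_from_counts(count_kmers(seqs, k), k = k)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("abundance_spectrum", class(res))
  res
}

#' Logarithmically bin an abundance spectrum
#'
#' Abundances up to `threshold` are kept as unit bins; above the threshold,
#' geometric bin edges `threshold * ratio^j` are integerised to half-open
#' ranges `[ceiling(lo), ceiling(hi))` (empty ranges dropped), so the total
#' mass is conserved exactly. The plotted bin centre is the abundance itself
#' for unit bins and the geometric mean of the integer edges for log bins.
#'
#' @param spectrum An [spectrum_from_counts()] tibble (single or multiple k).
#' @param threshold Largest abundance kept at unit resolution.
#' @param ratio Geometric edge ratio of the log bins.
#' @return A tibble of class `binned_spectrum` with columns `k`, `s_lo`,
#'   `s_hi` (half-open integer edges), `center`, `mass` and `density`
#'   (mass / integer bin width).
#' @examples
#' sp <- spectrum_from_counts(c(rep(1, 50), rep(12, 3), 40), k = 8)
#' log_bin(sp)
#' @export
log_bin <- function(spectrum, threshold = 7, ratio = 1.1885) {
  stop_domain_if(ratio <= 1, "`ratio` must exceed 1.")
  stop_domain_if(threshold < 1, "`threshold` must be >= 1.")
  bin_one <- function(df) {
    kk <- df$k[1]
    unit <- df[df$s <= threshold, ]
    out_unit <- tibble::tibble(
      k = kk, s_lo = unit$s, s_hi = unit$s + 1L,
      center = as.numeric(unit$s), mass = as.numeric(unit$n),
      density = as.numeric(unit$n)
    )
    hi_part <- df[df$s > threshold, ]
    if (nrow(hi_part) == 0L) {
      return(out_unit)
    }
    smax <- max(hi_part$s)
    j_max <- ceiling(log(smax / threshold) / log(ratio)) + 1L
    raw <- threshold * ratio^(0:j_max)
    edges <- unique(pmax(ceiling(raw), threshold + 1L))
    if (edges[length(edges)] <= smax) edges <- c(edges, smax + 1L)
    lo <- edges[-length(edges)]
    hi <- edges[-1]
    keep <- hi > lo
    lo <- lo[keep]; hi <- hi[keep]
    idx <- findInterval(hi_part$s, lo)
    mass <- vapply(seq_along(lo), function(j) {
      sum(as.numeric(hi_part$n[idx == j]))
    }, numeric(1))
    out_log <- tibble::tibble(
      k = kk, s_lo = lo, s_hi = hi,
      center = sqrt(as.numeric(lo) * as.numeric(hi)),
      mass = mass, density = mass / (hi - lo)
    )
    dplyr::bind_rows(out_unit, out_log)
  }
  res <- spectrum |>
    dplyr::group_by(.data$k) |>
    dplyr::group_split() |>
    purrr::map(bin_one) |>
    dplyr::bind_rows()
  class(res) <- c("binned_spectrum", class(res))
  attr(res, "threshold") <- threshold
  attr(res, "ratio") <- ratio
  res
}

#' Zipf rank table of k-mer abundances
#'
#' Sorts abundances in decreasing order and attaches ranks `1..n`; on
#' log-log axes a tail exponent `alpha` of the abundance spectrum appears as
#' a Zipf slope of `-1/(alpha - 1)`.
#'
#' @param counts Output of [count_kmers()] or a numeric vector of abundances.
#' @return A tibble with columns `rank` and `abundance` (non-increasing).
#' @examples
#' zipf_ranks(c(A = 5, B = 2, C = 2))
#' @export
zipf_ranks <- function(counts) {
  ab <- if (is.data.frame(counts)) counts$count else as.numeric(counts)
  if (length(ab) == 0L) {
    return(tibble::tibble(rank = integer(0), abundance = numeric(0)))
  }
  ab <- sort(ab, decreasing = TRUE)
  tibble::tibble(rank = seq_along(ab), abundance = ab)
}
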