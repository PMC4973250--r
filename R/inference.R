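#' Discrete Hill estimator of a power-law tail exponent
#'
#' Maximum-likelihood estimator for a discrete power law
#' `P(s) ~ s^-alpha`, applied to the tail sample of abundances at or above
#' `s_min` with the standard half-integer continuity shift:
#' \deqn{\hat\alpha = 1 + n \left[\sum_i \ln\frac{s_i}{s_{\min} - 1/2}\right]^{-1}.}
#'
#' @param abundances Vector of positive counts (one observation per distinct
#'   k-mer, clone, ...).
#' @param s_min Tail cutoff: only observations with `s >= s_min` enter.
#' @return The estimate (a single number, always > 1), with the tail sample
#'   size attached as attribute `n_tail`.
#' @examples
#' hill_exponent(c(3, 3, 3)) # 1 + 1/log(1.2)
#' @export
hill_exponent <- function(abundances, s_min = 3) {
  s <- abundances[abundances >= s_min]
  if (length(s) < 2L) {
    stop_estimation(sprintf(
      "need at least 2 tail observations with s >= %g (got %d).",
      s_min, length(s)))
  }
  alpha <- 1 + length(s) / sum(log(s / (s_min - 0.5)))
  attr(alpha, "n_tail") <- length(s)
  alpha
}

#' Hill exponent of the abundance tail for each k
#'
#' For every requested `k`, counts k-mers in the sequence set, takes the
#' abundances of the distinct k-mers at or above `s_min`, and applies the
#' discrete Hill estimator. Values of `k` with fewer than `min_tail` tail
#' observations are skipped.
#'
#' @param elements Any input accepted by [count_kmers()] (an `element_set`,
#'   character vector, data frame with a `sequence` column or DNAStringSet).
#' @param k_values K-mer lengths to profile.
#' @param s_min Tail cutoff for the Hill estimator.
#' @param min_tail Minimum tail sample size for a k to be kept.
#' @return A tibble of class `exponent_curve` with columns `k`, `alpha_hat`,
#'   `n_tail` and `se` (the asymptotic Hill standard error
#'   `(alpha_hat - 1) / sqrt(n_tail)`).
#' @examples
#' el <- rep(c("ACGTACGTAC", "ACGTACGAAC"), c(6, 2))
#' exponent_curve(el, k_values = 4)
#' @export
exponent_curve <- function(elements, k_values = seq(35, 75, by = 5),
                           s_min = 3, min_tail = 10) {
  seqs <- as_sequences(elements)
  rows <- purrr::map(k_values, function(k) {
    cnt <- count_kmers(seqs, k)
    tail_s <- cnt$count[cnt$count >= s_min]
    if (length(tail_s) < max(2L, min_tail)) {
      return(NULL)
    }
    a <- hill_exponent(tail_s, s_min = s_min)
    tibble::tibble(k = k, alpha_hat = as.numeric(a),
                   n_tail = attr(a, "n_tail"))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop_estimation("no k had a sufficient abundance tail (s >= s_min).")
  }
  out$se <- (out$alpha_hat - 1) / sqrt(out$n_tail)
  class(out) <- c("exponent_curve", class(out))
  attr(out, "s_min") <- s_min
  out
}

#' Fit the exponent curve with the analytic alpha(k)
#'
#' Single-parameter Levenberg-Marquardt least-squares fit of the analytic
#' exponent `alpha(k) = 1 + 1 / (1 - ratio * k)` to measured Hill exponents,
#' over the window `k_lo <= k <= k_hi`. The free parameter is the rate ratio
#' `mu / (delta * gamma)`. The initial guess comes from inverting the
#' first and last points of the window.
#'
#' @param curve An [exponent_curve()] tibble (columns `k`, `alpha_hat`).
#' @param k_lo,k_hi Fit window in k.
#' @return An object of class `ratio_fit` with elements `ratio_hat`,
#'   `se`, `residual_norm`, `n_points`, `k_range` and the underlying
#'   `nls` fit. Use [generics::tidy()] / [generics::glance()].
#' @examples
#' crv <- tibble::tibble(k = seq(35, 75, 5),
#'                       alpha_hat = alpha_of_k(seq(35, 75, 5), ratio = 0.009))
#' fit_ratio(crv)
#' @export
fit_ratio <- function(curve, k_lo = 35, k_hi = 75) {
  pts <- curve[curve$k >= k_lo & curve$k <= k_hi, ]
  if (nrow(pts) < 2L) {
    stop_estimation(sprintf(
      "need >= 2 exponent-curve points inside [%g, %g]; got %d.",
      k_lo, k_hi, nrow(pts)))
  }
  # invert alpha = 1 + 1/(1 - r k)  =>  r = (alpha - 2)/(k (alpha - 1))
  inv <- function(k, a) pmax((a - 2) / (k * (a - 1)), 1e-8)
  r0 <- mean(inv(range(pts$k), pts$alpha_hat[c(1, nrow(pts))]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      alpha_hat ~ 1 + 1 / (1 - ratio * k),
      data = pts,
      start = list(ratio = r0),
      lower = 0, upper = 1 / max(pts$k) - 1e-12,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop_estimation(paste0("exponent-curve fit failed to converge: ",
                             conditionMessage(e)))
    }
  )
  est <- summary(fit)$coefficients
  structure(list(
    ratio_hat = unname(est["ratio", "Estimate"]),
    se = unname(est["ratio", "Std. Error"]),
    residual_norm = sum(stats::residuals(fit)^2),
    n_points = nrow(pts),
    k_range = c(k_lo, k_hi),
    fit = fit,
    curve = pts
  ), class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat("<ratio_fit>\n")
  cat(sprintf("  ratio mu/(delta*gamma) = %.6g (se %.2g)\n", x$ratio_hat, x$se))
  cat(sprintf("  %d points in k = [%g, %g], RSS = %.4g\n",
              x$n_points, x$k_range[1], x$k_range[2], x$residual_norm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_ratio
#' @param x A `ratio_fit` object.
#' @param ... Unused.
#' @export
tidy.ratio_fit <- function(x, ...) {
  tibble::tibble(term = "ratio", estimate = x$ratio_hat, std.error = x$se)
}

#' @rdname fit_ratio
#' @export
glance.ratio_fit <- function(x, ...) {
  tibble::tibble(ratio_hat = x$ratio_hat, std.error = x$se,
                 residual_norm = x$residual_norm, n_points = x$n_points,
                 k_lo = x$k_range[1], k_hi = x$k_range[2])
}

#' Estimate the number of repeat elements from k-mer totals
#'
#' Each element of length `L` contributes `L - k + 1` k-mers, so the total
#' k-mer occurrence count divided by `L - k + 1` estimates the element
#' count; the estimate is averaged over a range of k. For equal-length clean
#' sequences the estimate is exact for every k; mixed lengths bias it in
#' proportion to the length deviations.
#'
#' @param elements Any input accepted by [count_kmers()].
#' @param k_values K-mer lengths averaged over.
#' @param L Assumed element length in bp.
#' @return The element-count estimate (a single number).
#' @examples
#' estimate_N(rep(strrep("ACGT", 75), 10)) # 10
#' @export
estimate_N <- function(elements, k_values = 5:90, L = 300) {
  stop_domain_if(L <= max(k_values), "`L` must exceed max(k_values).")
  seqs <- as_sequences(elements)
  stop_input_if(length(seqs) == 0L, "`elements` is empty.")
  per_k <- vapply(k_values, function(k) {
    total_kmer_windows(seqs, k) / (L - k + 1)
  }, numeric(1))
  mean(per_k)
}

#' Fit the silent-phase duration T2 by spectrum matching
#'
#' Simulates the model (with `delta = 1`, where the spectra are insensitive
#' to `delta`) at each candidate `T2`, builds log-binned abundance spectra
#' for the same `k` values as the reference, and scores each candidate by
#' the mean squared difference of log10 densities over shared bins, summed
#' over k. Several simulation seeds per grid point are averaged.
#'
#' @param reference_spectra A [log_bin()]-ned spectrum tibble (multiple k
#'   allowed) computed from the data being fitted.
#' @param params A [burst_params()] object; its `T2` entry is ignored.
#' @param T2_grid Candidate values of `T2` (units `1/mu0`).
#' @param target_n Elements per simulation.
#' @param ancestor Ancestral sequence used for the simulations.
#' @param k_values K-mer lengths; defaults to those present in the reference.
#' @param n_seeds Simulation replicates averaged per grid point.
#' @param seed Integer seed for the whole scan.
#' @param threshold,ratio Binning settings (must match the reference).
#' @return An object of class `t2_fit`: list with `best_T2` and the
#'   `profile` tibble (columns `T2`, `distance`).
#' @export
fit_T2 <- function(reference_spectra, params, T2_grid, target_n, ancestor,
                   k_values = NULL, n_seeds = 3, seed = NULL,
                   threshold = 7, ratio = 1.1885) {
  stop_domain_if(length(T2_grid) == 0L, "`T2_grid` must be non-empty.")
  k_values <- k_values %||% sort(unique(reference_spectra$k))
  ref_key <- spectrum_key(reference_spectra)
  # the spectra are delta-insensitive at fixed delta*gamma in the asymptotic
  # regime, so the scan simulates the cheap fully-active parameterisation
  sim_params <- params
  sim_params$gamma <- params$delta * params$gamma
  sim_params$delta <- 1
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, length(T2_grid) * n_seeds)
    dist <- purrr::map_dbl(seq_along(T2_grid), function(i) {
      p <- sim_params
      p$T2 <- T2_grid[i]
      d <- vapply(seq_len(n_seeds), function(j) {
        s <- seeds[(i - 1L) * n_seeds + j]
        sim <- simulate_elements(p, target_n, ancestor, seed = s)
        binned <- log_bin(kmer_spectra(sim, k_values),
                          threshold = threshold, ratio = ratio)
        spectrum_distance(ref_key, spectrum_key(binned))
      }, numeric(1))
      mean(d)
    })
    structure(list(
      best_T2 = T2_grid[which.min(dist)],
      profile = tibble::tibble(T2 = T2_grid, distance = dist)
    ), class = "t2_fit")
  })
}

# flat key -> log-density lookup for binned spectra
spectrum_key <- function(binned) {
  pos <- binned[binned$density > 0, ]
  stats::setNames(log10(pos$density),
                  paste(pos$k, pos$s_lo, pos$s_hi, sep = ":"))
}

spectrum_distance <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    stop_estimation("binned spectra share no bins; check the binning settings.")
  }
  mean((a[shared] - b[shared])^2)
}

#' @export
print.t2_fit <- function(x, ...) {
  cat("<t2_fit>\n")
  cat(sprintf("  best T2 = %g over %d grid points\n",
              x$best_T2, nrow(x$profile)))
  invisible(x)
}

#' @rdname fit_T2
#' @param x A `t2_fit` object.
#' @param ... Unused.
#' @export
tidy.t2_fit <- function(x, ...) x$profile

#' @rdname fit_T2
#' @export
glance.t2_fit <- function(x, ...) {
  tibble::tibble(best_T2 = x$best_T2,
                 min_distance = min(x$profile$distance),
                 max_distance = max(x$profile$distance),
                 n_grid = nrow(x$profile))
}

#' Simulate a full element set in one call
#'
#' Convenience composition of [simulate_burst()] and [evolve_sequences()].
#'
#' @param params A [burst_params()] object.
#' @param target_n Number of elements.
#' @param ancestor Ancestral sequence; default built by [make_ancestral()]
#'   from the parameter set's `L` and `n_cpg`.
#' @param seed Integer seed covering both stages.
#' @return An `element_set` tibble; the tree is attached as attribute
#'   `tree`.
#' @examples
#' p <- burst_params(gamma = 20, T1 = 0.05, T2 = 0.01)
#' simulate_elements(p, 20, seed = 1)
#' @export
simulate_elements <- function(params, target_n, ancestor = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(ancestor)) {
      ancestor <- make_ancestral(params$L, params$n_cpg)
    }
    tree <- simulate_burst(params, target_n)
    els <- evolve_sequences(tree, ancestor, params)
    attr(els, "tree") <- tree
    els
  })
}
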