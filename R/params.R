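#' Model parameters for a repeat-family expansion burst
#'
#' Bundles the rate and time constants of the two-phase expansion model. All
#' rates are measured in units of the background per-nucleotide mutation rate
#' `mu0`, and all times in units of `1/mu0`, so `mu0 = 1` is the natural
#' default; a value of `mu0` in per-year units only enters via the reporting
#' helpers ([time_in_years()], [mu0_from_age()]).
#'
#' @param gamma Duplication rate of an active element, in units of `mu0`.
#' @param delta Probability that a newly created copy is itself active
#'   (able to duplicate). `delta = 1` is the transposon model, `delta -> 0`
#'   the master-gene model.
#' @param mu0 Background per-nucleotide mutation rate; the time unit.
#' @param cpg_factor Rate multiplier for nucleotides inside a CpG
#'   dinucleotide (deamination-driven C>T / G>A hypermutability).
#' @param T1 Duration of the active (duplication) burst, in units of `1/mu0`.
#' @param T2 Duration of the silent phase that follows, in units of `1/mu0`.
#' @param L Element length in bp.
#' @param n_cpg Number of CpG dinucleotides in the ancestral element.
#'
#' @return An object of class `burst_params` (a named list).
#' @seealso [alu_params()] for an Alu-family calibrated default set.
#' @examples
#' p <- burst_params(gamma = 200, delta = 1, T1 = 0.068, T2 = 0.024)
#' effective_rates(p)
#' @export
burst_params <- function(gamma, delta = 1, mu0 = 1, cpg_factor = 6,
                         T1 = 0, T2 = 0, L = 300, n_cpg = 24) {
  stop_domain_if(!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0,
                 "`gamma` must be a single positive number.")
  stop_domain_if(delta < 0 || delta > 1, "`delta` must lie in [0, 1].")
  stop_domain_if(mu0 <= 0, "`mu0` must be positive.")
  stop_domain_if(cpg_factor < 1, "`cpg_factor` must be >= 1.")
  stop_domain_if(T1 < 0 || T2 < 0, "`T1` and `T2` must be non-negative.")
  stop_domain_if(L < 1, "`L` must be at least 1.")
  stop_domain_if(n_cpg < 0 || 2 * n_cpg > L,
                 "need 0 <= 2 * n_cpg <= L (CpG dinucleotides occupy 2 bp each).")
  structure(
    list(gamma = gamma, delta = delta, mu0 = mu0, cpg_factor = cpg_factor,
         T1 = T1, T2 = T2, L = as.integer(L), n_cpg = as.integer(n_cpg)),
    class = "burst_params"
  )
}

#' Alu-family calibrated parameter set
#'
#' Parameters calibrated to the human Alu repeat family (excluding the still
#' active AluY subfamily): an AluSx-like ancestor of `L = 300` bp with 24 CpG
#' dinucleotides, effective duplication rate `delta * gamma = 200 mu0`, burst
#' duration `T1` chosen so that the expected element count at the end of the
#' burst equals `n_final` (776710 by default, the family's census size), and
#' silent phase `T2 = 0.024 / mu0`.
#'
#' @param delta Active-copy probability; `gamma` is scaled as `200 / delta`
#'   so the effective duplication rate is held fixed.
#' @param n_final Expected number of elements at the end of the burst, used
#'   to set `T1`.
#' @return A [burst_params()] object.
#' @examples
#' alu_params()$T1 # about 6.8e-2
#' @export
alu_params <- function(delta = 1, n_final = 776710) {
  gamma <- 200 / delta
  p <- burst_params(gamma = gamma, delta = delta, mu0 = 1, cpg_factor = 6,
                    T1 = 0, T2 = 0.024, L = 300, n_cpg = 24)
  p$T1 <- estimate_T1(n_final, p)
  p
}

#' @export
print.burst_params <- function(x, ...) {
  cat("<burst_params>\n")
  cat(sprintf("  gamma = %g, delta = %g  (delta*gamma = %g)\n",
              x$gamma, x$delta, x$delta * x$gamma))
  cat(sprintf("  T1 = %g, T2 = %g  (units 1/mu0)\n", x$T1, x$T2))
  cat(sprintf("  L = %d bp, %d CpG, cpg_factor = %g, mu0 = %g\n",
              x$L, x$n_cpg, x$cpg_factor, x$mu0))
  invisible(x)
}

#' Effective per-nucleotide mutation rate of an element
#'
#' The length-weighted average of the background rate (1, in units of `mu0`)
#' and the CpG rate (`cpg_factor`), given that `2 * n_cpg` of the `L`
#' positions sit inside CpG dinucleotides:
#' `mu = ((L - 2 n_cpg) + 2 n_cpg * cpg_factor) / L`.
#' For the Alu defaults (300 bp, 24 CpG, factor 6) this is 1.8.
#'
#' @param L Element length in bp.
#' @param n_cpg Number of CpG dinucleotides.
#' @param cpg_factor CpG rate multiplier.
#' @return Effective rate in units of `mu0` (a single number).
#' @examples
#' effective_mu(300, 24, 6) # 1.8
#' @export
effective_mu <- function(L = 300, n_cpg = 24, cpg_factor = 6) {
  stop_domain_if(n_cpg < 0 || 2 * n_cpg > L,
                 "need 0 <= 2 * n_cpg <= L.")
  ((L - 2 * n_cpg) + 2 * n_cpg * cpg_factor) / L
}

#' Effective rates implied by a parameter set
#'
#' @param params A [burst_params()] object.
#' @return A one-row tibble with columns `mu` (effective mutation rate,
#'   units `mu0`), `delta_gamma` (effective duplication rate) and `ratio`
#'   (`mu / delta_gamma`), the single dimensionless parameter that controls
#'   the exponent curve.
#' @examples
#' effective_rates(alu_params())
#' @export
effective_rates <- function(params) {
  mu <- effective_mu(params$L, params$n_cpg, params$cpg_factor) * params$mu0
  dg <- params$delta * params$gamma
  tibble::tibble(mu = mu, delta_gamma = dg, ratio = mu / dg)
}

#' Convert model-unit times and rates to calendar units
#'
#' Model times are in units of `1/mu0`. Given a value of the background
#' mutation rate in per-year units, `time_in_years()` converts a model time
#' to years; `mu0_from_age()` inverts the relation, estimating `mu0` in
#' per-year units from a model-unit age and an independently known calendar
#' age (e.g. the ~80 My phylogenetic age of a repeat family).
#'
#' @param t Time in model units (`1/mu0`).
#' @param mu0_per_year Background mutation rate in `yr^-1`.
#' @return Years (`time_in_years`) or a rate in `yr^-1` (`mu0_from_age`).
#' @examples
#' mu0_from_age(7.7e-2, 80e6) # about 0.96e-9 per year
#' @export
time_in_years <- function(t, mu0_per_year = 1e-9) {
  stop_domain_if(mu0_per_year <= 0, "`mu0_per_year` must be positive.")
  t / mu0_per_year
}

#' @rdname time_in_years
#' @param age_years Calendar age in years.
#' @export
mu0_from_age <- function(t, age_years) {
  stop_domain_if(age_years <= 0, "`age_years` must be positive.")
  t / age_years
}
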